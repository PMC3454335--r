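#' @include AllClasses.R
#' @importFrom utils read.csv write.csv read.delim write.table
#' @importFrom rtracklayer import export blocks
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom VariantAnnotation readVcf info geno ref alt
NULL

# Coordinate convention: all in-memory intervals are GRanges (1-based,
# closed), the Bioconductor convention. 0-based half-open inputs (BED,
# bedGraph) and 1-based wiggle/VCF inputs are converted once, at the reader
# boundary, by rtracklayer / VariantAnnotation; writers convert back.

#' Read a plate table of dual-reporter measurements
#'
#' Parses a CSV of one well per row: \code{clone_id, batch_id, enzyme,
#' well_role, firefly, renilla}. Enzyme must be one of \code{Sau3AI},
#' \code{AluI}, \code{control}; well_role one of \code{experimental},
#' \code{promoter_only}, \code{no_promoter}, \code{positive_enhancer}.
#' Wells with a non-positive Renilla (no transfection-efficiency denominator)
#' or non-positive firefly signal are flagged \code{usable = FALSE} — never
#' silently dropped; downstream stages decide what to do with them.
#'
#' @param path CSV file path.
#' @return data.frame with the six input columns plus \code{usable} (logical)
#'   and \code{note} (why a well is unusable).
#' @export
readPlateTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("clone_id", "batch_id", "enzyme", "well_role", "firefly", "renilla")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("plate table is missing column(s): ", paste(missing, collapse = ", "))
  }
  badEnzyme <- which(!df$enzyme %in% .ENZYMES)
  if (length(badEnzyme)) {
    stop(
      "unknown enzyme in row(s) ", paste(badEnzyme, collapse = ", "),
      " (allowed: ", paste(.ENZYMES, collapse = ", "), ")"
    )
  }
  badRole <- which(!df$well_role %in% .WELL_ROLES)
  if (length(badRole)) {
    stop(
      "unknown well_role in row(s) ", paste(badRole, collapse = ", "),
      " (allowed: ", paste(.WELL_ROLES, collapse = ", "), ")"
    )
  }
  df$firefly <- as.numeric(df$firefly)
  df$renilla <- as.numeric(df$renilla)
  df$usable <- TRUE
  df$note <- ""
  badRen <- is.na(df$renilla) | df$renilla <= 0
  df$usable[badRen] <- FALSE
  df$note[badRen] <- "renilla <= 0 or missing"
  badFf <- !badRen & (is.na(df$firefly) | df$firefly <= 0)
  df$usable[badFf] <- FALSE
  df$note[badFf] <- "firefly <= 0 or missing"
  df
}

#' Write a plate table
#'
#' Inverse of [readPlateTable()]; the \code{usable}/\code{note} columns are
#' derived and not written.
#'
#' @param df plate table data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePlateTable <- function(df, path) {
  cols <- c("clone_id", "batch_id", "enzyme", "well_role", "firefly", "renilla")
  write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' BED3/6/12 via rtracklayer; 0-based half-open records become 1-based closed
#' GRanges. With \code{expandBlocks = TRUE} a BED12 record is expanded into
#' its blocks (sub-intervals), each carrying the parent name.
#'
#' @param path BED file path.
#' @param expandBlocks expand BED12 blocks into one range each?
#' @return GRanges (with name/score metadata when present).
#' @export
readBed <- function(path, expandBlocks = FALSE) {
  gr <- import(path, format = "bed")
  if (any(start(gr) < 1L)) stop("negative start coordinate in BED input")
  if (expandBlocks && !is.null(mcols(gr)$blocks)) {
    bl <- blocks(gr)
    out <- unlist(bl, use.names = FALSE)
    mcols(out)$name <- rep(mcols(gr)$name, lengths(bl))
    return(out)
  }
  gr
}

#' Read a per-base score track
#'
#' Reads a bedGraph or wiggle (fixed-step) file and materializes one value per
#' covered base. Wiggle's 1-based starts and bedGraph's 0-based half-open
#' records are both converted by rtracklayer at the boundary. Overlapping
#' records are an error: a base may not have two values.
#'
#' @param path bedGraph (.bedGraph/.bg) or wiggle (.wig) file.
#' @param format "auto" (from extension), "bedGraph" or "wig".
#' @return A [ScoreTrack-class].
#' @export
readScoreTrack <- function(path, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  }
  gr <- import(path, format = format)
  if (is.null(mcols(gr)$score)) stop("score column missing from track")
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  if (sum(width(red)) != sum(width(gr))) {
    stop("overlapping records in score track: base values would be ambiguous")
  }
  ScoreTrack(
    intervals = GenomicRanges::granges(gr),
    values = NumericList(mapply(rep, mcols(gr)$score, width(gr), SIMPLIFY = FALSE))
  )
}

#' Write a score track as bedGraph
#'
#' One record per base (exact per-base round trip with [readScoreTrack()]).
#'
#' @param track a [ScoreTrack-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreTrack <- function(track, path) {
  iv <- trackIntervals(track)
  chrom <- rep(as.character(seqnames(iv)), width(iv))
  pos1 <- unlist(lapply(seq_along(iv), function(i) start(iv)[i]:end(iv)[i]))
  vals <- unlist(trackValues(track))
  writeLines(
    sprintf("%s\t%d\t%d\t%s", chrom, pos1 - 1L, pos1, format(vals, digits = 12)),
    path
  )
  invisible(path)
}

#' Read biallelic SNVs from a VCF
#'
#' Reads a VCF subset (CHROM/POS/ID/REF/ALT plus either an AF INFO field or
#' GT genotype columns) and computes the minor allele frequency as
#' \code{min(AF, 1 - AF)}. When AF is absent, the alternate-allele frequency
#' is computed from allele counts over non-missing genotype calls. Records
#' that are not biallelic SNVs (indels, multi-allelic sites) are retained but
#' flagged \code{usable = FALSE}, never silently dropped.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{pos0} (0-based offset), \code{id}, \code{ref}, \code{alt},
#'   \code{maf}, \code{usable}, \code{note}.
#' @export
readVariants <- function(path) {
  vcf <- readVcf(path, genome = "unknown")
  n <- nrow(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(ref(vcf))
  altList <- alt(vcf)
  nAlt <- lengths(altList)
  alts <- rep(NA_character_, n)
  alts[nAlt == 1L] <- as.character(unlist(altList[nAlt == 1L]))
  usable <- rep(TRUE, n)
  note <- rep("", n)
  multi <- nAlt != 1L
  usable[multi] <- FALSE
  note[multi] <- "not biallelic"
  notSnv <- !multi & (nchar(refs) != 1L | nchar(alts) != 1L |
    !refs %in% c("A", "C", "G", "T") | !alts %in% c("A", "C", "G", "T"))
  usable[notSnv] <- FALSE
  note[notSnv] <- "not an SNV"

  af <- rep(NA_real_, n)
  infoDf <- info(vcf)
  if ("AF" %in% colnames(infoDf)) {
    rawAf <- infoDf$AF
    af <- vapply(seq_len(n), function(i) {
      v <- rawAf[[i]]
      if (length(v)) as.numeric(v[1]) else NA_real_
    }, numeric(1))
  }
  needGt <- is.na(af)
  if (any(needGt)) {
    gt <- tryCatch(geno(vcf)$GT, error = function(e) NULL)
    if (is.null(gt)) {
      if (all(needGt)) stop("VCF has neither an AF INFO field nor GT genotypes")
    } else {
      gtAf <- apply(gt, 1L, function(g) {
        alleles <- unlist(strsplit(g, "[/|]"))
        alleles <- alleles[alleles != "."]
        if (!length(alleles)) return(NA_real_)
        mean(alleles != "0")
      })
      af[needGt] <- gtAf[needGt]
    }
  }
  if (anyNA(af[usable])) stop("allele frequency unavailable for some usable records")
  data.frame(
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    pos0 = start(rr) - 1L,
    id = names(rr),
    ref = refs,
    alt = alts,
    maf = pmin(af, 1 - af),
    usable = usable,
    note = note,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Read gene models from BED12
#'
#' One BED12 record per gene/transcript. Blocks become exons; thickStart /
#' thickEnd delimit the CDS, and each exon is split into pure-typed pieces
#' (UTR5 / CDS / UTR3 assigned strand-aware; genes without a thick region are
#' all \code{noncoding_exon}). Exons within a record must be sorted and
#' non-overlapping.
#'
#' @param path BED12 file path.
#' @return named list of [GeneModel-class], keyed by the BED name field.
#' @export
readGeneModel <- function(path) {
  gr <- import(path, format = "bed")
  if (is.null(mcols(gr)$blocks)) stop("BED12 input with block structure required")
  if (is.null(mcols(gr)$name)) stop("BED12 name field required (gene id)")
  bl <- blocks(gr)
  out <- lapply(seq_along(gr), function(i) {
    ex <- bl[[i]]
    if (length(ex) > 1L && is.unsorted(start(ex), strictly = TRUE)) {
      stop("exon blocks out of order for gene ", mcols(gr)$name[i])
    }
    thick <- mcols(gr)$thick[i]
    makeGeneModelFromExons(
      geneID = mcols(gr)$name[i],
      exons = ex,
      strand = as.character(strand(gr))[i],
      cdsStart = if (width(thick) > 0) start(thick) else NA_integer_,
      cdsEnd = if (width(thick) > 0) end(thick) else NA_integer_
    )
  })
  names(out) <- mcols(gr)$name
  out
}

#' Build a GeneModel from exon ranges and a CDS span
#'
#' Splits each exon at the CDS boundaries and assigns exon types strand-aware
#' (the 5' UTR is genomically left of the CDS on \code{+}, right of it on
#' \code{-}). Exons are reordered into transcript orientation.
#'
#' @param geneID gene identifier.
#' @param exons GRanges or IRanges of exon spans (1-based closed).
#' @param strand "+" or "-".
#' @param cdsStart,cdsEnd 1-based closed CDS span; NA for a non-coding gene.
#' @param chrom sequence name, used when \code{exons} is an IRanges.
#' @param cdsFrameOffset frame offset of the first codon (default 0).
#' @return A [GeneModel-class].
#' @export
makeGeneModelFromExons <- function(geneID, exons, strand,
                                   cdsStart = NA_integer_, cdsEnd = NA_integer_,
                                   chrom = "chr1", cdsFrameOffset = 0L) {
  if (is(exons, "GRanges")) {
    chrom <- as.character(seqnames(exons))[1]
    exons <- IRanges(start(exons), end(exons))
  }
  pieces <- list()
  for (j in seq_along(exons)) {
    s <- start(exons)[j]; e <- end(exons)[j]
    if (is.na(cdsStart)) {
      pieces[[length(pieces) + 1L]] <- c(s, e, "noncoding_exon")
      next
    }
    leftType <- if (strand == "+") "UTR5" else "UTR3"
    rightType <- if (strand == "+") "UTR3" else "UTR5"
    if (e < cdsStart) {
      pieces[[length(pieces) + 1L]] <- c(s, e, leftType)
    } else if (s > cdsEnd) {
      pieces[[length(pieces) + 1L]] <- c(s, e, rightType)
    } else {
      if (s < cdsStart) pieces[[length(pieces) + 1L]] <- c(s, cdsStart - 1L, leftType)
      pieces[[length(pieces) + 1L]] <- c(max(s, cdsStart), min(e, cdsEnd), "CDS")
      if (e > cdsEnd) pieces[[length(pieces) + 1L]] <- c(cdsEnd + 1L, e, rightType)
    }
  }
  m <- do.call(rbind, pieces)
  gr <- GRanges(
    chrom,
    IRanges(as.integer(m[, 1]), as.integer(m[, 2])),
    strand = strand,
    exon_type = m[, 3]
  )
  gr <- gr[order(start(gr), decreasing = (strand == "-"))]
  GeneModel(geneID, gr, cdsFrameOffset = cdsFrameOffset)
}

#' Read an expression matrix with sample factors
#'
#' The matrix TSV has gene identifiers in the first column and one column per
#' sample; the factor TSV has columns \code{sample}, \code{genotype} and
#' optionally \code{treatment}. Every matrix sample must appear in the factor
#' table (and vice versa).
#'
#' @param matrixPath expression matrix TSV.
#' @param factorPath sample factor TSV.
#' @return A [FactorialExpressionSet-class].
#' @export
readExpressionSet <- function(matrixPath, factorPath) {
  mat <- read.delim(matrixPath, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- mat[[1]]
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- genes
  fac <- read.delim(factorPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "genotype") %in% colnames(fac))) {
    stop("factor table needs 'sample' and 'genotype' columns")
  }
  if (!setequal(colnames(m), fac$sample)) {
    stop("samples in matrix and factor table do not match")
  }
  fac <- fac[match(colnames(m), fac$sample), ]
  FactorialExpressionSet(
    m,
    genotype = fac$genotype,
    treatment = if ("treatment" %in% colnames(fac)) fac$treatment else NULL
  )
}

#' Write an expression set as a matrix TSV + factor TSV pair
#'
#' @param fes a [FactorialExpressionSet-class].
#' @param matrixPath,factorPath output paths.
#' @return \code{matrixPath}, invisibly.
#' @export
writeExpressionSet <- function(fes, matrixPath, factorPath) {
  m <- SummarizedExperiment::assay(fes, "exprs")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(fes)
  fac <- data.frame(sample = colnames(m), genotype = cd$genotype)
  if ("treatment" %in% colnames(cd)) fac$treatment <- cd$treatment
  write.table(fac, factorPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

#' Write variant records as a minimal VCF
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO with the allele frequency in
#' an AF INFO field, readable by [readVariants()].
#'
#' @param variants data.frame with \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} and either \code{af} or \code{maf}.
#' @param path output VCF path.
#' @return \code{path}, invisibly.
#' @export
writeVariantsVcf <- function(variants, path) {
  af <- if ("af" %in% colnames(variants)) variants$af else variants$maf
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ids <- if ("id" %in% colnames(variants)) variants$id else
    sprintf("snv%d", seq_len(nrow(variants)))
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\t.\tAF=%s",
    variants$chrom, variants$pos, ids, variants$ref, variants$alt,
    format(af, digits = 6, trim = TRUE)
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
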