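#' @include AllClasses.R stats.R
#' @importFrom Biostrings DNAString reverseComplement subseq GENETIC_CODE
NULL

#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF strictly above the threshold (the population
#' screen keeps common polymorphisms, MAF > 1\%; a site at exactly the
#' threshold is dropped).
#'
#' @param variants variant data.frame ([readVariants()]).
#' @param mafMin threshold, strict (default 0.01).
#' @return the retained rows.
#' @export
filterByMaf <- function(variants, mafMin = 0.01) {
  variants[!is.na(variants$maf) & variants$maf > mafMin, , drop = FALSE]
}

# CDS sequence of a gene in translation order plus the genomic position of
# every CDS base (parallel to the sequence).
.cdsInfo <- function(gene, genome) {
  ex <- exons(gene)
  cds <- ex[mcols(ex)$exon_type == "CDS"]
  if (!length(cds)) return(NULL)
  chrom <- as.character(seqnames(cds))[1]
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " missing from genome")
  minus <- as.character(strand(cds))[1] == "-"
  seqParts <- character(length(cds))
  posParts <- vector("list", length(cds))
  for (j in seq_along(cds)) {
    piece <- subseq(genome[[chrom]], start(cds)[j], end(cds)[j])
    p <- start(cds)[j]:end(cds)[j]
    if (minus) { piece <- reverseComplement(piece); p <- rev(p) }
    seqParts[j] <- as.character(piece)
    posParts[[j]] <- p
  }
  list(
    seq = paste(seqParts, collapse = ""),
    genomicPos = unlist(posParts),
    minus = minus
  )
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify the coding consequence of a variant
#'
#' A biallelic SNV inside a CDS exon is classified by translating its
#' reference and alternate codons (strand-aware, standard nuclear genetic
#' code): same amino acid, synonymous; different (including stop gains or
#' losses), nonsynonymous. Variants in UTR or non-coding exons are
#' \code{noncoding}; a variant falling in a partial codon at a CDS edge (a
#' nonzero frame offset or a trailing incomplete codon) is \code{unassigned},
#' as is a variant outside the gene's exons. The FASTA reference base must
#' match the variant's REF allele.
#'
#' @param variant one-row variant data.frame (chrom, pos, ref, alt).
#' @param gene a [GeneModel-class].
#' @param genome named DNAStringSet (chromosome sequences).
#' @return one of "synonymous", "nonsynonymous", "noncoding", "unassigned".
#' @export
classifyConsequence <- function(variant, gene, genome) {
  stopifnot(nrow(variant) == 1L)
  ex <- exons(gene)
  gr <- GRanges(variant$chrom, IRanges(variant$pos, variant$pos))
  hits <- findOverlaps(gr, ex, ignore.strand = TRUE)
  if (!length(hits)) return("unassigned")
  type <- mcols(ex)$exon_type[subjectHits(hits)[1]]
  if (type != "CDS") return("noncoding")
  info <- .cdsInfo(gene, genome)
  cdsIdx <- match(variant$pos, info$genomicPos)
  refBaseGenomic <- as.character(subseq(genome[[variant$chrom]], variant$pos, variant$pos))
  if (refBaseGenomic != variant$ref) {
    stop(
      "REF allele mismatch at ", variant$chrom, ":", variant$pos,
      " (FASTA ", refBaseGenomic, ", VCF ", variant$ref, ")"
    )
  }
  off <- gene@cdsFrameOffset
  if (cdsIdx <= off) return("unassigned")
  codonNum <- (cdsIdx - off - 1L) %/% 3L
  codonStart <- off + codonNum * 3L + 1L
  if (codonStart + 2L > nchar(info$seq)) return("unassigned")
  refCodon <- substr(info$seq, codonStart, codonStart + 2L)
  altBase <- if (info$minus) .COMPLEMENT[[variant$alt]] else variant$alt
  altCodon <- refCodon
  substr(altCodon, cdsIdx - codonStart + 1L, cdsIdx - codonStart + 1L) <- altBase
  if (GENETIC_CODE[[refCodon]] == GENETIC_CODE[[altCodon]]) "synonymous"
  else "nonsynonymous"
}

#' Classify consequences for a variant table
#'
#' Applies [classifyConsequence()] to every usable row; non-SNV rows are
#' \code{unassigned}.
#'
#' @param variants variant data.frame.
#' @param gene a [GeneModel-class].
#' @param genome named DNAStringSet.
#' @return \code{variants} with an added \code{consequence} column.
#' @export
classifyConsequences <- function(variants, gene, genome) {
  variants$consequence <- vapply(seq_len(nrow(variants)), function(i) {
    if (!isTRUE(variants$usable[i])) return("unassigned")
    classifyConsequence(variants[i, , drop = FALSE], gene, genome)
  }, character(1))
  variants
}

#' Per-bp substitution rate over intervals
#'
#' Count of retained variant sites inside the intervals divided by the total
#' interval length in bases.
#'
#' @param intervals GRanges.
#' @param variants variant data.frame (already MAF-filtered as desired).
#' @return rate per bp (0 when the intervals are empty of variants).
#' @export
substitutionRate <- function(intervals, variants) {
  len <- sum(width(intervals))
  if (len == 0L) stop("zero-length interval set")
  if (!nrow(variants)) return(0)
  gr <- GRanges(variants$chrom, IRanges(variants$pos, variants$pos))
  hits <- findOverlaps(gr, intervals, ignore.strand = TRUE)
  length(unique(queryHits(hits))) / len
}

#' Compare element vs host-gene substitution rates
#'
#' For each element, computes the per-bp substitution rate inside the element
#' and in the remainder of its host gene's exons (the element's own bases are
#' excluded from the host denominator), then tests the paired differences
#' (element - host) with the Wilcoxon signed-rank dialect of
#' [wilcoxonSignedRank()] — zero differences are dropped, which is why the
#' effective N_r can be smaller than the number of elements. Strata:
#' \code{all} uses all exonic bases and all retained SNVs;
#' \code{synonymous} / \code{nonsynonymous} restrict both the variants (by
#' coding consequence) and the denominators (to CDS bases).
#'
#' @param panel list of entries, each a list with \code{element} (GRanges of
#'   length 1), \code{gene} ([GeneModel-class]) and optionally \code{id}.
#' @param variants variant data.frame ([readVariants()]).
#' @param genome named DNAStringSet; required for consequence strata.
#' @param stratum "all", "synonymous" or "nonsynonymous".
#' @param mafMin MAF filter threshold, strict (default 0.01).
#' @return list: \code{perElement} (id, element_rate, host_rate, diff),
#'   \code{medians} (element, host), \code{test} ([TestResult-class]).
#' @export
compareRates <- function(panel, variants, genome = NULL,
                         stratum = c("all", "synonymous", "nonsynonymous"),
                         mafMin = 0.01) {
  stratum <- match.arg(stratum)
  if (stratum != "all" && is.null(genome)) {
    stop("consequence strata require the genome sequence")
  }
  kept <- filterByMaf(variants[variants$usable, , drop = FALSE], mafMin)
  rows <- lapply(seq_along(panel), function(i) {
    entry <- panel[[i]]
    ex <- exons(entry$gene)
    vars <- kept[kept$chrom %in% as.character(seqnames(ex)), , drop = FALSE]
    if (stratum == "all") {
      denom <- granges(ex)
    } else {
      vars <- classifyConsequences(vars, entry$gene, genome)
      vars <- vars[vars$consequence == stratum, , drop = FALSE]
      denom <- granges(ex[mcols(ex)$exon_type == "CDS"])
    }
    elemIv <- GenomicRanges::intersect(
      granges(entry$element), denom, ignore.strand = TRUE
    )
    hostIv <- GenomicRanges::setdiff(denom, granges(entry$element),
                                     ignore.strand = TRUE)
    if (!sum(width(elemIv)) || !sum(width(hostIv))) {
      stop("element ", i, " has an empty element or host denominator in stratum '",
           stratum, "'")
    }
    data.frame(
      id = if (!is.null(entry$id)) entry$id else sprintf("element%d", i),
      element_rate = substitutionRate(elemIv, vars),
      host_rate = substitutionRate(hostIv, vars),
      stringsAsFactors = FALSE
    )
  })
  perElement <- do.call(rbind, rows)
  perElement$diff <- perElement$element_rate - perElement$host_rate
  test <- wilcoxonSignedRank(perElement$diff)
  list(
    perElement = perElement,
    medians = c(
      element = median(perElement$element_rate),
      host = median(perElement$host_rate)
    ),
    test = test
  )
}
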