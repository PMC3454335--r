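#' @include AllClasses.R
#' @importFrom GenomicRanges findOverlaps pintersect reduce granges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Filter clones to those whose best alignment is exonic
#'
#' Keeps clones whose rank-1 genome alignment has identity at or above
#' \code{minIdentity} (default 0.98, admitting near-perfect long fragments)
#' and overlaps an exon (CDS, UTR or non-coding exon) of a supplied gene
#' model. Clones whose rank-1 score is tied between multiple targets (e.g. a
#' gene and a processed pseudogene) are retained but flagged ambiguous.
#'
#' @param alignments data.frame with columns clone_id, chrom, start, end
#'   (1-based closed), strand, identity, score, rank.
#' @param genes list of [GeneModel-class].
#' @param minIdentity minimum alignment identity (default 0.98).
#' @return data.frame: clone_id, retained, flag (one row per clone).
#' @export
filterExonicClones <- function(alignments, genes, minIdentity = 0.98) {
  exonGr <- .allExons(genes)
  ids <- unique(alignments$clone_id)
  rows <- lapply(ids, function(id) {
    a <- alignments[alignments$clone_id == id, , drop = FALSE]
    if (!nrow(a)) {
      return(data.frame(clone_id = id, retained = FALSE, flag = "no_alignment"))
    }
    top <- a[a$rank == min(a$rank), , drop = FALSE]
    ambiguous <- nrow(top) > 1L && length(unique(top$score)) == 1L
    best <- top[which.max(top$score), , drop = FALSE]
    if (best$identity < minIdentity) {
      return(data.frame(clone_id = id, retained = FALSE, flag = "low_identity"))
    }
    gr <- GRanges(best$chrom, IRanges(best$start, best$end))
    hit <- length(findOverlaps(gr, exonGr, ignore.strand = TRUE)) > 0L
    data.frame(
      clone_id = id, retained = hit,
      flag = if (!hit) "non_exonic" else if (ambiguous) "ambiguous" else "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.allExons <- function(genes) {
  if (is(genes, "GeneModel")) genes <- list(genes)
  do.call(c, unname(lapply(genes, exons)))
}

#' Locate an element within its host gene
#'
#' Assigns the exon-type category of the element's genomic interval:
#' \code{coding} (CDS), \code{5'UTR}, \code{3'UTR} or \code{noncoding_exon}.
#' An element spanning two exon types gets the type with the majority of
#' overlapped bases, flagged as a boundary case. An element not overlapping
#' the gene at all is categorized \code{intergenic_intronic}.
#'
#' @param interval GRanges of length 1, the element.
#' @param gene a [GeneModel-class].
#' @return list with \code{category}, \code{boundary} (logical) and
#'   \code{overlap_bp} (named vector of bases overlapped per exon type).
#' @export
locateElement <- function(interval, gene) {
  stopifnot(length(interval) == 1L)
  ex <- exons(gene)
  hits <- findOverlaps(interval, ex, ignore.strand = TRUE)
  if (!length(hits)) {
    return(list(
      category = "intergenic_intronic", boundary = FALSE,
      overlap_bp = setNames(numeric(0), character(0))
    ))
  }
  ov <- pintersect(ex[subjectHits(hits)], rep(interval, length(hits)),
                   ignore.strand = TRUE)
  byType <- tapply(width(ov), mcols(ex)$exon_type[subjectHits(hits)], sum)
  byType <- sort(byType, decreasing = TRUE)
  labels <- c(
    CDS = "coding", UTR5 = "5'UTR", UTR3 = "3'UTR",
    noncoding_exon = "noncoding_exon"
  )
  list(
    category = unname(labels[names(byType)[1]]),
    boundary = length(byType) > 1L,
    overlap_bp = byType
  )
}

#' Annotate elements with feature-track overlaps
#'
#' Intersects elements with named feature tracks (TFBS peaks, DNase
#' hypersensitive sites, histone-mark or chromatin-state segments, ...) and
#' reports any overlap of at least one base, with its length.
#'
#' @param elements named GRanges of elements (names or \code{mcols()$name}
#'   used as element ids).
#' @param tracks named list of GRanges feature tracks.
#' @return data.frame: element, track, overlap_bp (one row per overlapping
#'   element x track pair).
#' @export
annotateOverlaps <- function(elements, tracks) {
  ids <- if (!is.null(names(elements))) names(elements)
         else if (!is.null(mcols(elements)$name)) mcols(elements)$name
         else sprintf("element%d", seq_along(elements))
  out <- list()
  for (tn in names(tracks)) {
    hits <- findOverlaps(elements, tracks[[tn]], ignore.strand = TRUE)
    if (!length(hits)) next
    ov <- pintersect(
      elements[queryHits(hits)], tracks[[tn]][subjectHits(hits)],
      ignore.strand = TRUE
    )
    out[[tn]] <- data.frame(
      element = ids[queryHits(hits)], track = tn, overlap_bp = width(ov),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(
      element = character(), track = character(), overlap_bp = integer(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect CpG islands
#'
#' Scans a DNA sequence with 200-bp windows at 1-bp steps and merges
#' qualifying windows into maximal islands. A window qualifies when its
#' GC fraction exceeds 0.5 and its observed/expected CpG ratio is at least
#' 0.6, with expected CpG = (#C x #G) / window length. N bases are excluded
#' from the C, G and CpG counts and from the GC-fraction denominator.
#'
#' @param sequence DNA as a character string or Biostrings::DNAString
#'   (uppercase A/C/G/T/N).
#' @param minLength window/island length floor (default 200).
#' @param minGc GC-fraction threshold, strict (default 0.5).
#' @param minObsExp observed/expected CpG threshold (default 0.6).
#' @return IRanges of maximal islands (1-based, in sequence coordinates).
#' @export
detectCgi <- function(sequence, minLength = 200L, minGc = 0.5, minObsExp = 0.6) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  L <- length(s)
  if (L < minLength) return(IRanges())
  isC <- as.integer(s == "C"); isG <- as.integer(s == "G")
  isN <- as.integer(s == "N")
  isCpG <- as.integer(s[-L] == "C" & s[-1] == "G")
  cumC <- c(0L, cumsum(isC)); cumG <- c(0L, cumsum(isG))
  cumN <- c(0L, cumsum(isN)); cumCpG <- c(0L, cumsum(isCpG))
  starts <- seq_len(L - minLength + 1L)
  ends <- starts + minLength - 1L
  nC <- cumC[ends + 1L] - cumC[starts]
  nG <- cumG[ends + 1L] - cumG[starts]
  nN <- cumN[ends + 1L] - cumN[starts]
  # CpG dinucleotide starts falling inside the window
  nCpG <- cumCpG[ends] - cumCpG[starts]
  denom <- minLength - nN
  gcFrac <- ifelse(denom > 0, (nC + nG) / denom, 0)
  expected <- nC * nG / minLength
  obsExp <- ifelse(expected > 0, nCpG / expected, 0)
  ok <- gcFrac > minGc & obsExp >= minObsExp
  if (!any(ok)) return(IRanges())
  reduce(IRanges(starts[ok], ends[ok]))
}

#' Does an element fall in a CpG island?
#'
#' @param element IRanges or GRanges of length 1 (sequence coordinates must
#'   match those of \code{islands}).
#' @param islands IRanges from [detectCgi()].
#' @return list with \code{inCgi} (any overlap) and \code{fraction} of the
#'   element's bases covered by islands.
#' @export
elementInCgi <- function(element, islands) {
  if (is(element, "GRanges")) element <- IRanges(start(element), end(element))
  stopifnot(length(element) == 1L)
  if (!length(islands)) return(list(inCgi = FALSE, fraction = 0))
  ov <- IRanges::intersect(element, reduce(islands))
  covered <- sum(width(ov))
  list(inCgi = covered > 0L, fraction = covered / width(element))
}
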