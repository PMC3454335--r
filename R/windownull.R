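#' @include AllClasses.R stats.R
NULL

#' Concatenate exonic per-base scores of a gene
#'
#' Extracts the per-base scores of every exon from a score track and
#' concatenates them in transcript (5' to 3') order — the "expressed region"
#' axis along which the sliding-window null is built. For minus-strand genes
#' the per-exon score vectors are reversed so the axis runs with the
#' transcript. A coordinate map recovers the genomic position (1-based) of
#' every concatenated index.
#'
#' @param gene a [GeneModel-class].
#' @param track a [ScoreTrack-class] covering all exonic bases.
#' @return list with \code{scores} (numeric vector, length = exonic length)
#'   and \code{genomicPos} (parallel integer vector of genomic positions).
#' @export
concatExonicTrack <- function(gene, track) {
  minus <- as.character(strand(exons(gene)))[1] == "-"
  iv <- trackIntervals(track)
  vals <- trackValues(track)
  scores <- numeric(0)
  pos <- integer(0)
  for (j in seq_along(exons(gene))) {
    ex <- exons(gene)[j]
    hits <- findOverlaps(ex, iv, ignore.strand = TRUE)
    exPos <- start(ex):end(ex)
    exScore <- rep(NA_real_, length(exPos))
    for (h in subjectHits(hits)) {
      lo <- max(start(ex), start(iv)[h]); hi <- min(end(ex), end(iv)[h])
      exScore[(lo:hi) - start(ex) + 1L] <-
        vals[[h]][(lo:hi) - start(iv)[h] + 1L]
    }
    if (anyNA(exScore)) {
      stop("score track does not cover all bases of exon ", j,
           " of gene ", geneID(gene))
    }
    if (minus) { exScore <- rev(exScore); exPos <- rev(exPos) }
    scores <- c(scores, exScore)
    pos <- c(pos, exPos)
  }
  list(scores = scores, genomicPos = pos)
}

#' Sliding-window means
#'
#' Means of every length-\code{L} window of a score vector, shifted in
#' single-base increments: output length is \code{T - L + 1}.
#'
#' @param scores numeric vector (length T).
#' @param L window length, \code{L <= T}.
#' @return numeric vector of window means.
#' @export
windowScores <- function(scores, L) {
  T <- length(scores)
  if (L < 1L || L > T) stop("window length must satisfy 1 <= L <= length(scores)")
  cs <- c(0, cumsum(scores))
  (cs[(L + 1L):(T + 1L)] - cs[seq_len(T - L + 1L)]) / L
}

#' Test an element's scores against its host-gene null
#'
#' Compares a regulatory element's per-base scores with the rest of its host
#' gene's exonic track. In the default \code{window_rank} mode the element's
#' own window mean is ranked within the empirical null of ALL window means of
#' length L along the concatenated exonic axis (the element's window
#' included, so p >= 1/n_windows); the two-sided p is the doubled smaller
#' tail fraction, capped at 1. In \code{basewise_ranksum} mode a Wilcoxon
#' rank-sum test compares the element's per-base scores with all other exonic
#' bases.
#'
#' @param elementStart 1-based start of the element on the concatenated axis.
#' @param L element length in bases.
#' @param scores concatenated exonic score vector ([concatExonicTrack()]).
#' @param mode "window_rank" (default) or "basewise_ranksum".
#' @param excludeOverlapping in window_rank mode, drop windows overlapping
#'   the element from the null (default FALSE: they are kept).
#' @return list: element_score (element mean), n_windows, p_value, direction
#'   ("higher"/"lower"), mode, and null_scores (window-mean vector; NULL in
#'   basewise mode).
#' @export
elementVsHostTest <- function(elementStart, L, scores,
                              mode = c("window_rank", "basewise_ranksum"),
                              excludeOverlapping = FALSE) {
  mode <- match.arg(mode)
  T <- length(scores)
  if (elementStart < 1L || elementStart + L - 1L > T) {
    stop("element does not lie within the concatenated exonic axis")
  }
  idx <- elementStart:(elementStart + L - 1L)
  if (anyNA(scores[idx])) stop("element overlaps track gaps")
  elementMean <- mean(scores[idx])
  restMean <- if (T > L) mean(scores[-idx]) else elementMean
  direction <- if (elementMean >= restMean) "higher" else "lower"
  if (mode == "window_rank") {
    wm <- windowScores(scores, L)
    # rank the element's own entry of the window-mean vector: comparing a
    # separately computed mean() against cumsum-based window means loses the
    # tie with itself to roundoff
    em <- wm[elementStart]
    nullScores <- wm
    if (excludeOverlapping) {
      keep <- abs(seq_along(wm) - elementStart) >= L
      nullScores <- c(em, wm[keep])
    }
    pUp <- mean(nullScores >= em)
    pLo <- mean(nullScores <= em)
    p <- min(1, 2 * min(pUp, pLo))
    list(
      element_score = elementMean, n_windows = length(wm),
      p_value = p, direction = direction, mode = mode,
      null_scores = wm
    )
  } else {
    tr <- wilcoxonRankSum(scores[idx], scores[-idx])
    list(
      element_score = elementMean, n_windows = T - L + 1L,
      p_value = pValue(tr), direction = direction, mode = mode,
      null_scores = NULL
    )
  }
}

#' Per-base GC indicator track
#'
#' G or C bases map to 1, A or T to 0, N to NA (masked). Feeding this vector
#' through the sliding-window machinery turns the conservation test into the
#' GC-content test: a window mean is the window's GC fraction.
#'
#' @param sequence DNA character string or DNAString.
#' @return numeric vector of 0/1/NA, one per base.
#' @export
gcIndicatorTrack <- function(sequence) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  out <- rep(NA_real_, length(s))
  out[s %in% c("G", "C")] <- 1
  out[s %in% c("A", "T")] <- 0
  out
}

#' Classify an element's conservation category
#'
#' Bins the element's mean per-base conservation score: above 0.5 the element
#' is strongly conserved across vertebrates, above 0.1 somewhat conserved,
#' at or below 0.1 not conserved.
#'
#' @param meanScore element mean per-base conservation score in [0, 1].
#' @return "strongly", "somewhat" or "not_conserved".
#' @export
classifyConservation <- function(meanScore) {
  stopifnot(is.finite(meanScore))
  if (meanScore > 0.5) "strongly"
  else if (meanScore > 0.1) "somewhat"
  else "not_conserved"
}

#' Batch element-vs-host tests with FDR control
#'
#' Runs [elementVsHostTest()] for a panel of elements (each with its host
#' gene and score track) and pools the p-values into one Benjamini-Hochberg
#' correction across the element set.
#'
#' @param panel list of entries, each a list with components \code{element}
#'   (GRanges of length 1, genomic coordinates), \code{gene}
#'   ([GeneModel-class]) and \code{track} ([ScoreTrack-class]); optionally
#'   \code{id}.
#' @param mode passed to [elementVsHostTest()].
#' @param excludeOverlapping passed to [elementVsHostTest()].
#' @return data.frame: element_id, element_score, conservation (category),
#'   n_windows, direction, p_value, q_value.
#' @export
batchElementTests <- function(panel, mode = "window_rank",
                              excludeOverlapping = FALSE) {
  rows <- lapply(seq_along(panel), function(i) {
    entry <- panel[[i]]
    ct <- concatExonicTrack(entry$gene, entry$track)
    onAxis <- which(ct$genomicPos %in% start(entry$element):end(entry$element))
    if (length(onAxis) != width(entry$element) ||
        any(diff(sort(onAxis)) != 1L)) {
      stop("element ", i, " is not a contiguous exonic interval of its host gene")
    }
    res <- elementVsHostTest(
      min(onAxis), length(onAxis), ct$scores,
      mode = mode, excludeOverlapping = excludeOverlapping
    )
    data.frame(
      element_id = if (!is.null(entry$id)) entry$id else sprintf("element%d", i),
      element_score = res$element_score,
      conservation = classifyConservation(res$element_score),
      n_windows = res$n_windows,
      direction = res$direction,
      p_value = res$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhFdr(out$p_value)
  out
}
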