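#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom IRanges IRanges NumericList
NULL

.EXON_TYPES <- c("CDS", "UTR5", "UTR3", "noncoding_exon")
.ENZYMES <- c("Sau3AI", "AluI", "control")
.WELL_ROLES <- c("experimental", "promoter_only", "no_promoter", "positive_enhancer")

#' TestResult: container for a single statistical test
#'
#' Holds the statistic, degrees of freedom (when defined), two-sided p-value,
#' the effective sample size used and a method label, in the shape shared by
#' every test the pipeline runs (t, F, W, rank-sum, correlation). Degenerate
#' inputs (for example zero-variance replicates) yield a result whose
#' \code{note} says why no p-value was emitted, instead of an error deep in a
#' pipeline run.
#'
#' @slot statistic numeric(1), the test statistic (NA when undefined).
#' @slot df numeric(1), degrees of freedom; NA for rank-based tests.
#' @slot pValue numeric(1) in [0, 1], two-sided; NA when flagged.
#' @slot nEffective integer(1), observations actually used (e.g. nonzero
#'   paired differences in the signed-rank test).
#' @slot method character(1) label.
#' @slot note character(1), "" or the reason the test is degenerate.
#'
#' @exportClass TestResult
setClass("TestResult",
  representation(
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    nEffective = "integer",
    method = "character",
    note = "character"
  ),
  prototype(
    statistic = NA_real_, df = NA_real_, pValue = NA_real_,
    nEffective = NA_integer_, method = "", note = ""
  )
)

setValidity("TestResult", function(object) {
  msg <- character()
  p <- object@pValue
  if (length(p) != 1L) msg <- c(msg, "pValue must have length 1")
  if (length(p) == 1L && !is.na(p) && (p < 0 || p > 1)) {
    msg <- c(msg, "pValue must lie in [0, 1]")
  }
  if (length(object@df) == 1L && !is.na(object@df) && object@df < 1) {
    msg <- c(msg, "df must be >= 1 when present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TestResult
#'
#' @param statistic,df,pValue,nEffective,method,note see the class slots.
#' @return A [TestResult-class] object.
#' @export
TestResult <- function(statistic = NA_real_, df = NA_real_, pValue = NA_real_,
                       nEffective = NA_integer_, method = "", note = "") {
  new("TestResult",
    statistic = as.numeric(statistic), df = as.numeric(df),
    pValue = as.numeric(pValue), nEffective = as.integer(nEffective),
    method = as.character(method), note = as.character(note)
  )
}

#' GeneModel: exon structure of one gene
#'
#' Exon intervals of a single gene, each typed as coding sequence (CDS),
#' 5' UTR, 3' UTR or non-coding exon, held as a \linkS4class{GRanges} with an
#' \code{exon_type} metadata column. Exons are stored sorted in transcript
#' (5' to 3') orientation: ascending genomic coordinates on the plus strand,
#' descending on the minus strand. All coordinates follow the 0-based
#' half-open convention used throughout the package (GRanges starts are
#' therefore the 0-based offset + 1 internally; constructors and readers do
#' the conversion once, at the boundary).
#'
#' @slot geneID character(1) identifier.
#' @slot exons GRanges with mcols()$exon_type in
#'   \code{c("CDS","UTR5","UTR3","noncoding_exon")}.
#' @slot cdsFrameOffset integer(1) in 0..2, offset of the first complete codon
#'   from the CDS 5' end.
#'
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneID = "character",
    exons = "GRanges",
    cdsFrameOffset = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (is.null(mcols(ex)$exon_type)) {
    return("exons must carry an 'exon_type' metadata column")
  }
  if (!all(mcols(ex)$exon_type %in% .EXON_TYPES)) {
    msg <- c(msg, sprintf(
      "exon_type values must be one of: %s",
      paste(.EXON_TYPES, collapse = ", ")
    ))
  }
  st <- unique(as.character(strand(ex)))
  if (length(ex) && (length(st) != 1L || !st %in% c("+", "-"))) {
    msg <- c(msg, "all exons must share one strand, '+' or '-'")
  }
  if (length(ex) > 1L) {
    o <- order(start(ex))
    if (any(start(ex)[o][-1] <= end(ex)[o][-length(ex)])) {
      msg <- c(msg, "exons must not overlap")
    }
    s <- start(ex)
    sorted5to3 <- if (st == "+") !is.unsorted(s, strictly = TRUE)
                  else !is.unsorted(rev(s), strictly = TRUE)
    if (!sorted5to3) {
      msg <- c(msg, "exons must be sorted 5'->3' in transcript orientation")
    }
  }
  if (length(object@cdsFrameOffset) != 1L ||
      !object@cdsFrameOffset %in% 0:2) {
    msg <- c(msg, "cdsFrameOffset must be a single value in 0..2")
  }
  cdsLen <- sum(width(ex)[mcols(ex)$exon_type == "CDS"])
  if (cdsLen > 0 && identical(object@cdsFrameOffset, 0L) && cdsLen %% 3L != 0L) {
    msg <- c(msg, "total CDS length must be divisible by 3 when the frame offset is 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneID gene identifier.
#' @param exons GRanges in transcript order with an \code{exon_type} metadata
#'   column (values \code{"CDS"}, \code{"UTR5"}, \code{"UTR3"},
#'   \code{"noncoding_exon"}).
#' @param cdsFrameOffset integer in 0..2 (default 0).
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(geneID, exons, cdsFrameOffset = 0L) {
  new("GeneModel",
    geneID = as.character(geneID), exons = exons,
    cdsFrameOffset = as.integer(cdsFrameOffset)
  )
}

#' ScoreTrack: per-base scores over genomic intervals
#'
#' A per-base score track (conservation probabilities, GC indicators, ...)
#' over a set of genomic intervals: one numeric value per covered base.
#' Intervals must be disjoint so every base has a unique value.
#'
#' @slot intervals GRanges of covered intervals.
#' @slot values NumericList, parallel to \code{intervals}; element i has
#'   \code{width(intervals)[i]} values.
#'
#' @exportClass ScoreTrack
setClass("ScoreTrack",
  representation(intervals = "GRanges", values = "NumericList")
)

setValidity("ScoreTrack", function(object) {
  msg <- character()
  if (length(object@intervals) != length(object@values)) {
    msg <- c(msg, "intervals and values must be parallel")
  } else if (!all(lengths(object@values) == width(object@intervals))) {
    msg <- c(msg, "each interval needs exactly one value per base")
  }
  if (length(object@intervals) > 1L) {
    red <- GenomicRanges::reduce(object@intervals, ignore.strand = TRUE)
    if (sum(width(red)) != sum(width(object@intervals))) {
      msg <- c(msg, "intervals must be disjoint (ambiguous base values)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreTrack
#'
#' @param intervals GRanges of covered intervals.
#' @param values NumericList (or plain list) of per-base scores, parallel to
#'   \code{intervals}.
#' @return A [ScoreTrack-class] object.
#' @export
ScoreTrack <- function(intervals, values) {
  if (!is(values, "NumericList")) values <- NumericList(values)
  new("ScoreTrack", intervals = intervals, values = values)
}

#' FactorialExpressionSet: expression matrix with genotype/treatment factors
#'
#' A \linkS4class{SummarizedExperiment} whose column data carry the factors of
#' a transcription-factor perturbation design: \code{genotype} (two levels,
#' e.g. wild-type vs null or dominant-negative) and optionally
#' \code{treatment} (two levels, e.g. vehicle vs agonist, or fed vs fasting).
#' Expression values are assumed already log-scale.
#'
#' @exportClass FactorialExpressionSet
setClass("FactorialExpressionSet", contains = "SummarizedExperiment")

setValidity("FactorialExpressionSet", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"genotype" %in% colnames(cd)) {
    return("colData must contain a 'genotype' column")
  }
  if (length(unique(cd$genotype)) != 2L) {
    msg <- c(msg, "genotype must have exactly two levels")
  }
  if ("treatment" %in% colnames(cd) &&
      length(unique(cd$treatment)) != 2L) {
    msg <- c(msg, "treatment, when present, must have exactly two levels")
  }
  if (any(is.na(cd$genotype))) msg <- c(msg, "genotype labels must be complete")
  if ("treatment" %in% colnames(cd) && any(is.na(cd$treatment))) {
    msg <- c(msg, "treatment labels must be complete")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FactorialExpressionSet
#'
#' @param exprs numeric matrix, genes x samples, log-scale expression.
#' @param genotype character/factor of length ncol(exprs), two levels.
#' @param treatment optional character/factor of length ncol(exprs), two
#'   levels; omit for one-factor (two-group) designs.
#' @return A [FactorialExpressionSet-class].
#' @export
FactorialExpressionSet <- function(exprs, genotype, treatment = NULL) {
  exprs <- as.matrix(exprs)
  cd <- DataFrame(genotype = as.character(genotype))
  if (!is.null(treatment)) cd$treatment <- as.character(treatment)
  rownames(cd) <- colnames(exprs)
  new("FactorialExpressionSet",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = exprs), colData = cd
    )
  )
}
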