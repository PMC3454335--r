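#' @include AllClasses.R
NULL

#' @rdname TestResult-class
#' @param object a TestResult, GeneModel or ScoreTrack.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname TestResult-class
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname TestResult-class
#' @export
setGeneric("degreesOfFreedom", function(object) standardGeneric("degreesOfFreedom"))

#' @rdname TestResult-class
#' @export
setGeneric("nEffective", function(object) standardGeneric("nEffective"))

#' @rdname TestResult-class
#' @export
setGeneric("testNote", function(object) standardGeneric("testNote"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneID", function(object) standardGeneric("geneID"))

#' @rdname GeneModel-class
#' @export
setGeneric("exons", function(object) standardGeneric("exons"))

#' @rdname GeneModel-class
#' @export
setGeneric("exonicLength", function(object) standardGeneric("exonicLength"))

#' @rdname GeneModel-class
#' @export
setGeneric("cdsLength", function(object) standardGeneric("cdsLength"))

#' @rdname ScoreTrack-class
#' @export
setGeneric("trackIntervals", function(object) standardGeneric("trackIntervals"))

#' @rdname ScoreTrack-class
#' @export
setGeneric("trackValues", function(object) standardGeneric("trackValues"))

setMethod("pValue", "TestResult", function(object) object@pValue)
setMethod("testStatistic", "TestResult", function(object) object@statistic)
setMethod("degreesOfFreedom", "TestResult", function(object) object@df)
setMethod("nEffective", "TestResult", function(object) object@nEffective)
setMethod("testNote", "TestResult", function(object) object@note)

setMethod("geneID", "GeneModel", function(object) object@geneID)
setMethod("exons", "GeneModel", function(object) object@exons)
setMethod("exonicLength", "GeneModel", function(object) sum(width(object@exons)))
setMethod("cdsLength", "GeneModel", function(object) {
  sum(width(object@exons)[mcols(object@exons)$exon_type == "CDS"])
})

setMethod("trackIntervals", "ScoreTrack", function(object) object@intervals)
setMethod("trackValues", "ScoreTrack", function(object) object@values)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n", object@method))
  cat(sprintf(
    "  statistic = %s, df = %s, p = %s, n = %s\n",
    format(object@statistic, digits = 5),
    ifelse(is.na(object@df), "-", format(object@df)),
    ifelse(is.na(object@pValue), "-", format(object@pValue, digits = 4)),
    ifelse(is.na(object@nEffective), "-", object@nEffective)
  ))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "GeneModel", function(object) {
  tab <- table(mcols(object@exons)$exon_type)
  cat(sprintf(
    "GeneModel '%s' (%s strand): %d exons [%s], exonic length %d bp\n",
    object@geneID,
    if (length(object@exons)) as.character(strand(object@exons))[1] else ".",
    length(object@exons),
    paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ", "),
    exonicLength(object)
  ))
})

setMethod("show", "ScoreTrack", function(object) {
  v <- unlist(object@values)
  cat(sprintf(
    "ScoreTrack: %d intervals, %d bases, score range [%s, %s]\n",
    length(object@intervals), sum(width(object@intervals)),
    format(suppressWarnings(min(v)), digits = 4),
    format(suppressWarnings(max(v)), digits = 4)
  ))
})

#' Convert a TestResult to a one-row data.frame
#'
#' @param x a TestResult.
#' @param row.names,optional,... passed through for the as.data.frame generic.
#' @return data.frame with columns statistic, df, p_value, n_effective,
#'   method, note.
#' @export
as.data.frame.TestResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    statistic = x@statistic, df = x@df, p_value = x@pValue,
    n_effective = x@nEffective, method = x@method, note = x@note,
    stringsAsFactors = FALSE
  )
}
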