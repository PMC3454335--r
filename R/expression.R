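#' @include AllClasses.R stats.R
#' @importFrom SummarizedExperiment assay colData
NULL

.geneValues <- function(fes, gene) {
  m <- assay(fes, "exprs")
  if (!gene %in% rownames(m)) stop("gene '", gene, "' not found in expression set")
  m[gene, ]
}

#' Factorial ANOVA validation of a gene's cis-regulation
#'
#' Two-way (genotype x treatment) ANOVA on one gene's expression values, with
#' post-hoc pooled-variance t-tests of treated vs untreated replicates within
#' each genotype. The hallmark of cis-regulation through the perturbed
#' transcription factor is a treatment effect confined to the wild-type
#' genotype: a significant post-hoc test in wild-type and a non-significant
#' one in the null genotype. Post-hoc orientation is (untreated - treated),
#' so repression by the treatment gives a positive t.
#'
#' @param fes a [FactorialExpressionSet-class] with genotype and treatment.
#' @param gene gene identifier (row name).
#' @param treatedLevel which treatment level is "treated". By default the
#'   level that is not a recognized baseline label (vehicle, control,
#'   untreated, none, fed, baseline); if neither level is recognized, the
#'   second sorted level.
#' @return list: \code{anova} (list of [TestResult-class]: genotype,
#'   treatment, interaction) and \code{postHoc} (named list of
#'   [TestResult-class], one per genotype level).
#' @export
factorialAnalysis <- function(fes, gene, treatedLevel = NULL) {
  cd <- colData(fes)
  if (!"treatment" %in% colnames(cd)) {
    stop("factorial analysis needs a 'treatment' factor; see twoGroupAnalysis")
  }
  v <- .geneValues(fes, gene)
  a <- anova2x2(v, cd$genotype, cd$treatment)
  tLevels <- sort(unique(cd$treatment))
  if (is.null(treatedLevel)) {
    baselines <- c("vehicle", "control", "untreated", "none", "fed", "baseline")
    isBase <- tolower(tLevels) %in% baselines
    treatedLevel <- if (sum(isBase) == 1L) tLevels[!isBase] else tLevels[2]
  }
  if (!treatedLevel %in% tLevels) stop("unknown treatment level '", treatedLevel, "'")
  untreatedLevel <- setdiff(tLevels, treatedLevel)
  postHoc <- lapply(sort(unique(cd$genotype)), function(g) {
    twoSampleT(
      v[cd$genotype == g & cd$treatment == untreatedLevel],
      v[cd$genotype == g & cd$treatment == treatedLevel]
    )
  })
  names(postHoc) <- sort(unique(cd$genotype))
  list(
    anova = list(genotype = a$A, treatment = a$B, interaction = a$AB),
    postHoc = postHoc
  )
}

#' Two-group comparison of a gene's expression
#'
#' Pooled-variance t-test between the two genotype groups (df = n1 + n2 - 2),
#' for one-factor designs such as wild-type vs dominant-negative.
#' Orientation is (first sorted genotype level - second).
#'
#' @param fes a [FactorialExpressionSet-class].
#' @param gene gene identifier.
#' @return A [TestResult-class].
#' @export
twoGroupAnalysis <- function(fes, gene) {
  cd <- colData(fes)
  v <- .geneValues(fes, gene)
  g <- sort(unique(cd$genotype))
  twoSampleT(v[cd$genotype == g[1]], v[cd$genotype == g[2]])
}

#' Specificity check against a negative-control gene
#'
#' Runs the same analysis on the target gene and a negative-control gene
#' (e.g. a related housekeeping gene with no known binding site for the
#' perturbed factor) and flags the effect as "specific" when the target is
#' significant and the control is not, at level \code{alpha}. Significance of
#' a factorial analysis is taken as the smallest of the three ANOVA effect
#' p-values.
#'
#' @param fes a [FactorialExpressionSet-class].
#' @param targetGene,controlGene gene identifiers.
#' @param alpha significance level (default 0.05).
#' @return list: \code{target}, \code{control} (analysis results),
#'   \code{specific} (logical).
#' @export
controlGeneCheck <- function(fes, targetGene, controlGene, alpha = 0.05) {
  cd <- colData(fes)
  factorial <- "treatment" %in% colnames(cd)
  analyse <- function(gene) {
    if (factorial) factorialAnalysis(fes, gene) else twoGroupAnalysis(fes, gene)
  }
  minP <- function(res) {
    if (factorial) min(vapply(res$anova, pValue, 1)) else pValue(res)
  }
  target <- analyse(targetGene)
  control <- analyse(controlGene)
  list(
    target = target, control = control,
    specific = isTRUE(minP(target) < alpha) && !isTRUE(minP(control) < alpha)
  )
}

#' Parse a GEO series-matrix file
#'
#' Reads an (uncompressed or gzipped) GEO series-matrix text file: sample
#' metadata from the \code{!Sample_*} header lines and the expression matrix
#' between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end}. No network access; the file must already
#' be on disk.
#'
#' @param path series-matrix file path.
#' @return list with \code{exprs} (numeric matrix, probes x samples) and
#'   \code{samples} (data.frame of the Sample_ header fields).
#' @export
readGeoSeriesMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^!Sample_", lines, value = TRUE)
  meta <- lapply(hdr, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    gsub("^\"|\"$", "", parts[-1])
  })
  names(meta) <- sub("^!", "", vapply(
    hdr, function(l) strsplit(l, "\t")[[1]][1], ""
  ))
  names(meta) <- make.unique(names(meta))
  begin <- grep("^!series_matrix_table_begin", lines)
  finish <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(finish) != 1L) {
    stop("series-matrix table markers not found")
  }
  tab <- read.delim(
    textConnection(lines[(begin + 1L):(finish - 1L)]),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- gsub("^\"|\"$", "", tab[[1]])
  colnames(m) <- gsub("^\"|\"$", "", colnames(m))
  samples <- as.data.frame(meta, stringsAsFactors = FALSE, check.names = FALSE)
  list(exprs = m, samples = samples)
}

#' Pick one probe per gene by highest mean expression
#'
#' Microarray platforms carry several probes per gene; when collapsing to
#' gene level this helper keeps, for each gene symbol, the probe with the
#' highest mean expression across samples.
#'
#' @param exprs probes x samples numeric matrix.
#' @param probeGenes character vector of gene symbols parallel to
#'   \code{rownames(exprs)}.
#' @return genes x samples matrix.
#' @export
collapseProbes <- function(exprs, probeGenes) {
  stopifnot(length(probeGenes) == nrow(exprs))
  keep <- !is.na(probeGenes) & nzchar(probeGenes)
  exprs <- exprs[keep, , drop = FALSE]
  probeGenes <- probeGenes[keep]
  means <- rowMeans(exprs)
  best <- tapply(seq_along(means), probeGenes, function(i) i[which.max(means[i])])
  out <- exprs[unlist(best), , drop = FALSE]
  rownames(out) <- names(best)
  out
}
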