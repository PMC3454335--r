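#' @include AllClasses.R stats.R
NULL

#' Relative reporter activity
#'
#' The log10 ratio of firefly (experimental) to Renilla (transfection-control)
#' luciferase signal — the activity measure of the whole screen.
#'
#' @param firefly,renilla positive signal vectors.
#' @return log10(firefly / renilla).
#' @examples
#' relativeActivity(1000, 100) # 1
#' @export
relativeActivity <- function(firefly, renilla) {
  if (any(!is.finite(firefly)) || any(!is.finite(renilla)) ||
      any(firefly <= 0) || any(renilla <= 0)) {
    stop("relative activity requires strictly positive firefly and renilla signals")
  }
  log10(firefly / renilla)
}

#' Compute activity records from a plate table
#'
#' Converts usable wells of a plate table into activity records (clone, batch,
#' enzyme, role, relative activity). Unusable wells are dropped here, after
#' having been flagged by the reader.
#'
#' @param plate plate table from [readPlateTable()] or [simulateScreen()].
#' @return data.frame with columns clone_id, batch_id, enzyme, well_role,
#'   activity.
#' @export
activityRecords <- function(plate) {
  usable <- if ("usable" %in% colnames(plate)) plate$usable else
    plate$renilla > 0 & plate$firefly > 0
  p <- plate[usable, , drop = FALSE]
  data.frame(
    clone_id = p$clone_id, batch_id = p$batch_id, enzyme = p$enzyme,
    well_role = p$well_role,
    activity = relativeActivity(p$firefly, p$renilla),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Quantile-normalize screen activities across plates
#'
#' Applies quantile normalization across plates (batches) separately within
#' each restriction-enzyme group, since the two digest libraries have
#' different activity distributions. The normalization reference is learned
#' from experimental wells only; control wells are mapped through it (their
#' value is replaced by the reference quantile at their position in the
#' plate's experimental-well distribution), so a handful of extreme controls
#' cannot distort the reference. An enzyme group with a single plate is
#' passed through unchanged with a warning.
#'
#' @param records activity records from [activityRecords()].
#' @return \code{records} with an added \code{normalized_activity} column.
#' @export
normalizeScreen <- function(records) {
  records$normalized_activity <- NA_real_
  for (enz in unique(records$enzyme[records$well_role == "experimental"])) {
    expIdx <- which(records$enzyme == enz & records$well_role == "experimental")
    # control wells belong to an enzyme group through their plate
    ctlIdx <- which(records$well_role != "experimental" &
                      records$batch_id %in% unique(records$batch_id[expIdx]))
    batches <- split(expIdx, records$batch_id[expIdx])
    if (length(batches) < 2L) {
      warning("enzyme group '", enz, "' has a single plate; passing activities through")
      records$normalized_activity[c(expIdx, ctlIdx)] <-
        records$activity[c(expIdx, ctlIdx)]
      next
    }
    ref <- .quantileReference(lapply(batches, function(i) records$activity[i]))
    for (b in names(batches)) {
      i <- batches[[b]]
      records$normalized_activity[i] <- .mapThroughReference(records$activity[i], ref)
      j <- ctlIdx[records$batch_id[ctlIdx] == b]
      if (length(j)) {
        records$normalized_activity[j] <- .mapValuesViaEcdf(
          records$activity[j], records$activity[i], ref
        )
      }
    }
  }
  leftover <- is.na(records$normalized_activity)
  records$normalized_activity[leftover] <- records$activity[leftover]
  records
}

#' Select screen candidates beyond two standard deviations
#'
#' Flags experimental clones whose normalized activity lies more than
#' \code{k} sample standard deviations from the mean, both tails, with mean
#' and sd computed over experimental clones within each enzyme group
#' (controls excluded).
#'
#' @param records normalized activity records ([normalizeScreen()]).
#' @param k threshold in standard deviations (default 2).
#' @return character vector of selected clone ids.
#' @export
selectCandidates <- function(records, k = 2) {
  exp <- records[records$well_role == "experimental", , drop = FALSE]
  if (nrow(exp) < 3L) stop("need at least 3 experimental clones")
  selected <- character()
  for (enz in unique(exp$enzyme)) {
    a <- exp$normalized_activity[exp$enzyme == enz]
    ids <- exp$clone_id[exp$enzyme == enz]
    s <- sd(a)
    if (s == 0) {
      warning("zero activity spread in enzyme group '", enz, "'; nothing selected")
      next
    }
    selected <- c(selected, ids[abs(a - mean(a)) > k * s])
  }
  unique(selected)
}

#' Confirm candidates over two replicate rounds
#'
#' Each candidate is retested in two rounds (three then eight replicate
#' assays). Per round, a one-sample t-test compares the replicates with the
#' promoter-only control reference; Benjamini-Hochberg q-values are computed
#' across candidates within each round. A clone is confirmed only if it
#' passes \code{q < alpha} in BOTH rounds with the same direction of effect.
#'
#' @param round1,round2 named lists (by clone id) of replicate activity
#'   vectors, n = 3 and n = 8 respectively (other sizes allowed).
#' @param controlReference mean normalized activity of promoter-only wells.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame (one row per candidate): round statistics, q-values,
#'   mean activities and the final \code{call} in
#'   \{enhancer, silencer, not_confirmed\}.
#' @export
confirmRounds <- function(round1, round2, controlReference, alpha = 0.05) {
  ids <- intersect(names(round1), names(round2))
  if (!length(ids)) stop("no candidates shared between rounds")
  testRound <- function(reps) {
    lapply(reps, function(x) {
      if (length(x) < 2L || sd(x[is.finite(x)]) == 0) {
        TestResult(nEffective = length(x), method = "One-sample t-test",
                   note = "degenerate replicates")
      } else {
        oneSampleT(x, mu0 = controlReference)
      }
    })
  }
  t1 <- testRound(round1[ids]); t2 <- testRound(round2[ids])
  p1 <- vapply(t1, pValue, 1); p2 <- vapply(t2, pValue, 1)
  q1 <- bhFdr(p1); q2 <- bhFdr(p2)
  m1 <- vapply(round1[ids], mean, 1); m2 <- vapply(round2[ids], mean, 1)
  pass <- !is.na(q1) & !is.na(q2) & q1 < alpha & q2 < alpha &
    sign(m1 - controlReference) == sign(m2 - controlReference)
  call <- ifelse(
    pass,
    vapply(m2, classifyCall, "", controlReference = controlReference),
    "not_confirmed"
  )
  data.frame(
    clone_id = ids,
    t_round1 = vapply(t1, testStatistic, 1), p_round1 = p1, q_round1 = q1,
    t_round2 = vapply(t2, testStatistic, 1), p_round2 = p2, q_round2 = q2,
    mean_round1 = m1, mean_round2 = m2,
    call = call,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify a confirmed call as enhancer or silencer
#'
#' @param meanActivity confirmed clone's mean activity.
#' @param controlReference promoter-only reference activity.
#' @return "enhancer" if above the reference, "silencer" if below.
#' @export
classifyCall <- function(meanActivity, controlReference) {
  if (meanActivity > controlReference) "enhancer" else "silencer"
}

#' Run the full reporter screen workflow
#'
#' Composition of the screening stages: relative activities, per-enzyme
#' quantile normalization across plates, two-standard-deviation candidate
#' selection, optional exonic filtering of candidates (when alignments and
#' gene models are supplied), and two FDR-gated confirmation rounds against
#' the promoter-only reference. Stage counts telescope: each stage retains a
#' subset of the previous one.
#'
#' @param plates plate table (initial screen wells).
#' @param round1,round2 named lists of replicate activity vectors covering at
#'   least the selected candidates.
#' @param alignments optional alignment table for exonic filtering (see
#'   [filterExonicClones()]).
#' @param genes optional list of [GeneModel-class] (with \code{alignments}).
#' @param k selection threshold in SD units (default 2).
#' @param alpha per-round FDR threshold (default 0.05).
#' @return list with \code{calls} (confirmation table), \code{records}
#'   (normalized activities), \code{controlReference} and \code{report}
#'   (stage counts: screened, selected, exon_retained, round1_pass,
#'   confirmed).
#' @export
runScreen <- function(plates, round1, round2, alignments = NULL, genes = NULL,
                      k = 2, alpha = 0.05) {
  records <- normalizeScreen(activityRecords(plates))
  candidates <- selectCandidates(records, k = k)
  retained <- candidates
  if (!is.null(alignments) && !is.null(genes)) {
    fx <- filterExonicClones(alignments, genes)
    retained <- intersect(candidates, fx$clone_id[fx$retained])
  }
  ctl <- records$normalized_activity[records$well_role == "promoter_only"]
  if (!length(ctl)) stop("no promoter-only wells: control reference undefined")
  controlReference <- mean(ctl)
  retained <- intersect(retained, intersect(names(round1), names(round2)))
  if (length(retained)) {
    calls <- confirmRounds(
      round1[retained], round2[retained], controlReference, alpha = alpha
    )
  } else {
    calls <- data.frame(
      clone_id = character(), t_round1 = numeric(), p_round1 = numeric(),
      q_round1 = numeric(), t_round2 = numeric(), p_round2 = numeric(),
      q_round2 = numeric(), mean_round1 = numeric(), mean_round2 = numeric(),
      call = character(), stringsAsFactors = FALSE
    )
  }
  round1Pass <- sum(!is.na(calls$q_round1) & calls$q_round1 < alpha)
  report <- c(
    screened = length(unique(
      records$clone_id[records$well_role == "experimental"]
    )),
    selected = length(candidates),
    exon_retained = length(retained),
    round1_pass = round1Pass,
    confirmed = sum(calls$call != "not_confirmed")
  )
  list(
    calls = calls, records = records,
    controlReference = controlReference, report = report
  )
}
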