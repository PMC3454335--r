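#' @include AllClasses.R io.R
#' @importFrom stats rlnorm
#' @importFrom utils head
NULL

# Skew-normal sampler (Azzalini construction): delta|Z0| + sqrt(1-delta^2) Z1,
# recentred so the returned values have mean `location` and sd `scale`.
.rSkewNormal <- function(n, location = 0, scale = 1, shape = 0) {
  if (shape == 0) return(rnorm(n, location, scale))
  delta <- shape / sqrt(1 + shape^2)
  z0 <- abs(rnorm(n)); z1 <- rnorm(n)
  x <- delta * z0 + sqrt(1 - delta^2) * z1
  mu <- delta * sqrt(2 / pi)
  sdv <- sqrt(1 - 2 * delta^2 / pi)
  location + scale * (x - mu) / sdv
}

#' Simulate a dual-reporter plate screen with known ground truth
#'
#' Generates the initial screen (one well per clone, distributed over
#' 96-well plates that each carry the three control roles), plus replicate
#' activities for the two confirmation rounds and a truth table. Neutral
#' clones sit at the promoter-only level; their initial-screen spread is a
#' negatively skewed, near-normal distribution of assay noise (left-skewed
#' skew-normal on the log10 activity scale, matching the observed shape of
#' exonic fragment libraries where silencers stretch the lower tail). Spiked
#' enhancers/silencers are shifted by their true effect everywhere. Additive
#' plate effects emulate batch differences removed by quantile normalization;
#' firefly signals are back-computed as renilla x 10^activity with
#' multiplicative noise, so the log-ratio is the natural recovered quantity.
#'
#' @param nClones number of experimental clones (default 1000).
#' @param seed integer seed (mandatory: generators are pure functions of
#'   configuration and seed).
#' @param nEnhancers,nSilencers spiked regulatory clones (default 10 + 10).
#' @param effectRange absolute log10 effect magnitudes, drawn uniformly
#'   (default c(0.5, 1)).
#' @param assaySd sd of the well-level assay noise, shared by initial-screen
#'   wells and confirmation replicates (default 0.1).
#' @param plateSd sd of additive plate effects (default 0.15).
#' @param skewShape skew-normal shape of the screen noise (default -4,
#'   negative skew; 0 gives a Gaussian screen).
#' @param plateSize experimental wells per plate (default 90; each plate adds
#'   two wells per control role).
#' @param controlLevels named activity levels of the control roles (defaults:
#'   no_promoter -1.5, promoter_only 0, positive_enhancer 1).
#' @return list: \code{plates} (plate table as from [readPlateTable()]),
#'   \code{round1}, \code{round2} (named lists of replicate activities, 3 and
#'   8 per clone), \code{truth} (clone_id, true_class, true_effect).
#' @export
simulateScreen <- function(nClones = 1000, seed,
                           nEnhancers = 10, nSilencers = 10,
                           effectRange = c(0.5, 1),
                           assaySd = 0.1,
                           plateSd = 0.15, skewShape = -4,
                           plateSize = 90,
                           controlLevels = c(
                             no_promoter = -1.5, promoter_only = 0,
                             positive_enhancer = 1
                           )) {
  if (missing(seed)) stop("seed is mandatory")
  if (!all(names(controlLevels) %in% setdiff(.WELL_ROLES, "experimental"))) {
    stop("unknown control role in controlLevels")
  }
  if (nEnhancers + nSilencers > nClones) stop("more spikes than clones")
  set.seed(seed)
  ids <- sprintf("clone%04d", seq_len(nClones))
  trueClass <- rep("neutral", nClones)
  trueEffect <- rep(0, nClones)
  spike <- sample(nClones, nEnhancers + nSilencers)
  if (nEnhancers) {
    eIdx <- spike[seq_len(nEnhancers)]
    trueClass[eIdx] <- "enhancer"
    trueEffect[eIdx] <- runif(nEnhancers, effectRange[1], effectRange[2])
  }
  if (nSilencers) {
    sIdx <- spike[nEnhancers + seq_len(nSilencers)]
    trueClass[sIdx] <- "silencer"
    trueEffect[sIdx] <- -runif(nSilencers, effectRange[1], effectRange[2])
  }
  enzyme <- sample(rep(c("Sau3AI", "AluI"), length.out = nClones))
  promoterLevel <- controlLevels[["promoter_only"]]

  rows <- list()
  for (enz in c("Sau3AI", "AluI")) {
    idx <- which(enzyme == enz)
    nPlates <- max(1L, ceiling(length(idx) / plateSize))
    plateOf <- rep(seq_len(nPlates), each = plateSize)[seq_along(idx)]
    plateEffect <- rnorm(nPlates, 0, plateSd)
    for (p in seq_len(nPlates)) {
      i <- idx[plateOf == p]
      batch <- sprintf("%s_P%02d", enz, p)
      screenNoise <- .rSkewNormal(length(i), 0, assaySd, skewShape)
      actExp <- promoterLevel + trueEffect[i] + screenNoise + plateEffect[p]
      ctlRoles <- rep(names(controlLevels), each = 2L)
      actCtl <- controlLevels[ctlRoles] + plateEffect[p] +
        rnorm(length(ctlRoles), 0, assaySd)
      act <- c(actExp, actCtl)
      ren <- rlnorm(length(act), log(1000), 0.3)
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = c(ids[i], sprintf("%s_ctl%02d", batch, seq_along(ctlRoles))),
        batch_id = batch,
        enzyme = c(rep(enz, length(i)), rep("control", length(ctlRoles))),
        well_role = c(rep("experimental", length(i)), ctlRoles),
        firefly = ren * 10^act,
        renilla = ren,
        stringsAsFactors = FALSE
      )
    }
  }
  plates <- do.call(rbind, rows)
  rownames(plates) <- NULL
  plates$usable <- TRUE
  plates$note <- ""

  replicates <- function(nRep) {
    out <- lapply(seq_len(nClones), function(i) {
      promoterLevel + trueEffect[i] + rnorm(nRep, 0, assaySd)
    })
    names(out) <- ids
    out
  }
  list(
    plates = plates,
    round1 = replicates(3L),
    round2 = replicates(8L),
    truth = data.frame(
      clone_id = ids, true_class = trueClass, true_effect = trueEffect,
      enzyme = enzyme, stringsAsFactors = FALSE
    )
  )
}

#' Simulate a gene locus with an embedded scored element
#'
#' Builds a multi-exon gene model (first exon 5' UTR, middle exons CDS, last
#' exon 3' UTR), a random chromosome sequence with controllable GC content
#' per region, a per-base conservation-like score track over the exons
#' (background scores Beta-distributed; element bases shifted up by the
#' configured lift, clipped to [0, 1]), and the ground-truth element
#' interval, embedded entirely within one exon.
#'
#' @param seed integer seed (mandatory).
#' @param exonLengths exon lengths 5' to 3' (default c(150, 399, 600, 399,
#'   150); the middle CDS lengths sum to a multiple of 3).
#' @param elementLength element length in bp (default 200).
#' @param elementExon index of the exon hosting the element (default: a
#'   random exon wide enough).
#' @param bgMean background mean score (default 0.2).
#' @param lift increase of the element's mean score over background (default
#'   0; element mean is clipped to 0.99).
#' @param concentration Beta concentration of per-base scores (default 10).
#' @param gcBackground,gcElement GC probability per region (defaults 0.45).
#' @param intronLength spacing between exons (default 200).
#' @param strand "+" (default) or "-".
#' @return list: \code{gene} ([GeneModel-class]), \code{genome} (named
#'   DNAStringSet), \code{track} ([ScoreTrack-class] over the exons),
#'   \code{element} (GRanges), \code{truth} (list: lift, element mean used).
#' @export
simulateLocus <- function(seed,
                          exonLengths = c(150, 399, 600, 399, 150),
                          elementLength = 200, elementExon = NULL,
                          bgMean = 0.2, lift = 0, concentration = 10,
                          gcBackground = 0.45, gcElement = 0.45,
                          intronLength = 200, strand = "+") {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  nEx <- length(exonLengths)
  if (nEx < 3L) stop("need at least 3 exons (UTR5, CDS, UTR3)")
  if (sum(exonLengths[-c(1, nEx)]) %% 3L != 0L) {
    stop("CDS exon lengths must sum to a multiple of 3")
  }
  if (elementLength > max(exonLengths)) {
    stop("requested element longer than any exon span")
  }
  starts <- cumsum(c(101L, head(exonLengths, -1) + intronLength))
  ends <- starts + exonLengths - 1L
  chrom <- "chrS"
  exGr <- GRanges(chrom, IRanges(starts, ends), strand = strand)
  types <- c("UTR5", rep("CDS", nEx - 2L), "UTR3")
  if (strand == "-") types <- rev(types)
  mcols(exGr)$exon_type <- types
  if (strand == "-") exGr <- exGr[order(start(exGr), decreasing = TRUE)]
  gene <- GeneModel("simGene", exGr)

  if (is.null(elementExon)) {
    elementExon <- sample(which(exonLengths >= elementLength), 1L)
  }
  if (exonLengths[elementExon] < elementLength) {
    stop("element does not fit in exon ", elementExon)
  }
  eStart <- starts[elementExon] +
    sample.int(exonLengths[elementExon] - elementLength + 1L, 1L) - 1L
  element <- GRanges(chrom, IRanges(eStart, eStart + elementLength - 1L),
                     strand = strand)
  mcols(element)$name <- "simElement"

  chromLen <- max(ends) + 100L
  gcProb <- rep(gcBackground, chromLen)
  gcProb[eStart:(eStart + elementLength - 1L)] <- gcElement
  isGC <- runif(chromLen) < gcProb
  base <- character(chromLen)
  base[isGC] <- sample(c("G", "C"), sum(isGC), replace = TRUE)
  base[!isGC] <- sample(c("A", "T"), sum(!isGC), replace = TRUE)
  genome <- DNAStringSet(setNames(paste(base, collapse = ""), chrom))

  elemMean <- min(bgMean + lift, 0.99)
  rbetaMean <- function(n, m) rbeta(n, m * concentration, (1 - m) * concentration)
  values <- lapply(seq_len(nEx), function(j) {
    v <- rbetaMean(exonLengths[j], bgMean)
    if (j == elementExon) {
      rel <- (eStart:(eStart + elementLength - 1L)) - starts[j] + 1L
      v[rel] <- rbetaMean(elementLength, elemMean)
    }
    v
  })
  track <- ScoreTrack(GRanges(chrom, IRanges(starts, ends)), values)
  list(
    gene = gene, genome = genome, track = track, element = element,
    truth = list(lift = lift, elementMean = elemMean, elementExon = elementExon)
  )
}

#' Simulate population SNVs over a locus
#'
#' Drops biallelic SNVs over the exonic bases of a simulated locus at a
#' configured per-bp site density, multiplied by \code{multiplier} inside the
#' regulatory element (values below 1 emulate reduced population diversity in
#' the element). Sites are independent per base, so counts are
#' binomial/Poisson; the REF allele matches the locus sequence and MAFs are
#' drawn from a scaled Beta law covering (0, 0.5].
#'
#' @param locus a locus list from [simulateLocus()].
#' @param seed integer seed (mandatory).
#' @param siteDensity SNV site probability per exonic bp (default 0.005,
#'   roughly one common SNP per 200 bp).
#' @param multiplier density multiplier inside the element, in [0, 1]
#'   (default 0.3).
#' @param mafShape shape parameters of the Beta MAF law, scaled to (0, 0.5]
#'   (default c(0.5, 3): most variants rare).
#' @return variant data.frame in the [readVariants()] layout (with
#'   \code{af = maf} for the writer).
#' @export
simulateVariants <- function(locus, seed, siteDensity = 0.005,
                             multiplier = 0.3, mafShape = c(0.5, 3)) {
  if (missing(seed)) stop("seed is mandatory")
  if (multiplier < 0 || multiplier > 1) stop("multiplier must lie in [0, 1]")
  set.seed(seed)
  ex <- exons(locus$gene)
  pos <- sort(unique(unlist(lapply(seq_along(ex), function(j) {
    start(ex)[j]:end(ex)[j]
  }))))
  inElem <- pos >= start(locus$element) & pos <= end(locus$element)
  prob <- ifelse(inElem, siteDensity * multiplier, siteDensity)
  hit <- runif(length(pos)) < prob
  pos <- pos[hit]
  n <- length(pos)
  chrom <- as.character(seqnames(ex))[1]
  seqChars <- strsplit(as.character(locus$genome[[chrom]]), "")[[1]]
  refs <- seqChars[pos]
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  maf <- 0.5 * rbeta(n, mafShape[1], mafShape[2])
  data.frame(
    chrom = rep(chrom, n), pos = pos, pos0 = pos - 1L,
    id = sprintf("simsnv%04d", seq_len(n)),
    ref = refs, alt = unname(alts), maf = maf, af = maf,
    usable = rep(TRUE, n), note = rep("", n),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate a factorial TF-perturbation expression experiment
#'
#' Generates log-scale expression for a target gene and a negative-control
#' gene under the competition model of transcription-factor cis-regulation:
#' in the 2x2 (genotype x treatment) design the target's mean is lowered by
#' \code{repression} only in the wild-type x treated cell (activating the
#' repressing factor has no effect once the factor is knocked out); in the
#' two-group design the target is lowered in the dominant-negative genotype.
#' The control gene is unaffected in every cell. Gaussian noise with
#' configured sd.
#'
#' @param seed integer seed (mandatory).
#' @param design "factorial" (genotype x treatment) or "two_group".
#' @param n replicates per cell (default 3).
#' @param repression log2 drop of the target in the affected cell/group
#'   (default 1).
#' @param noiseSd residual sd (default 0.2).
#' @param baseTarget,baseControl baseline log2 means (defaults 8 and 7).
#' @return A [FactorialExpressionSet-class] with genes "TARGET" and
#'   "CONTROL".
#' @export
simulateFactorialExpression <- function(seed, design = c("factorial", "two_group"),
                                        n = 3, repression = 1, noiseSd = 0.2,
                                        baseTarget = 8, baseControl = 7) {
  if (missing(seed)) stop("seed is mandatory")
  design <- match.arg(design)
  set.seed(seed)
  if (design == "factorial") {
    genotype <- rep(c("wild_type", "null"), each = 2 * n)
    treatment <- rep(rep(c("vehicle", "agonist"), each = n), 2)
    target <- baseTarget -
      repression * (genotype == "wild_type" & treatment == "agonist")
  } else {
    genotype <- rep(c("wild_type", "dominant_negative"), each = n)
    treatment <- NULL
    target <- baseTarget - repression * (genotype == "dominant_negative")
  }
  nSamp <- length(genotype)
  m <- rbind(
    TARGET = target + rnorm(nSamp, 0, noiseSd),
    CONTROL = baseControl + rnorm(nSamp, 0, noiseSd)
  )
  colnames(m) <- sprintf("S%02d", seq_len(nSamp))
  FactorialExpressionSet(m, genotype = genotype, treatment = treatment)
}
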