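# Shared fixture builders: everything constructed in code, nothing on disk.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(S4Vectors)
})

# Plus-strand gene: UTR5 [101,160], CDS [201,320] + [401,460] (180 bp, 60
# codons), UTR3 [501,560].
makePlusGene <- function() {
  makeGeneModelFromExons(
    geneID = "gplus",
    exons = IRanges(c(101, 201, 401, 501), c(160, 320, 460, 560)),
    strand = "+", cdsStart = 201, cdsEnd = 460, chrom = "chr1"
  )
}

# Minus-strand mirror of the same layout: transcript runs right to left, so
# the UTR5 is the rightmost exon.
makeMinusGene <- function() {
  makeGeneModelFromExons(
    geneID = "gminus",
    exons = IRanges(c(101, 201, 401, 501), c(160, 320, 460, 560)),
    strand = "-", cdsStart = 201, cdsEnd = 460, chrom = "chr1"
  )
}

# Deterministic chr1 sequence long enough for the fixture genes.
makeGenome <- function(len = 700, seed = 42) {
  set.seed(seed)
  DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "chr1"
  ))
}

# Score track covering the fixture gene's exons with given per-base values
# (or a constant).
makeTrackFor <- function(gene, values = NULL, constant = NULL) {
  ex <- GenomicRanges::sort(exons(gene), ignore.strand = TRUE)
  w <- width(ex)
  if (is.null(values)) {
    stopifnot(!is.null(constant))
    values <- lapply(w, function(n) rep(constant, n))
  }
  ScoreTrack(granges(ex), values)
}

# Minimal plate table data.frame builder.
makePlate <- function(clone_id, batch_id, enzyme, well_role, firefly, renilla) {
  data.frame(
    clone_id = clone_id, batch_id = batch_id, enzyme = enzyme,
    well_role = well_role, firefly = firefly, renilla = renilla,
    stringsAsFactors = FALSE
  )
}

# Brute-force Benjamini-Hochberg step-up (independent oracle).
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i) # rank of p[i]
    q[i] <- min(1, min(sort(p)[j:m] * m / (j:m)))
  }
  q
}

# Brute-force two-sided rank-sum p by enumerating all rank assignments.
enumerationRankSumP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  sums <- apply(combos, 2, function(i) sum(rank(c(x, y))[i]))
  mu <- n1 * (n1 + n2 + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu))
}
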