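# A hand-built locus for consequence tests: plus-strand gene on a genome we
# write base by base, CDS = GCT GAT AAA (Ala-Asp-Lys) at chr1:11..19.
makeCodonFixture <- function(strand = "+") {
  pre <- strrep("T", 5) # 1..5
  utr5 <- "AACCA" # 6..10
  cds <- "GCTGATAAA" # 11..19
  utr3 <- "GGTTG" # 20..24
  post <- strrep("T", 6)
  seqStr <- paste0(pre, utr5, cds, utr3, post)
  if (strand == "-") {
    # mirror the layout so that the reverse strand reads the same codons:
    # place reverse-complement of the plus cassette at the same coordinates
    cassette <- paste0(utr5, cds, utr3)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cassette)))
    seqStr <- paste0(pre, rc, post)
  }
  genome <- Biostrings::DNAStringSet(setNames(seqStr, "chr1"))
  gene <- makeGeneModelFromExons(
    "codonGene", IRanges(6, 24), strand = strand,
    cdsStart = 11, cdsEnd = 19, chrom = "chr1"
  )
  list(genome = genome, gene = gene)
}

test_that("MAF filtering is strictly greater-than", {
  v <- data.frame(maf = c(0.011, 0.01, 0.5, NA), usable = TRUE)
  kept <- filterByMaf(v)
  expect_equal(kept$maf, c(0.011, 0.5))
})

test_that("codon-aware consequence classification is strand-aware", {
  fx <- makeCodonFixture("+")
  mkVar <- function(pos, ref, alt) {
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  # GCT -> GCC (third base T>C): Ala -> Ala, synonymous
  expect_equal(classifyConsequence(mkVar(13, "T", "C"), fx$gene, fx$genome),
               "synonymous")
  # GCT -> ACT (first base G>A): Ala -> Thr, nonsynonymous
  expect_equal(classifyConsequence(mkVar(11, "G", "A"), fx$gene, fx$genome),
               "nonsynonymous")
  # AAA -> TAA introduces a stop: counted as nonsynonymous
  expect_equal(classifyConsequence(mkVar(17, "A", "T"), fx$gene, fx$genome),
               "nonsynonymous")
  # UTR3 variant
  expect_equal(classifyConsequence(mkVar(21, "G", "A"), fx$gene, fx$genome),
               "noncoding")
  # outside the gene
  expect_equal(classifyConsequence(mkVar(2, "T", "A"), fx$gene, fx$genome),
               "unassigned")
  # REF mismatch against the FASTA
  expect_error(classifyConsequence(mkVar(11, "C", "A"), fx$gene, fx$genome),
               "mismatch")

  # minus strand: the CDS reads through the reverse complement, so the
  # genomic base complementary to the codon wobble is synonymous
  fm <- makeCodonFixture("-")
  cdsSeq <- ExonScreen:::.cdsInfo(fm$gene, fm$genome)
  expect_equal(cdsSeq$seq, "GCTGATAAA")
  # third codon base of GCT sits at genomic position 17 on the minus cassette
  pos3 <- cdsSeq$genomicPos[3]
  refBase <- substr(as.character(fm$genome[["chr1"]]), pos3, pos3)
  # T>C on the transcript is A>G on the genome
  expect_equal(refBase, "A")
  expect_equal(
    classifyConsequence(mkVar(pos3, "A", "G"), fm$gene, fm$genome),
    "synonymous"
  )
})

test_that("partial codons at a CDS edge are unassigned", {
  # frame offset 1: the first CDS base belongs to an upstream partial codon
  genome <- Biostrings::DNAStringSet(setNames(strrep("GCTGATAAA", 4), "chr1"))
  gene <- makeGeneModelFromExons(
    "offsetGene", IRanges(1, 30), strand = "+",
    cdsStart = 2, cdsEnd = 29, chrom = "chr1", cdsFrameOffset = 1L
  )
  v <- data.frame(chrom = "chr1", pos = 2, ref = "C", alt = "A",
                  stringsAsFactors = FALSE)
  expect_equal(classifyConsequence(v, gene, genome), "unassigned")
})

test_that("consequence calls agree with a whole-CDS translation oracle", {
  set.seed(61)
  for (rep in 1:6) {
    nCodon <- sample(5:12, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), nCodon * 3, TRUE), collapse = "")
    flank <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    strand <- sample(c("+", "-"), 1)
    cdsGenomic <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    } else cds
    genome <- Biostrings::DNAStringSet(setNames(
      paste0(flank, cdsGenomic, flank), "chr1"
    ))
    gene <- makeGeneModelFromExons(
      "rndGene", IRanges(11, 10 + nCodon * 3), strand = strand,
      cdsStart = 11, cdsEnd = 10 + nCodon * 3, chrom = "chr1"
    )
    for (k in 1:8) {
      pos <- sample(11:(10 + nCodon * 3), 1)
      ref <- substr(as.character(genome[["chr1"]]), pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classifyConsequence(
        data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt),
        gene, genome
      )
      # oracle: mutate the genome, extract and translate the entire CDS
      mutated <- as.character(genome[["chr1"]])
      substr(mutated, pos, pos) <- alt
      extract <- function(s) {
        x <- Biostrings::DNAString(substr(s, 11, 10 + nCodon * 3))
        if (strand == "-") x <- Biostrings::reverseComplement(x)
        suppressWarnings(as.character(Biostrings::translate(
          x, no.init.codon = TRUE, if.fuzzy.codon = "X"
        )))
      }
      oracle <- if (identical(extract(as.character(genome[["chr1"]])),
                              extract(mutated))) "synonymous" else "nonsynonymous"
      expect_equal(got, oracle)
    }
  }
})

test_that("consequence categories partition retained variants", {
  l <- simulateLocus(seed = 77, exonLengths = c(300, 900, 300))
  v <- simulateVariants(l, seed = 78, siteDensity = 0.02, multiplier = 1)
  cls <- classifyConsequences(v, l$gene, l$genome)
  expect_true(all(cls$consequence %in%
    c("synonymous", "nonsynonymous", "noncoding", "unassigned")))
  expect_equal(
    sum(table(cls$consequence)), nrow(v)
  )
  # CDS variants are syn or nonsyn, UTR variants noncoding
  cdsEx <- exons(l$gene)[mcols(exons(l$gene))$exon_type == "CDS"]
  inCds <- v$pos >= min(start(cdsEx)) & v$pos <= max(end(cdsEx))
  expect_true(all(cls$consequence[inCds] %in% c("synonymous", "nonsynonymous")))
  expect_true(all(cls$consequence[!inCds] == "noncoding"))
})

test_that("substitution rates count sites per base pair", {
  iv <- GRanges("chr1", IRanges(1, 100))
  v2 <- data.frame(chrom = "chr1", pos = c(10L, 20L))
  expect_equal(substitutionRate(iv, v2), 0.02)
  expect_equal(substitutionRate(iv, v2[0, ]), 0)
  # splitting invariance: rate over a union equals pooled count / length
  split2 <- GRanges("chr1", IRanges(c(1, 51), c(50, 100)))
  expect_equal(substitutionRate(split2, v2), 0.02)
  outside <- data.frame(chrom = "chr1", pos = 150L)
  expect_equal(substitutionRate(iv, outside), 0)
})

test_that("rate comparison pairs elements with their hosts", {
  l <- simulateLocus(seed = 81, exonLengths = c(300, 900, 300))
  # hand-placed variants: 2 in the element, 4 in the host remainder
  ePos <- start(l$element) + c(10L, 50L)
  ex <- exons(l$gene)
  hostEx <- GenomicRanges::setdiff(granges(ex), granges(l$element))
  hPos <- c(start(hostEx)[1] + c(5L, 25L), start(hostEx)[2] + c(3L, 8L))
  seqChars <- strsplit(as.character(l$genome[["chrS"]]), "")[[1]]
  mkv <- function(p) data.frame(
    chrom = "chrS", pos = p, pos0 = p - 1L, id = sprintf("v%d", seq_along(p)),
    ref = seqChars[p], alt = "N", maf = 0.25, usable = TRUE, note = "",
    stringsAsFactors = FALSE
  )
  vars <- mkv(c(ePos, hPos))
  vars$alt <- vapply(vars$ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
  cmp <- compareRates(
    list(list(element = l$element, gene = l$gene, id = "E1")), vars
  )
  expect_equal(cmp$perElement$element_rate, 2 / width(l$element))
  expect_equal(cmp$perElement$host_rate, 4 / sum(width(hostEx)))

  # forced sign: empty elements against a populated host
  vHost <- mkv(hPos)
  vHost$alt <- vapply(vHost$ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
  cmp0 <- compareRates(
    list(list(element = l$element, gene = l$gene, id = "E1")), vHost
  )
  expect_equal(cmp0$perElement$element_rate, 0)
  expect_gt(cmp0$perElement$host_rate, 0)
  expect_lt(cmp0$perElement$diff, 0)
})

test_that("null variant simulation gives balanced element and host rates", {
  diffs <- vapply(1:40, function(s) {
    l <- simulateLocus(seed = s + 100, exonLengths = c(300, 900, 300))
    v <- simulateVariants(l, seed = s + 500, siteDensity = 0.02, multiplier = 1)
    cmp <- compareRates(list(list(element = l$element, gene = l$gene)), v,
                        mafMin = 0)
    cmp$perElement$diff
  }, numeric(1))
  # paired difference centered at zero under multiplier = 1
  expect_lt(abs(median(diffs)), 0.01)
  tst <- wilcoxonSignedRank(diffs)
  expect_gt(pValue(tst), 0.05)
})

test_that("stratified comparison restricts variants and denominators to the CDS", {
  l <- simulateLocus(seed = 91, exonLengths = c(300, 900, 300), elementExon = 2)
  v <- simulateVariants(l, seed = 92, siteDensity = 0.03, multiplier = 1)
  cmpSyn <- compareRates(
    list(list(element = l$element, gene = l$gene)), v,
    genome = l$genome, stratum = "synonymous", mafMin = 0
  )
  cmpNon <- compareRates(
    list(list(element = l$element, gene = l$gene)), v,
    genome = l$genome, stratum = "nonsynonymous", mafMin = 0
  )
  cls <- classifyConsequences(filterByMaf(v, 0), l$gene, l$genome)
  cdsEx <- exons(l$gene)[mcols(exons(l$gene))$exon_type == "CDS"]
  inElem <- cls$pos >= start(l$element) & cls$pos <= end(l$element)
  nSynElem <- sum(cls$consequence == "synonymous" & inElem)
  expect_equal(
    cmpSyn$perElement$element_rate, nSynElem / width(l$element)
  )
  nNonHost <- sum(cls$consequence == "nonsynonymous" & !inElem)
  hostLen <- sum(width(cdsEx)) - width(l$element)
  expect_equal(cmpNon$perElement$host_rate, nNonHost / hostLen)
})
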