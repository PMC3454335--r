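test_that("quantile normalization matches the sorted-row-mean oracle", {
  # identical batches are left unchanged
  out <- quantileNormalize(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(out$A, c(1, 2, 3))
  expect_equal(out$B, c(1, 2, 3))

  # equal sizes: both batches get the row means of the sorted columns
  out <- quantileNormalize(list(A = c(1, 2, 3), B = c(4, 6, 8)))
  expect_equal(out$A, c(2.5, 4, 5.5))
  expect_equal(out$B, c(2.5, 4, 5.5))

  # ties share the mean of the tied reference values
  out <- quantileNormalize(list(A = c(1, 1, 3), B = c(2, 4, 6)))
  expect_equal(out$A, c(2.0, 2.0, 4.5))

  # random equal-size case against the brute-force oracle (and limma)
  set.seed(11)
  m <- matrix(rnorm(40), ncol = 4)
  got <- quantileNormalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  oracle <- apply(m, 2, function(col) ref[rank(col)])
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  expect_equal(
    unname(got), unname(as.matrix(limma::normalizeQuantiles(m))),
    tolerance = 1e-12
  )

  expect_error(quantileNormalize(list(A = numeric(0), B = 1:3)), "empty")
})

test_that("quantile normalization preserves rank order and is idempotent", {
  set.seed(21)
  for (rep in 1:5) {
    batches <- lapply(sample(3:9, 3, replace = TRUE), function(n) rnorm(n, sd = runif(1, 0.5, 3)))
    names(batches) <- c("A", "B", "C")
    out <- quantileNormalize(batches)
    for (b in names(batches)) {
      expect_equal(rank(out[[b]]), rank(batches[[b]]))
    }
    # equal-size batches end up with identical sorted vectors
    eq <- lapply(1:3, function(i) rnorm(7, mean = i))
    norm <- quantileNormalize(eq)
    expect_equal(sort(norm[[1]]), sort(norm[[2]]), tolerance = 1e-12)
    expect_equal(sort(norm[[2]]), sort(norm[[3]]), tolerance = 1e-12)
    # idempotent
    twice <- quantileNormalize(norm)
    expect_equal(twice, norm, tolerance = 1e-10)
  }
})

test_that("one-sample t-test: df, closed-form p, degenerate input", {
  expect_equal(degreesOfFreedom(oneSampleT(rnorm(8), 0)), 7)
  expect_equal(degreesOfFreedom(oneSampleT(rnorm(3), 0)), 2)

  r <- oneSampleT(c(1, 2, 3), 0)
  expect_equal(testStatistic(r), 2 / (1 / sqrt(3)), tolerance = 1e-4) # 3.4641
  # closed form of the t CDF at df = 2: F(t) = 1/2 + t / (2 sqrt(2 + t^2))
  t0 <- testStatistic(r)
  expect_equal(pValue(r), 2 * (1 - (0.5 + t0 / (2 * sqrt(2 + t0^2)))), tolerance = 1e-10)
  expect_equal(round(pValue(r), 4), 0.0742)

  flat <- oneSampleT(c(2, 2, 2), 2)
  expect_true(is.na(pValue(flat)))
  expect_match(testNote(flat), "zero")
})

test_that("two-sample t is pooled-variance Student", {
  expect_equal(degreesOfFreedom(twoSampleT(rnorm(3), rnorm(3))), 4)

  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(testStatistic(same), 0)
  expect_equal(pValue(same), 1)

  r <- twoSampleT(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, se = sqrt(2/3), t = -3 / se
  expect_equal(testStatistic(r), -3 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(degreesOfFreedom(r), 4)

  degen <- twoSampleT(c(1, 1), c(2, 2))
  expect_true(is.na(pValue(degen)))
})

test_that("2x2 ANOVA reproduces the hand-computed decomposition", {
  # four identical cells: all effects exactly zero
  v <- rep(c(1, 2, 3), 4)
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  res <- anova2x2(v, a, b)
  expect_equal(testStatistic(res$A), 0)
  expect_equal(testStatistic(res$B), 0)
  expect_equal(testStatistic(res$AB), 0)

  # cells (1,3),(2,4),(5,7),(6,8): SS_A=32, SS_B=2, SS_AB=0, MS_err=2
  v <- c(1, 3, 2, 4, 5, 7, 6, 8)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), 2)
  res <- anova2x2(v, a, b)
  expect_equal(testStatistic(res$A), 16)
  expect_equal(testStatistic(res$B), 1)
  expect_equal(testStatistic(res$AB), 0)
  expect_equal(degreesOfFreedom(res$A), 1)

  expect_error(anova2x2(1:6, c("a","a","a","a","b","b"), c("x","y","x","y","x","y")),
               "balanced")
})

# independent oracle: group-mean sums of squares computed from first principles
bruteForceSS <- function(v, a, b) {
  n <- length(v) / 4
  gm <- mean(v)
  mA <- tapply(v, a, mean); mB <- tapply(v, b, mean)
  mAB <- tapply(v, interaction(a, b), mean)
  ssA <- 2 * n * sum((mA - gm)^2)
  ssB <- 2 * n * sum((mB - gm)^2)
  ssCells <- n * sum((mAB - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssErr <- sum((v - mAB[interaction(a, b)])^2)
  list(A = ssA, B = ssB, AB = ssAB, err = ssErr, total = sum((v - gm)^2))
}

test_that("2x2 ANOVA agrees with the first-principles decomposition and conserves SS", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    a <- rep(c("a1", "a2"), each = 2 * n)
    b <- rep(rep(c("b1", "b2"), each = n), 2)
    v <- rnorm(4 * n) + 0.5 * (a == "a2") + 0.3 * (a == "a2") * (b == "b2")
    ss <- bruteForceSS(v, a, b)
    expect_equal(ss$A + ss$B + ss$AB + ss$err, ss$total, tolerance = 1e-9)
    res <- anova2x2(v, a, b)
    dfe <- 4 * n - 4
    expect_equal(testStatistic(res$A), (ss$A / 1) / (ss$err / dfe), tolerance = 1e-9)
    expect_equal(testStatistic(res$B), (ss$B / 1) / (ss$err / dfe), tolerance = 1e-9)
    expect_equal(testStatistic(res$AB), (ss$AB / 1) / (ss$err / dfe), tolerance = 1e-9)
  }
})

test_that("signed-rank dialect reproduces the printed p-values exactly", {
  # W = 10 with N_r = 5 (positive ranks {1, 4, 5})
  r5 <- wilcoxonSignedRank(c(0.1, -0.2, -0.3, 0.4, 0.5))
  expect_equal(testStatistic(r5), 10)
  expect_equal(nEffective(r5), 5L)
  expect_equal(round(pValue(r5), 4), 0.5896)

  # W = 10 with N_r = 4 (all positive)
  r4 <- wilcoxonSignedRank(c(1, 2, 3, 4))
  expect_equal(testStatistic(r4), 10)
  expect_equal(nEffective(r4), 4L)
  expect_equal(round(pValue(r4), 4), 0.1003)

  # derived case: z = (9 - 7.5 - 0.5)/sqrt(13.75)
  r <- wilcoxonSignedRank(c(1, -2, 3, -4, 5))
  expect_equal(testStatistic(r), 9)
  expect_equal(round(pValue(r), 4), 0.7874)

  # zeros are dropped before ranking
  rz <- wilcoxonSignedRank(c(0, 0, 1, 2, 3, 4))
  expect_equal(nEffective(rz), 4L)
  expect_equal(testStatistic(rz), 10)

  allz <- wilcoxonSignedRank(c(0, 0, 0))
  expect_true(is.na(pValue(allz)))

  # at W = 30, N_r = 8 the p-value is tie-sensitive at the fourth decimal:
  # tie-free variance gives 0.1073, one tied |difference| pair gives 0.1069
  expect_equal(round(signedRankP(30, 8), 4), 0.1073)
  expect_equal(round(signedRankP(30, 8, tieCounts = c(2L)), 4), 0.1069)
})

test_that("signed-rank approximation matches wilcox.test and the exact option psignrank", {
  set.seed(3)
  for (rep in 1:10) {
    d <- round(rnorm(sample(5:12, 1)), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    ours <- wilcoxonSignedRank(d)
    base <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
    expect_equal(testStatistic(ours), unname(base$statistic))
    expect_equal(pValue(ours), base$p.value, tolerance = 1e-10)
    if (!anyDuplicated(abs(d))) {
      oursX <- wilcoxonSignedRank(d, exact = TRUE)
      baseX <- wilcox.test(d, exact = TRUE)
      expect_equal(pValue(oursX), baseX$p.value, tolerance = 1e-10)
    }
  }
})

test_that("rank-sum exact mode equals full enumeration on tie-free inputs", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4, 5))
  expect_equal(pValue(r), 0.2)

  expect_equal(pValue(wilcoxonRankSum(1, 1)), 1)

  set.seed(5)
  for (rep in 1:12) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    pool <- sample(seq_len(99), n1 + n2) # tie-free values, ranks on both sides
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    expect_equal(
      pValue(wilcoxonRankSum(x, y)),
      enumerationRankSumP(x, y),
      tolerance = 1e-10
    )
  }
})

test_that("rank-sum exact and approximate p agree closely at n1 = n2 = 6", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- wilcox.test(x, y, exact = TRUE)$p.value
    ours <- pValue(wilcoxonRankSum(x, y)) # 12 tie-free values: exact branch
    apprx <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(ours, exact, tolerance = 1e-12)
    expect_lt(abs(exact - apprx), 0.02)
  }
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (rep in 1:10) {
    p <- runif(sample(2:20, 1))
    expect_equal(bhFdr(p), bruteForceBH(p), tolerance = 1e-12)
  }
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(testStatistic(pearsonR(x, x)), 1)
  expect_equal(testStatistic(pearsonR(x, -x)), -1)
  r <- pearsonR(c(1, 2, 3), c(1, 2, 4))
  expect_equal(testStatistic(r), 3 / sqrt(2 * 14 / 3), tolerance = 1e-4) # 0.9820
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "variance")
})
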