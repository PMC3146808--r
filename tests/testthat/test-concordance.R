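test_that("pearsonWithPValue matches its closed form and a permutation oracle", {
  x <- as.numeric(1:10)
  expect_equal(pearsonWithPValue(x, x)$r, 1)
  expect_equal(pearsonWithPValue(x, -x)$r, -1)
  expect_error(pearsonWithPValue(x, rep(1, 10)), "zero variance")
  expect_error(pearsonWithPValue(x, x[1:5]), "equal length")

  set.seed(23)
  n <- 25
  z <- stats::rnorm(n)
  x <- z + stats::rnorm(n, 0, 0.75)
  y <- 0.8 * z + stats::rnorm(n, 0, 0.6)
  got <- pearsonWithPValue(x, y)
  perm <- replicate(100000, abs(stats::cor(x, sample(y))))
  pPerm <- (sum(perm >= abs(got$r)) + 1) / (length(perm) + 1)
  expect_lt(got$p, 2 * pPerm)
  expect_gt(got$p, pPerm / 2)
})

test_that("matchedUnmatched partitions all cross correlations", {
  xg <- simulateXenograftPairs(smallConfig(seed = 24), smallDegradation(seed = 25))
  conc <- matchedUnmatched(xg$ff, xg$ffpe)
  expect_identical(length(matchedR(conc)), 25L)
  expect_identical(length(unmatchedR(conc)), 600L)
  expect_true(all(abs(c(matchedR(conc), unmatchedR(conc))) <= 1))

  # identity comparison: every matched coefficient is exactly 1
  self <- matchedUnmatched(xg$ff, xg$ff,
                           pairing = stats::setNames(colnames(xg$ff),
                                                     colnames(xg$ff)))
  expect_equal(unname(matchedR(self)), rep(1, 25), tolerance = 1e-12)

  # permuting sample order leaves the multisets unchanged
  perm <- xg$ffpe[, sample(ncol(xg$ffpe))]
  conc2 <- matchedUnmatched(xg$ff, perm)
  expect_equal(sort(unname(matchedR(conc2))), sort(unname(matchedR(conc))))
  expect_equal(sort(unname(unmatchedR(conc2))), sort(unname(unmatchedR(conc))))

  bad <- xg$ffpe
  SummarizedExperiment::colData(bad)$pair_id[1] <- "P99"
  expect_error(matchedUnmatched(xg$ff, bad), "unresolvable|absent")
})

test_that("re-amplified pairs correlate higher matched than unmatched", {
  cfg <- smallConfig(seed = 26)
  xg <- simulateXenograftPairs(cfg, identityDegradation())
  re <- simulateReamplification(xg$ff, cfg, seed = 27)
  colnames(re) <- sub("_FF$", "_RE", colnames(re))
  conc <- matchedUnmatched(xg$ff, re,
                           pairing = stats::setNames(colnames(re),
                                                     colnames(xg$ff)))
  s <- summary(conc)
  expect_gt(s$matched_mean, s$unmatched_mean)
})

test_that("sdFilterAndCenter keeps top-SD probes and centers both ways", {
  set.seed(28)
  high <- matrix(stats::rnorm(50 * 10, 7, 2), 50, 10)
  low <- matrix(stats::rnorm(30 * 10, 7, 0.1), 30, 10)
  m <- 2^rbind(high, low)
  dimnames(m) <- list(sprintf("p%02d", 1:80), sprintf("s%02d", 1:10))
  se <- makeExpressionSet(m)
  out <- sdFilterAndCenter(se, 50L)
  expect_setequal(rownames(out), sprintf("p%02d", 1:50))
  expect_lt(max(abs(colMeans(out))), 1e-10)

  all_ <- sdFilterAndCenter(se, 80L)
  expect_identical(nrow(all_), 80L)
  # with nKeep = all, result equals plain two-way centering of log2 data
  x <- log2(m)[rownames(all_), ]
  x <- x - rowMeans(x)
  x <- sweep(x, 2L, colMeans(x))
  expect_equal(all_, x, tolerance = 1e-12)
  expect_error(sdFilterAndCenter(se, 81L), "exceeds")
})

test_that("uncentered correlation behaves like a cosine similarity", {
  m <- cbind(a = c(1, 0, 0), b = c(2, 0, 0), c = c(0, 3, 0))
  s <- uncenteredCorrelation(m)
  expect_equal(s["a", "a"], 1)
  expect_equal(s["a", "b"], 1)   # parallel vectors
  expect_equal(s["a", "c"], 0)   # orthogonal vectors
  expect_error(uncenteredCorrelation(cbind(m, z = c(0, 0, 0))), "all-zero")
})

test_that("clustering merges match a hand-computed toy case", {
  # a and b identical, c orthogonal: merge {a,b} at 0, then c at height 1
  m <- cbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  hc <- clusterSamples(m)
  expect_equal(hc$height, c(0, 1), tolerance = 1e-12)
  expect_identical(stats::cutree(hc, 2)[["c"]],
                   unique(stats::cutree(hc, 2)[c("a", "b")]) + 1L)
  expect_error(clusterSamples(m[, 1, drop = FALSE]), "at least 2")
})

test_that("merge heights are non-decreasing under average linkage", {
  xg <- simulateXenograftPairs(smallConfig(seed = 29), smallDegradation(seed = 30))
  comb <- makeExpressionSet(cbind(exprsMatrix(xg$ff), exprsMatrix(xg$ffpe)))
  hc <- clusterSamples(sdFilterAndCenter(comb, 200L))
  expect_true(all(diff(hc$height) >= -1e-12))
  path <- withr::local_tempfile(fileext = ".nwk")
  writeDendrogram(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(comb))
})

test_that("pcaScores explains variance in non-increasing fractions", {
  xg <- simulateXenograftPairs(smallConfig(seed = 31), identityDegradation())
  full <- pcaScores(xg$ff, nComponents = 24L)
  expect_true(all(diff(full$varianceExplained) <= 1e-12))
  expect_lte(sum(full$varianceExplained), 1 + 1e-8)

  # a rank-1 matrix concentrates all variance on the first component
  u <- stats::rnorm(60); v <- stats::rnorm(8)
  m <- 2^(7 + outer(u, v) / 4)
  dimnames(m) <- list(sprintf("p%02d", 1:60), sprintf("s%d", 1:8))
  p1 <- pcaScores(makeExpressionSet(m), 2L)
  expect_gt(p1$varianceExplained[1], 1 - 1e-8)

  # duplicate samples receive identical scores
  dup <- makeExpressionSet(cbind(exprsMatrix(xg$ff),
                                 DUP = exprsMatrix(xg$ff)[, 1]))
  sc <- pcaScores(dup, 2L)$scores
  expect_equal(sc["DUP", ], sc[colnames(xg$ff)[1], ], tolerance = 1e-8)
})

test_that("patientConcordance applies the minimum-difference rule", {
  r1 <- patientConcordance(list(A = c(0.10, 0.45)), c(A = 0.50))
  expect_equal(r1$perPatient$min_abs_diff, 0.05)
  expect_true(r1$perPatient$concordant)

  r2 <- patientConcordance(list(A = c(0.20, 0.30)), c(A = 0.90))
  expect_equal(r2$perPatient$min_abs_diff, 0.60)
  expect_false(r2$perPatient$concordant)
  expect_equal(r2$summary$concordance_rate, 0)

  # 5 of 6 concordant reports an 83% rate
  ff <- stats::setNames(as.list(rep(0.5, 6)), LETTERS[1:6])
  ffpe <- stats::setNames(c(rep(0.5, 5), 0.95), LETTERS[1:6])
  r3 <- patientConcordance(ff, ffpe)
  expect_identical(r3$summary$concordance_rate, 83)

  expect_error(patientConcordance(list(A = 0.5), c(B = 0.5)), "FF lesion")
})
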