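test_that("probe selection matches a brute-force t ranking", {
  cfg <- smallConfig(seed = 12, effectSize = 3)
  ts <- simulateTrainingSet(cfg, "RAS")
  truth <- signatureProbeIds(cfg, "RAS")
  got <- selectSignatureProbes(ts$se, ts$design, length(truth))
  expect_setequal(got, truth)

  # brute-force oracle for the full ranking
  x <- log2(exprsMatrix(ts$se))
  tt <- apply(x, 1L, function(v) {
    a <- v[ts$design@perturbedIds]; b <- v[ts$design@controlIds]
    sp <- sqrt(((length(b) - 1) * stats::var(b) +
                  (length(a) - 1) * stats::var(a)) /
                 (length(a) + length(b) - 2)) + 1e-6
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  })
  want <- rownames(x)[order(-abs(tt), rownames(x))]
  expect_identical(selectSignatureProbes(ts$se, ts$design, nrow(x)), want)
})

test_that("probe selection is deterministic under ties", {
  m <- matrix(rep(c(100, 200), each = 4 * 6), nrow = 8, byrow = TRUE)
  m <- matrix(100, 8, 6,
              dimnames = list(paste0("p", 8:1), paste0("s", 1:6)))
  se <- makeExpressionSet(m)
  d <- trainingDesign("X", paste0("s", 1:3), paste0("s", 4:6))
  got <- selectSignatureProbes(se, d, 4L)
  # all statistics tie at 0; lexicographic probe order breaks them
  expect_identical(got, sort(rownames(m))[1:4])
})

test_that("computeMetagenes agrees with a full-SVD oracle", {
  set.seed(13)
  x <- matrix(stats::rnorm(150 * 16), 150, 16,
              dimnames = list(sprintf("p%03d", 1:150), sprintf("s%02d", 1:16)))
  x <- x - rowMeans(x)
  full <- svd(x)
  mg <- computeMetagenes(x, 3L)
  recon <- mg$loadings %*% diag(mg$singularValues) %*%
    (diag(1 / mg$singularValues) %*% mg$trainingFactors)
  err <- sum((x - mg$loadings %*% mg$trainingFactors)^2)
  expect_equal(err, sum(full$d[4:length(full$d)]^2), tolerance = 1e-8)
  # full rank (15 after per-probe centering) reconstruction is exact
  mgF <- computeMetagenes(x, 15L)
  expect_lt(max(abs(x - mgF$loadings %*% mgF$trainingFactors)), 1e-8)
  # orthonormal loadings and deterministic sign convention
  expect_equal(crossprod(mg$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in 1:3) {
    i <- which.max(abs(mg$loadings[, j]))
    expect_gt(mg$loadings[i, j], 0)
  }
  expect_error(computeMetagenes(x, 16L), "rank")
})

test_that("a rank-1 matrix is fully captured by one factor", {
  u <- stats::rnorm(40); v <- stats::rnorm(10)
  x <- outer(u, v)
  dimnames(x) <- list(sprintf("p%02d", 1:40), sprintf("s%02d", 1:10))
  mg <- computeMetagenes(x, 1L)
  expect_lt(max(abs(x - mg$loadings %*% mg$trainingFactors)), 1e-8)
})

test_that("buildSignature composes the pipeline stages", {
  ts <- simulateTrainingSet(smallConfig(seed = 14), "RAS")
  sig <- quickSignature(ts, nProbes = 40L, k = 3L)
  expect_s4_class(sig, "PathwaySignature")
  expect_identical(length(signatureProbes(sig)), 40L)
  expect_identical(factorCount(sig), 3L)
  expect_identical(pathwayName(sig), "RAS")
  expect_identical(dim(metageneLoadings(sig)), c(40L, 3L))
  expect_identical(ncol(posteriorDraws(sig)), 4L)
  expect_error(buildSignature(ts$se, ts$design, nProbes = 10, k = 11),
               "k exceeds")
})

test_that("projection reproduces training factors and centers the mean", {
  ts <- simulateTrainingSet(smallConfig(seed = 15), "RAS")
  sig <- quickSignature(ts)
  f <- projectSamples(sig, ts$se[, sig@trainingIds], mode = "standardize")
  expect_lt(max(abs(f - sig@trainingFactors)), 1e-8)

  grand <- 2^rowMeans(log2(exprsMatrix(ts$se)))
  f0 <- projectSamples(sig, grand, mode = "standardize")
  expect_lt(max(abs(f0)), 1e-8)

  sub <- ts$se[setdiff(rownames(ts$se), sig@probeIds[1]), ]
  expect_error(projectSamples(sig, sub), sig@probeIds[1])
})

test_that("predictions are probabilities inside their credible intervals", {
  ts <- simulateTrainingSet(smallConfig(seed = 16), "RAS")
  sig <- quickSignature(ts)
  pred <- predictActivity(sig, ts$se)
  expect_true(all(pred$ci_low >= 0 & pred$ci_high <= 1))
  expect_true(all(pred$probability >= pred$ci_low &
                    pred$probability <= pred$ci_high))
  lab <- stats::setNames(ts$truth[pred$sample_id, "RAS"], pred$sample_id)
  expect_true(all(pred$probability[lab == 1] > 0.5))
  expect_true(all(pred$probability[lab == 0] < 0.5))
})

test_that("quantile mode is invariant to monotone transforms", {
  ts <- simulateTrainingSet(smallConfig(seed = 17), "RAS")
  sig <- quickSignature(ts)
  xg <- simulateXenograftPairs(smallConfig(seed = 18), identityDegradation())
  p1 <- predictActivity(sig, xg$ff, mode = "quantile")
  cubed <- makeExpressionSet(exprsMatrix(xg$ff)^3)
  p2 <- predictActivity(sig, cubed, mode = "quantile")
  expect_equal(p1$probability, p2$probability, tolerance = 1e-12)
})

test_that("arrayscale mode absorbs a global multiplicative shift", {
  ts <- simulateTrainingSet(smallConfig(seed = 19), "RAS")
  sig <- quickSignature(ts)
  xg <- simulateXenograftPairs(smallConfig(seed = 20), identityDegradation())
  p1 <- predictActivity(sig, xg$ff, mode = "arrayscale")
  dimmed <- makeExpressionSet(exprsMatrix(xg$ff) / 8)
  p2 <- predictActivity(sig, dimmed, mode = "arrayscale")
  expect_equal(p1$probability, p2$probability, tolerance = 1e-10)
})

test_that("signatures round-trip through JSON serialization", {
  ts <- simulateTrainingSet(smallConfig(seed = 21), "RAS")
  sig <- quickSignature(ts)
  path <- withr::local_tempfile(fileext = ".json")
  writeSignature(sig, path)
  back <- readSignature(path)
  expect_identical(signatureProbes(back), signatureProbes(sig))
  # JSON carries 17 significant digits; round trip is exact to 1 ulp
  expect_equal(metageneLoadings(back), metageneLoadings(sig),
               tolerance = 1e-14)
  expect_equal(unclass(posteriorDraws(sig))[, ], posteriorDraws(back),
               tolerance = 1e-14, ignore_attr = TRUE)
  p1 <- predictActivity(sig, ts$se)
  p2 <- predictActivity(back, ts$se)
  expect_equal(p1$probability, p2$probability, tolerance = 1e-12)
  writeLines('{"format": "other"}', path)
  expect_error(readSignature(path), "format tag")
})

test_that("held-out samples exchangeable with a twin get similar scores", {
  ts <- simulateTrainingSet(smallConfig(seed = 22), "RAS")
  sig <- quickSignature(ts)
  # a near-duplicate of a training sample scores like the original
  orig <- exprsMatrix(ts$se)[, "RAS_01", drop = FALSE]
  twin <- makeExpressionSet(orig * 2^stats::rnorm(nrow(orig), 0, 0.01) ,
                            colData = S4Vectors::DataFrame(row.names = "twin"))
  colnames(twin) <- "twin"
  p <- predictActivity(sig, twin)$probability
  p0 <- predictActivity(sig, ts$se[, "RAS_01", drop = FALSE])$probability
  expect_lt(abs(p - p0), 0.05)
})
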