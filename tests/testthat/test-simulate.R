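test_that("training sets follow the study replicate design", {
  ras <- simulateTrainingSet(smallConfig(), "RAS")
  expect_identical(ncol(ras$se), 16L)
  expect_identical(length(ras$design@controlIds), 8L)
  expect_identical(length(ras$design@perturbedIds), 8L)
  myc <- simulateTrainingSet(smallConfig(), "MYC")
  expect_identical(ncol(myc$se), 14L)
  expect_identical(length(myc$design@perturbedIds), 6L)
  expect_true(all(ras$truth[ras$design@perturbedIds, "RAS"] == 1L))
  expect_true(all(ras$truth[, "MYC"] == 0L))
})

test_that("signature probes are shifted by the effect size in log2", {
  cfg <- smallConfig(seed = 11)
  ts <- simulateTrainingSet(cfg, "RAS")
  x <- log2(exprsMatrix(ts$se))
  sig <- signatureProbeIds(cfg, "RAS")
  diff <- rowMeans(x[sig, ts$design@perturbedIds]) -
    rowMeans(x[sig, ts$design@controlIds])
  # per-probe class-mean difference averages to effectSize; MC tolerance
  se <- cfg@replicateNoiseSd * sqrt(1 / 8 + 1 / 8) / sqrt(length(sig))
  expect_lt(abs(mean(diff) - cfg@effectSize), 3 * se)
  off <- setdiff(rownames(x), c(sig, unlist(controlProbePairs())))
  expect_lt(abs(mean(rowMeans(x[off, ts$design@perturbedIds]) -
                       rowMeans(x[off, ts$design@controlIds]))), 0.1)
})

test_that("a null effect size gives t statistics with a Student-t null", {
  cfg <- smallConfig(seed = 21, effectSize = 0)
  ts <- simulateTrainingSet(cfg, "RAS")
  x <- log2(exprsMatrix(ts$se))
  x <- x[setdiff(rownames(x), unlist(controlProbePairs())), ]
  tt <- apply(x, 1L, function(v)
    stats::t.test(v[ts$design@perturbedIds], v[ts$design@controlIds],
                  var.equal = TRUE)$statistic)
  # ~5% of |t| should exceed the t14 97.5% quantile
  frac <- mean(abs(tt) > stats::qt(0.975, df = 14))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("generators are pure functions of config and seed", {
  a <- simulateTrainingSet(smallConfig(seed = 4), "RAS")
  b <- simulateTrainingSet(smallConfig(seed = 4), "RAS")
  expect_identical(exprsMatrix(a$se), exprsMatrix(b$se))
  c <- simulateTrainingSet(smallConfig(seed = 5), "RAS")
  expect_false(identical(exprsMatrix(a$se), exprsMatrix(c$se)))

  xa <- simulateXenograftPairs(smallConfig(seed = 4), smallDegradation(seed = 2))
  xb <- simulateXenograftPairs(smallConfig(seed = 4), smallDegradation(seed = 2))
  expect_identical(exprsMatrix(xa$ffpe), exprsMatrix(xb$ffpe))
})

test_that("xenograft pairs follow the 5x5 design with valid pairing", {
  xg <- simulateXenograftPairs(smallConfig(seed = 6), smallDegradation(seed = 7))
  expect_identical(ncol(xg$ff), 25L)
  expect_identical(ncol(xg$ffpe), 25L)
  expect_identical(length(unique(xg$annotation$pair_id)), 25L)
  expect_identical(length(unique(xg$annotation$group_id)), 5L)
  # every pair_id links one FF and one FFPE sample
  expect_silent(pathsig:::checkAnnotation(xg$annotation))
  # both latent classes represented for each pathway
  expect_true(all(colSums(as.matrix(xg$truth[colnames(xg$ff), c("RAS", "MYC")])) %in% 5:20))
  expect_error(simulateXenograftPairs(smallConfig(), smallDegradation(),
                                      nLines = 0), ">= 1")
})

test_that("identity degradation returns the input exactly", {
  xg <- simulateXenograftPairs(smallConfig(seed = 8), identityDegradation())
  expect_identical(unname(exprsMatrix(xg$ffpe)), unname(exprsMatrix(xg$ff)))
  se <- makeExpressionSet(toyMatrix(10, 4) + 100)
  expect_error(applyFFPEDegradation(se, identityDegradation()),
               "control probes absent")
})

test_that("within-line fresh-frozen correlation exceeds between-line", {
  xg <- simulateXenograftPairs(smallConfig(seed = 9), identityDegradation())
  R <- stats::cor(log2(exprsMatrix(xg$ff)))
  line <- xg$annotation[colnames(xg$ff), "group_id"]
  same <- outer(line, line, "==") & upper.tri(R)
  diffl <- !outer(line, line, "==") & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diffl]))
})

test_that("five-prime control attenuation sets the geometric-mean ratio", {
  # constant matrix, severity and noise disabled: mean log2 ratio is exactly
  # checked against its Monte-Carlo expectation over many samples
  m <- 400L
  values <- matrix(10000, 50, m,
                   dimnames = list(c(unlist(controlProbePairs()),
                                     sprintf("p%02d", 1:46)),
                                   sprintf("s%03d", seq_len(m))))
  degr <- degradationConfig(severityLogSd = 0, dropoutRate = 0, seed = 31)
  out <- exprsMatrix(applyFFPEDegradation(makeExpressionSet(values), degr))
  for (pair in controlProbePairs()) {
    lr <- log2(out[pair[1], ] / out[pair[2], ])
    se <- stats::sd(lr) / sqrt(m)
    expect_lt(abs(mean(lr) - degr@fivePrimeExtraAttenuation), 3 * se)
  }
})

test_that("degradation preserves signature class separation", {
  # without dropout (and with a common severity) the per-probe class
  # difference is preserved exactly in expectation, because attenuation is
  # class-independent; checked within MC error
  cfg <- smallConfig(seed = 41)
  nodrop <- degradationConfig(dropoutRate = 0, severityLogSd = 0, seed = 42)
  xg <- simulateXenograftPairs(cfg, nodrop)
  sig <- signatureProbeIds(cfg, "RAS")
  act <- xg$truth[colnames(xg$ff), "RAS"] == 1L
  lff <- log2(exprsMatrix(xg$ff)[sig, ])
  lfp <- log2(exprsMatrix(xg$ffpe)[sig, ])
  dFF <- rowMeans(lff[, act]) - rowMeans(lff[, !act])
  dFFPE <- rowMeans(lfp[, act]) - rowMeans(lfp[, !act])
  mcse <- stats::sd(dFFPE - dFF) / sqrt(length(dFF))
  expect_lt(abs(mean(dFFPE) - mean(dFF)), 3 * mcse)

  # with default dropout the background floor absorbs part of the contrast
  # but most of the separation survives
  xg2 <- simulateXenograftPairs(cfg, smallDegradation(seed = 43))
  lfp2 <- log2(exprsMatrix(xg2$ffpe)[sig, ])
  dFFPE2 <- rowMeans(lfp2[, act]) - rowMeans(lfp2[, !act])
  expect_gt(mean(dFFPE2), cfg@effectSize / 2)
})

test_that("expected percent-present is monotone in the dropout rate", {
  # the dropout floor sits below the detection threshold, so percent
  # present can never increase with the rate; once the floored fraction
  # reaches the detection quantile it decreases strictly
  rates <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mean_pp <- sapply(rates, function(r) {
    mean(sapply(1:20, function(s) {
      xg <- simulateXenograftPairs(
        smallConfig(seed = 100 + s), nLines = 2L, nReplicates = 2L,
        degr = degradationConfig(dropoutRate = r, seed = 200 + s))
      mean(percentPresent(xg$ffpe, threshold = 60))
    }))
  })
  expect_true(all(diff(mean_pp) <= 1e-9))
  expect_lt(mean_pp[5], mean_pp[1])
})

test_that("patient lesion sets share latent activity within a patient", {
  pl <- simulatePatientLesions(smallConfig(seed = 51), smallDegradation(seed = 52))
  expect_identical(ncol(pl$ff), 18L)
  expect_identical(ncol(pl$ffpe), 6L)
  expect_identical(length(unique(pl$annotation$group_id)), 6L)
  tr <- pl$truth
  grp <- pl$annotation[tr$sample_id, "group_id"]
  for (p in c("RAS", "MYC")) {
    perPatient <- tapply(tr[[p]], grp, function(v) length(unique(v)))
    expect_true(all(perPatient == 1L))
  }
  # FFPE lesion is paired with the patient's first fresh lesion
  ann <- pl$annotation
  ffpePairs <- ann$pair_id[ann$preservation == "ffpe"]
  expect_identical(sort(ffpePairs),
                   sort(ann$pair_id[ann$preservation == "fresh_frozen" &
                                      !is.na(ann$pair_id)]))
  # single-lesion case reduces to the xenograft pairing structure
  one <- simulatePatientLesions(smallConfig(seed = 53), smallDegradation(seed = 54),
                                lesionsPerPatient = 1L)
  expect_identical(ncol(one$ff), 6L)
  expect_true(all(!is.na(one$annotation$pair_id)))
})

test_that("reamplification adds only assay noise", {
  cfg <- smallConfig(seed = 61)
  xg <- simulateXenograftPairs(cfg, identityDegradation())
  re <- simulateReamplification(xg$ff, cfg, seed = 62)
  d <- log2(exprsMatrix(re)) - log2(exprsMatrix(xg$ff))
  expect_lt(abs(mean(d)), 0.01)
  expect_lt(abs(stats::sd(d) - cfg@reamplificationNoiseSd), 0.01)
})
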