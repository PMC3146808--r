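pathwaysSupported <- c("RAS", "MYC")

#' Names of the 3'/5' control probe pairs
#'
#' Every generated matrix carries two dedicated control probe pairs emulating
#' the beta-actin and GAPDH 3'/5' QC probe sets of expression arrays.
#'
#' @return a named list of `c(probe_3p, probe_5p)` pairs.
#' @examples
#' controlProbePairs()
#' @export
controlProbePairs <- function() {
  list(ACTB = c("AFFX-ACTB-3", "AFFX-ACTB-5"),
       GAPDH = c("AFFX-GAPDH-3", "AFFX-GAPDH-5"))
}

# The probe universe implied by a SimulationConfig: probe ids, base log2
# abundances, and the (disjoint, deterministic) signature memberships.
# Depends only on universeSeed and the size parameters, so training and test
# sets generated under one config share their biology.
probeUniverse <- function(config) {
  ctrl <- unlist(controlProbePairs(), use.names = FALSE)
  nOther <- config@nProbes - length(ctrl)
  ids <- c(ctrl, sprintf("PS%05d_at", seq_len(nOther)))
  base <- withSeed(config@universeSeed,
                   stats::rnorm(nOther, config@baseLog2Mean, config@baseLog2Sd))
  baseLog2 <- c(rep(10, length(ctrl)), base)
  names(baseLog2) <- ids
  nsig <- config@nSignatureProbes
  sig <- list(
    RAS = ids[length(ctrl) + seq_len(nsig)],
    MYC = ids[length(ctrl) + nsig + seq_len(nsig)]
  )
  # uniform up-regulation: class-mean log2 difference = effectSize
  signs <- lapply(sig, function(p) {
    s <- rep(1, length(p))
    names(s) <- p
    s
  })
  list(probeIds = ids, baseLog2 = baseLog2, signatures = sig, signs = signs)
}

#' Signature probe membership of the simulated pathways
#'
#' @param config a [SimulationConfig-class].
#' @param pathway `"RAS"` or `"MYC"`.
#' @return character vector of the probes perturbed by that pathway.
#' @export
signatureProbeIds <- function(config, pathway = pathwaysSupported) {
  pathway <- match.arg(pathway)
  probeUniverse(config)$signatures[[pathway]]
}

# log2 shift vector applied to active samples of one pathway
activityShift <- function(universe, config, pathway) {
  delta <- numeric(length(universe$probeIds))
  names(delta) <- universe$probeIds
  sig <- universe$signatures[[pathway]]
  delta[sig] <- universe$signs[[pathway]] * config@effectSize
  delta
}

# Control 3'/5' rows for m samples: both members of a pair read the same
# housekeeping transcript, so abundance fluctuations are common-mode within
# the pair; only probe-set-level measurement noise (averaged over ~11 probe
# pairs, hence /sqrt(11)) differs between the 3' and 5' members.
controlRowValues <- function(m, config) {
  pairs <- controlProbePairs()
  out <- matrix(NA_real_, 2L * length(pairs), m)
  rownames(out) <- unlist(pairs, use.names = FALSE)
  for (pair in pairs) {
    common <- stats::rnorm(m, 0, config@replicateNoiseSd)
    for (p in pair)
      out[p, ] <- 10 + common +
        stats::rnorm(m, 0, config@replicateNoiseSd / sqrt(11))
  }
  out
}

truthFrame <- function(sampleIds, activity) {
  S4Vectors::DataFrame(sample_id = sampleIds,
                       RAS = as.integer(activity$RAS),
                       MYC = as.integer(activity$MYC),
                       row.names = sampleIds)
}

#' Simulate a two-class pathway training set
#'
#' Emulates the study's signature training design: control replicates
#' expressing a neutral insert versus replicates expressing the activated
#' oncogene (8 + 8 for RAS, 8 + 6 for MYC).  In perturbed samples the
#' pathway's signature probes are shifted up by `effectSize` log2 units;
#' every sample receives independent `replicateNoiseSd` log2 noise, with the
#' control 3'/5' probe pairs sharing common-mode abundance noise within each
#' pair (both members read the same transcript).  Deterministic given the config seeds.
#'
#' @param config a [SimulationConfig-class].
#' @param pathway `"RAS"` or `"MYC"`.
#' @param nControl,nPerturbed replicate counts; defaults are the study design.
#' @return list with elements `se` (expression `SummarizedExperiment`),
#'   `design` (a [TrainingDesign-class]) and `truth` (per-sample 0/1 activity
#'   for both pathways).
#' @examples
#' ts <- simulateTrainingSet(simulationConfig(nProbes = 400, seed = 1), "RAS")
#' dim(ts$se)
#' @export
simulateTrainingSet <- function(config, pathway = pathwaysSupported,
                                nControl = 8L,
                                nPerturbed = if (pathway == "MYC") 6L else 8L) {
  methods::validObject(config)
  pathway <- match.arg(pathway)
  if (nControl < 2L || nPerturbed < 2L)
    stop("each class needs at least 2 replicates")
  u <- probeUniverse(config)
  ctrlIds <- sprintf("GFP_%02d", seq_len(nControl))
  pertIds <- sprintf("%s_%02d", pathway, seq_len(nPerturbed))
  ids <- c(ctrlIds, pertIds)
  shift <- activityShift(u, config, pathway)
  log2x <- withSeed(config@seed + 1L, {
    noise <- matrix(stats::rnorm(length(u$probeIds) * length(ids),
                                 0, config@replicateNoiseSd),
                    length(u$probeIds), length(ids))
    x <- u$baseLog2 + noise + outer(shift, as.numeric(ids %in% pertIds))
    dimnames(x) <- list(u$probeIds, ids)
    ctrl <- controlRowValues(length(ids), config)
    x[rownames(ctrl), ] <- ctrl
    x
  })
  activity <- list(RAS = (pathway == "RAS") & ids %in% pertIds,
                   MYC = (pathway == "MYC") & ids %in% pertIds)
  ann <- S4Vectors::DataFrame(
    sample_id = ids,
    class_label = as.integer(ids %in% pertIds),
    group_id = NA_character_, pair_id = NA_character_,
    preservation = "cell_line", row.names = ids)
  list(se = makeExpressionSet(2^log2x, colData = ann),
       design = trainingDesign(pathway, ctrlIds, pertIds),
       truth = truthFrame(ids, activity))
}

#' Apply the FFPE degradation model to an expression matrix
#'
#' Degradation acts multiplicatively on the linear scale (additively in
#' log2).  Each non-control probe carries a truncated-normal log2
#' susceptibility shared across samples (probe-level degradation
#' susceptibility: a probe either measures degraded material tolerably or
#' it does not, consistently from array to array); each array carries a
#' log-normal severity multiplier (block-to-block variation in fixation
#' damage) scaling all its losses; every cell gains `extraNoiseSd` log2
#' noise.  Dropout is abundance-dependent: the weakest `dropoutRate`
#' fraction of degraded log2 signals collapses to a jittered background
#' level, so low-abundance and highly susceptible probes drop out first.
#'
#' Control 3'/5' probe pairs are treated as the probe-set averages they
#' emulate: their real counterparts summarize ~11 probe pairs of abundant
#' housekeeping transcripts, so they receive the deterministic mean
#' attenuation (no probe-level susceptibility draw), per-cell noise shrunk
#' by `sqrt(11)`, and no dropout; the 5' member loses
#' `fivePrimeExtraAttenuation` additional log2 units (times the array's
#' severity), so the geometric-mean 3'/5' ratio of an array with unit
#' severity is `2^fivePrimeExtraAttenuation`.  With all attenuation, noise
#' and dropout parameters zero the input is returned unchanged.
#'
#' @param se expression `SummarizedExperiment` (fresh-frozen profiles).
#' @param degr a [DegradationConfig-class].
#' @param controlPairs list of `c(probe_3p, probe_5p)` pairs present in `se`.
#' @return a degraded `SummarizedExperiment` with the same dimensions, sample
#'   ids unchanged (renaming is the caller's concern).
#' @export
applyFFPEDegradation <- function(se, degr, controlPairs = controlProbePairs()) {
  methods::validObject(degr)
  values <- exprsMatrix(se)
  ctrl <- unlist(controlPairs, use.names = FALSE)
  if (length(ctrl) && !all(ctrl %in% rownames(values)))
    stop("control probes absent from matrix: ",
         paste(setdiff(ctrl, rownames(values)), collapse = ", "))
  fivePrime <- vapply(controlPairs, `[`, character(1), 2L)
  n <- nrow(values); m <- ncol(values)
  out <- withSeed(degr@seed, {
    severity <- exp(stats::rnorm(m, 0, degr@severityLogSd))
    # truncated-normal probe susceptibility (inverse CDF; lower bound 0)
    att <- if (degr@attenuationLog2Sd > 0) {
      p0 <- stats::pnorm(0, degr@attenuationLog2Mean, degr@attenuationLog2Sd)
      stats::qnorm(stats::runif(n, p0, 1),
                   degr@attenuationLog2Mean, degr@attenuationLog2Sd)
    } else rep(degr@attenuationLog2Mean, n)
    isCtrl <- rownames(values) %in% ctrl
    att[isCtrl] <- degr@attenuationLog2Mean
    att[rownames(values) %in% fivePrime] <-
      degr@attenuationLog2Mean + degr@fivePrimeExtraAttenuation
    noiseSd <- rep(degr@extraNoiseSd, n)
    noiseSd[isCtrl] <- degr@extraNoiseSd / sqrt(11)
    noise <- if (degr@extraNoiseSd > 0)
      matrix(stats::rnorm(n * m, 0, noiseSd), n, m)
    else matrix(0, n, m)
    res <- values * 2^(noise - outer(att, severity))
    if (degr@dropoutRate > 0) {
      logRes <- log2(res[!isCtrl, , drop = FALSE])
      floorLevel <- stats::quantile(logRes, degr@dropoutRate, names = FALSE)
      drop <- matrix(FALSE, n, m)
      drop[!isCtrl, ] <- logRes < floorLevel
      res[drop] <- degr@backgroundLevel *
        2^stats::runif(sum(drop), -0.5, 0.5)
    }
    res
  })
  makeExpressionSet(out, colData = SummarizedExperiment::colData(se))
}

#' Simulate a repeat amplification of the same RNA
#'
#' Re-running the amplification assay on one RNA preparation shares all the
#' biology and differs only by assay noise: each cell gains independent
#' `reamplificationNoiseSd` log2 noise.
#'
#' @param se expression `SummarizedExperiment`.
#' @param config a [SimulationConfig-class] supplying the noise SD.
#' @param seed seed (defaults to a stream derived from the config seed).
#' @return a `SummarizedExperiment` of the same shape.
#' @export
simulateReamplification <- function(se, config,
                                    seed = deriveSeed(config@seed, "reamp")) {
  values <- exprsMatrix(se)
  out <- withSeed(seed, {
    values * 2^matrix(stats::rnorm(length(values), 0,
                                   config@reamplificationNoiseSd),
                      nrow(values), ncol(values))
  })
  makeExpressionSet(out, colData = SummarizedExperiment::colData(se))
}

# Balanced 0/1 latent activity assignment over groups: at least one active
# and one inactive group per pathway, order shuffled by the current RNG.
assignActivities <- function(nGroups) {
  lapply(stats::setNames(pathwaysSupported, pathwaysSupported), function(p) {
    a <- rep(c(1L, 0L), length.out = nGroups)
    sample(a)
  })
}

#' Simulate paired fresh-frozen / FFPE xenografts
#'
#' Emulates the paired xenograft design: `nLines` tumor cell lines injected
#' into `nReplicates` mice each (default 5 x 5 = 25 tumors).  Each line gets
#' a fixed latent activity per pathway (balanced across lines, shuffled by
#' seed) and a line-specific baseline (`biologicalSd`); each tumor adds
#' `replicateNoiseSd` noise.  Every tumor is split: the fresh-frozen half is
#' the tumor profile itself; the FFPE half is the same underlying profile
#' passed through [applyFFPEDegradation()].  `pair_id` links the halves.
#'
#' @param config a [SimulationConfig-class].
#' @param degr a [DegradationConfig-class].
#' @param nLines,nReplicates design size; both must be >= 1.
#' @return list with elements `ff`, `ffpe` (expression
#'   `SummarizedExperiment`s), `annotation` (`DataFrame` over all samples)
#'   and `truth` (per-sample latent activity).
#' @examples
#' xg <- simulateXenograftPairs(simulationConfig(nProbes = 400, seed = 2),
#'                              degradationConfig(seed = 3))
#' ncol(xg$ff)
#' @export
simulateXenograftPairs <- function(config, degr, nLines = 5L,
                                   nReplicates = 5L) {
  methods::validObject(config); methods::validObject(degr)
  if (nLines < 1L || nReplicates < 1L)
    stop("nLines and nReplicates must be >= 1")
  u <- probeUniverse(config)
  nP <- length(u$probeIds)
  lines <- sprintf("LINE%d", seq_len(nLines))
  tumor <- withSeed(config@seed + 2L, {
    act <- assignActivities(nLines)
    lineBase <- matrix(stats::rnorm(nP * nLines, 0, config@biologicalSd),
                       nP, nLines, dimnames = list(u$probeIds, lines))
    idx <- rep(seq_len(nLines), each = nReplicates)
    shift <- sapply(pathwaysSupported, function(p)
      activityShift(u, config, p))          # nP x 2
    log2x <- u$baseLog2 + lineBase[, idx] +
      shift %*% rbind(act$RAS[idx], act$MYC[idx]) +
      matrix(stats::rnorm(nP * length(idx), 0, config@replicateNoiseSd),
             nP, length(idx))
    rownames(log2x) <- u$probeIds
    ctrl <- controlRowValues(length(idx), config)
    log2x[rownames(ctrl), ] <- ctrl
    list(log2x = log2x, act = act, idx = idx)
  })
  nT <- nLines * nReplicates
  base <- sprintf("%s_R%d", lines[tumor$idx],
                  rep(seq_len(nReplicates), times = nLines))
  ffIds <- paste0(base, "_FF"); ffpeIds <- paste0(base, "_FFPE")
  pairIds <- sprintf("P%02d", seq_len(nT))
  x <- tumor$log2x
  dimnames(x) <- list(u$probeIds, ffIds)
  ffAnn <- S4Vectors::DataFrame(
    sample_id = ffIds, class_label = NA_integer_,
    group_id = lines[tumor$idx], pair_id = pairIds,
    preservation = "fresh_frozen", row.names = ffIds)
  ff <- makeExpressionSet(2^x, colData = ffAnn)
  ffpe <- applyFFPEDegradation(ff, degr)
  colnames(ffpe) <- ffpeIds
  ffpeAnn <- S4Vectors::DataFrame(
    sample_id = ffpeIds, class_label = NA_integer_,
    group_id = lines[tumor$idx], pair_id = pairIds,
    preservation = "ffpe", row.names = ffpeIds)
  SummarizedExperiment::colData(ffpe) <- ffpeAnn
  act <- list(RAS = tumor$act$RAS[tumor$idx], MYC = tumor$act$MYC[tumor$idx])
  truth <- rbind(truthFrame(ffIds, act), truthFrame(ffpeIds, act))
  list(ff = ff, ffpe = ffpe,
       annotation = rbind(ffAnn, ffpeAnn), truth = truth)
}

#' Simulate patient lesion sets with one FFPE lesion per patient
#'
#' Emulates the melanoma patient design: `nPatients` patients each
#' contribute `lesionsPerPatient` fresh-frozen in-transit lesions plus one
#' FFPE lesion.  All lesions of a patient share the patient's latent pathway
#' activity and baseline (`biologicalSd`); lesions add `replicateNoiseSd`
#' noise; the FFPE lesion is the degraded copy of the patient's first fresh
#' lesion and is linked to it by `pair_id`.
#'
#' @param config a [SimulationConfig-class].
#' @param degr a [DegradationConfig-class].
#' @param nPatients,lesionsPerPatient design size; both must be >= 1.
#' @return list with elements `ff`, `ffpe`, `annotation`, `truth` as in
#'   [simulateXenograftPairs()].
#' @export
simulatePatientLesions <- function(config, degr, nPatients = 6L,
                                   lesionsPerPatient = 3L) {
  methods::validObject(config); methods::validObject(degr)
  if (nPatients < 1L || lesionsPerPatient < 1L)
    stop("nPatients and lesionsPerPatient must be >= 1")
  u <- probeUniverse(config)
  nP <- length(u$probeIds)
  patients <- sprintf("PT%d", seq_len(nPatients))
  sim <- withSeed(config@seed + 3L, {
    act <- assignActivities(nPatients)
    ptBase <- matrix(stats::rnorm(nP * nPatients, 0, config@biologicalSd),
                     nP, nPatients, dimnames = list(u$probeIds, patients))
    idx <- rep(seq_len(nPatients), each = lesionsPerPatient)
    shift <- sapply(pathwaysSupported, function(p)
      activityShift(u, config, p))
    log2x <- u$baseLog2 + ptBase[, idx] +
      shift %*% rbind(act$RAS[idx], act$MYC[idx]) +
      matrix(stats::rnorm(nP * length(idx), 0, config@replicateNoiseSd),
             nP, length(idx))
    rownames(log2x) <- u$probeIds
    ctrl <- controlRowValues(length(idx), config)
    log2x[rownames(ctrl), ] <- ctrl
    list(log2x = log2x, act = act, idx = idx)
  })
  ffIds <- sprintf("%s_L%d_FF", patients[sim$idx],
                   rep(seq_len(lesionsPerPatient), times = nPatients))
  dimnames(sim$log2x) <- list(u$probeIds, ffIds)
  firstLesion <- ffIds[match(seq_len(nPatients), sim$idx)]
  pairIds <- sprintf("PP%02d", seq_len(nPatients))
  ffAnn <- S4Vectors::DataFrame(
    sample_id = ffIds, class_label = NA_integer_,
    group_id = patients[sim$idx], pair_id = NA_character_,
    preservation = "fresh_frozen", row.names = ffIds)
  # pair_id only on the first lesion of each patient
  ffAnn$pair_id[match(firstLesion, ffIds)] <- pairIds
  ff <- makeExpressionSet(2^sim$log2x, colData = ffAnn)
  ffpe <- applyFFPEDegradation(ff[, firstLesion], degr)
  ffpeIds <- sprintf("%s_FFPE", patients)
  colnames(ffpe) <- ffpeIds
  ffpeAnn <- S4Vectors::DataFrame(
    sample_id = ffpeIds, class_label = NA_integer_,
    group_id = patients, pair_id = pairIds,
    preservation = "ffpe", row.names = ffpeIds)
  SummarizedExperiment::colData(ffpe) <- ffpeAnn
  act <- list(RAS = sim$act$RAS[sim$idx], MYC = sim$act$MYC[sim$idx])
  actPt <- list(RAS = sim$act$RAS, MYC = sim$act$MYC)
  truth <- rbind(truthFrame(ffIds, act), truthFrame(ffpeIds, actPt))
  list(ff = ff, ffpe = ffpe,
       annotation = rbind(ffAnn, ffpeAnn), truth = truth)
}
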