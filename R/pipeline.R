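summaryFormatTag <- "pathsig-summary/1"

#' Configuration of a full synthetic study run
#'
#' Bundles every parameter of [runPipeline()]: the simulation and
#' degradation configurations (with all sub-seeds derived deterministically
#' from one master seed), signature settings per pathway, and the
#' concordance/QC settings.
#'
#' @param masterSeed integer master seed; every stage seed is derived from
#'   it with [deriveSeed()].
#' @param nProbes probe universe size.
#' @param effectSize perturbation effect size (log2).
#' @param nSignatureProbes probes perturbed per pathway in the generator.
#' @param signatureSize number of probes selected per fitted signature.
#' @param k metagene factors per signature.
#' @param nIter,burnIn,priorSd Gibbs sampler settings.
#' @param normalization test normalization mode, see [projectSamples()];
#'   the pipeline defaults to `"arrayscale"` with absent-call masking at the
#'   percent-present detection threshold, which is robust to the global
#'   signal loss of degraded arrays.
#' @param concordanceThreshold per-patient concordance threshold.
#' @param sdFilterSize probes kept by the SD filter before clustering.
#' @param degradation a [DegradationConfig-class]; its seed is overridden per
#'   stage.
#' @param generator a [SimulationConfig-class]; its seeds are overridden per
#'   stage (`universeSeed` from the master seed, so every generated set
#'   shares one probe universe).
#' @return a named list, the run configuration.
#' @export
pipelineConfig <- function(masterSeed = 1L,
                           nProbes = 10000L,
                           effectSize = 2.0,
                           nSignatureProbes = 150L,
                           signatureSize = 150L,
                           k = 3L,
                           nIter = 11000L,
                           burnIn = 1000L,
                           priorSd = 10,
                           normalization = c("arrayscale", "standardize",
                                             "quantile"),
                           concordanceThreshold = 0.3,
                           sdFilterSize = 1000L,
                           degradation = degradationConfig(),
                           generator = simulationConfig(
                             nProbes = nProbes,
                             nSignatureProbes = nSignatureProbes,
                             effectSize = effectSize)) {
  generator@universeSeed <- deriveSeed(masterSeed, "universe")
  list(masterSeed = as.integer(masterSeed),
       generator = generator,
       degradation = degradation,
       signatureSize = as.integer(signatureSize),
       k = as.integer(k),
       nIter = as.integer(nIter),
       burnIn = as.integer(burnIn),
       priorSd = priorSd,
       normalization = match.arg(normalization),
       concordanceThreshold = concordanceThreshold,
       sdFilterSize = as.integer(sdFilterSize),
       presentThreshold = 2 * degradation@backgroundLevel)
}

stageLog <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

# reseeded copies of the configs for one pipeline stage
stageGenerator <- function(config, stage) {
  g <- config$generator
  g@seed <- deriveSeed(config$masterSeed, stage)
  g
}
stageDegradation <- function(config, stage) {
  d <- config$degradation
  d@seed <- deriveSeed(config$masterSeed, stage)
  d
}

#' Run the full synthetic study end-to-end
#'
#' Simulates training sets, paired fresh-frozen/FFPE xenografts (plus a
#' re-amplification of each fresh-frozen profile) and patient lesion sets;
#' computes QC reports; builds RAS and MYC signatures; predicts pathway
#' activity in every test set; and runs the concordance analyses
#' (matched/unmatched correlations, SD-filtered clustering, PCA, prediction
#' scatter correlations, per-patient concordance).  All artifacts are
#' written as plain-text files under `outdir` and a machine-readable summary
#' is written to `summary.json`.  Identical configurations yield
#' byte-identical outputs.
#'
#' @param config a configuration from [pipelineConfig()].
#' @param outdir output directory (created if missing).
#' @return the summary, invisibly (also written as JSON).
#' @export
runPipeline <- function(config, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pth <- function(...) file.path(outdir, paste0(...))
  report <- list(format = summaryFormatTag, master_seed = config$masterSeed)

  stageLog("stage simulate: training sets")
  training <- lapply(stats::setNames(pathwaysSupported, pathwaysSupported),
    function(p) {
      ts <- simulateTrainingSet(stageGenerator(config, paste0("train-", p)), p)
      writeExpressionMatrix(ts$se, pth("training_", p, ".tsv"))
      ts
    })

  stageLog("stage simulate: xenograft pairs + re-amplification")
  xg <- simulateXenograftPairs(stageGenerator(config, "xeno"),
                               stageDegradation(config, "xeno-degr"))
  reamp <- simulateReamplification(xg$ff, config$generator,
                                   seed = deriveSeed(config$masterSeed, "reamp"))
  colnames(reamp) <- sub("_FF$", "_RE", colnames(reamp))
  writeExpressionMatrix(xg$ff, pth("xenograft_ff.tsv"))
  writeExpressionMatrix(xg$ffpe, pth("xenograft_ffpe.tsv"))
  writeExpressionMatrix(reamp, pth("xenograft_reamplified.tsv"))
  writeSampleAnnotation(xg$annotation, pth("xenograft_annotation.tsv"))
  writeGroundTruth(xg$truth, pth("xenograft_truth.tsv"))

  stageLog("stage simulate: patient lesions")
  pat <- simulatePatientLesions(stageGenerator(config, "patients"),
                                stageDegradation(config, "patients-degr"))
  writeExpressionMatrix(pat$ff, pth("patient_ff.tsv"))
  writeExpressionMatrix(pat$ffpe, pth("patient_ffpe.tsv"))
  writeSampleAnnotation(pat$annotation, pth("patient_annotation.tsv"))
  writeGroundTruth(pat$truth, pth("patient_truth.tsv"))

  stageLog("stage qc")
  qcFF <- qcReport(xg$ff, threshold = config$presentThreshold)
  qcFFPE <- qcReport(xg$ffpe, threshold = config$presentThreshold)
  writeQCReport(qcFF, pth("qc_xenograft_ff.tsv"))
  writeQCReport(qcFFPE, pth("qc_xenograft_ffpe.tsv"))
  report$qc <- list(
    ff = qcSummaryRow(qcFF), ffpe = qcSummaryRow(qcFFPE))

  stageLog("stage build-signature")
  sigs <- lapply(training, function(ts) {
    sig <- buildSignature(ts$se, ts$design,
                          nProbes = config$signatureSize, k = config$k,
                          priorSd = config$priorSd, nIter = config$nIter,
                          burnIn = config$burnIn,
                          seed = deriveSeed(config$masterSeed,
                                            paste0("mcmc-", ts$design@pathway)))
    writeSignature(sig, pth("signature_", ts$design@pathway, ".json"))
    sig
  })

  stageLog("stage predict")
  mode <- config$normalization
  thr <- config$presentThreshold
  pred <- list()
  for (p in pathwaysSupported) {
    pred[[p]] <- list(
      xeno_ff = predictActivity(sigs[[p]], xg$ff, mode = mode,
                                absentThreshold = thr),
      xeno_ffpe = predictActivity(sigs[[p]], xg$ffpe, mode = mode,
                                  absentThreshold = thr),
      pat_ff = predictActivity(sigs[[p]], pat$ff, mode = mode,
                               absentThreshold = thr),
      pat_ffpe = predictActivity(sigs[[p]], pat$ffpe, mode = mode,
                                 absentThreshold = thr))
    for (nm in names(pred[[p]])) {
      utils::write.table(as.data.frame(pred[[p]][[nm]]),
                         pth("predictions_", p, "_", nm, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  stageLog("stage concordance: whole-genome correlations")
  ffIds <- colnames(xg$ff)
  concReamp <- matchedUnmatched(
    xg$ff, reamp, pairing = stats::setNames(colnames(reamp), ffIds))
  concFFPE <- matchedUnmatched(xg$ff, xg$ffpe)
  writeConcordance(concReamp, pth("correlations_ff_vs_reamplified.tsv"))
  writeConcordance(concFFPE, pth("correlations_ff_vs_ffpe.tsv"))
  report$whole_genome <- list(
    ff_vs_reamplified = summary(concReamp),
    ff_vs_ffpe = summary(concFFPE))

  stageLog("stage concordance: clustering + PCA")
  combined <- makeExpressionSet(
    cbind(exprsMatrix(xg$ff), exprsMatrix(xg$ffpe)),
    colData = rbind(SummarizedExperiment::colData(xg$ff),
                    SummarizedExperiment::colData(xg$ffpe)))
  hc <- clusterSamples(sdFilterAndCenter(combined, config$sdFilterSize))
  writeDendrogram(hc, pth("dendrogram_ff_ffpe.nwk"))
  rootSplit <- stats::cutree(hc, k = 2L)
  pres <- stats::setNames(combined$preservation, colnames(combined))
  tab <- table(rootSplit, pres[names(rootSplit)])
  splitMatches <- nrow(tab) == 2L &&
    all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
  pca <- pcaScores(combined, nComponents = 2L)
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), pca$scores,
               check.names = FALSE),
    pth("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  report$clustering <- list(
    root_split_separates_preservation = splitMatches,
    pc_variance_explained = as.numeric(pca$varianceExplained))

  stageLog("stage concordance: prediction correlations + patients")
  report$predictions <- list()
  for (p in pathwaysSupported) {
    pairFF <- pred[[p]]$xeno_ff$probability
    names(pairFF) <- xg$annotation[colnames(xg$ff), "pair_id"]
    pairFFPE <- pred[[p]]$xeno_ffpe$probability
    names(pairFFPE) <- xg$annotation[colnames(xg$ffpe), "pair_id"]
    ct <- pearsonWithPValue(pairFF, pairFFPE[names(pairFF)])
    ffGroups <- split(pred[[p]]$pat_ff$probability,
                      pat$annotation[colnames(pat$ff), "group_id"])
    ffpeProb <- stats::setNames(pred[[p]]$pat_ffpe$probability,
                                pat$annotation[colnames(pat$ffpe), "group_id"])
    pc <- patientConcordance(ffGroups, ffpeProb,
                             threshold = config$concordanceThreshold)
    utils::write.table(as.data.frame(pc$perPatient),
                       pth("patient_concordance_", p, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$predictions[[p]] <- list(
      xenograft_ff_ffpe_r = ct$r,
      xenograft_ff_ffpe_p = ct$p,
      n_pairs = ct$n,
      patient_concordance_rate = pc$summary$concordance_rate,
      patient_mean_difference = pc$summary$mean_difference,
      patient_difference_range = as.numeric(pc$summary$difference_range))
  }

  jsonlite::write_json(report, pth("summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  stageLog("pipeline complete: ", pth("summary.json"))
  invisible(report)
}

writeGroundTruth <- function(truth, path) {
  df <- as.data.frame(truth)
  long <- do.call(rbind, lapply(pathwaysSupported, function(p)
    data.frame(sample_id = df$sample_id, pathway = p, activity = df[[p]])))
  long <- long[order(long$sample_id, long$pathway), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeQCReport <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeConcordance <- function(conc, path) {
  df <- rbind(
    data.frame(pair = names(matchedR(conc)), type = "matched",
               r = unname(matchedR(conc))),
    data.frame(pair = names(unmatchedR(conc)), type = "unmatched",
               r = unname(unmatchedR(conc))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

qcSummaryRow <- function(report) {
  list(
    percent_present_mean = mean(report$percent_present),
    percent_present_range = as.numeric(range(report$percent_present)),
    scaling_factor_mean = mean(report$scaling_factor),
    scaling_factor_range = as.numeric(range(report$scaling_factor)),
    ratio_3p5p_actb_range = as.numeric(range(report$ratio_3p5p_ACTB)),
    ratio_3p5p_gapdh_range = as.numeric(range(report$ratio_3p5p_GAPDH)))
}
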