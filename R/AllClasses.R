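#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Simulation parameters for synthetic expression studies
#'
#' Container for the parameters of the synthetic-data generator: the probe
#' universe (size, base log2 abundance distribution, which probes carry each
#' pathway signature), the perturbation effect size, and the noise components
#' at the replicate, re-amplification and biological (cell line / patient)
#' levels.  All values are on the log2 scale except `nProbes` and
#' `nSignatureProbes`.
#'
#' Two seeds are carried: `universeSeed` fixes the probe universe (base
#' abundances and signature memberships) so that independently generated
#' training and test sets describe the same biology, while `seed` drives the
#' sample-level randomness of a single generated data set.
#'
#' @slot nProbes number of probes, including the four 3'/5' control probes.
#' @slot nSignatureProbes probes perturbed per pathway.
#' @slot effectSize log2 mean shift of signature probes in perturbed samples.
#' @slot baseLog2Mean,baseLog2Sd distribution of probe base abundances.
#' @slot replicateNoiseSd per-replicate measurement/biology noise.
#' @slot reamplificationNoiseSd assay noise of a repeated amplification of the
#'   same RNA.
#' @slot biologicalSd between-group (cell line or patient) baseline variation.
#' @slot universeSeed seed for the probe universe.
#' @slot seed seed for sample-level randomness.
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nProbes = "integer",
    nSignatureProbes = "integer",
    effectSize = "numeric",
    baseLog2Mean = "numeric",
    baseLog2Sd = "numeric",
    replicateNoiseSd = "numeric",
    reamplificationNoiseSd = "numeric",
    biologicalSd = "numeric",
    universeSeed = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nProbes < 8L)
    msg <- c(msg, "nProbes must be at least 8 (4 control probes + signatures)")
  if (2L * object@nSignatureProbes + 4L > object@nProbes)
    msg <- c(msg, "two disjoint signatures plus control probes must fit in nProbes")
  sds <- c(object@baseLog2Sd, object@replicateNoiseSd,
           object@reamplificationNoiseSd, object@biologicalSd)
  if (any(sds < 0)) msg <- c(msg, "all standard deviations must be >= 0")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FFPE degradation model parameters
#'
#' Parameters of the formalin-fixation degradation model applied to a
#' fresh-frozen expression profile: probe-level signal attenuation (a
#' truncated-normal log2 loss shared across samples, modelling probe
#' degradation susceptibility), a per-sample degradation severity multiplier,
#' additional per-cell log2 noise, abundance-dependent dropout to a
#' background level (the weakest `dropoutRate` fraction of degraded signals
#' collapses), and an extra attenuation of the 5' members of the 3'/5'
#' control probe pairs (reverse transcription initiates at the 3' end, so 5'
#' signal is lost first as RNA fragments).
#'
#' @slot attenuationLog2Mean mean per-probe log2 signal loss.
#' @slot attenuationLog2Sd probe-to-probe SD of the loss (truncated at 0).
#' @slot severityLogSd SD of the log of the per-sample severity multiplier
#'   applied to all attenuation on a sample's array.
#' @slot dropoutRate marginal probability that a probe's signal collapses to
#'   background in a given sample; the lowest `dropoutRate` fraction of
#'   degraded log2 signals is floored, so dropout preferentially hits
#'   low-abundance and degradation-susceptible probes.
#' @slot backgroundLevel linear intensity around which dropped probes land.
#' @slot extraNoiseSd additional per-cell log2 noise.
#' @slot fivePrimeExtraAttenuation extra log2 loss of 5' control probes.
#' @slot seed seed for the degradation randomness.
#' @seealso [degradationConfig()], [applyFFPEDegradation()]
#' @export
setClass("DegradationConfig",
  representation(
    attenuationLog2Mean = "numeric",
    attenuationLog2Sd = "numeric",
    severityLogSd = "numeric",
    dropoutRate = "numeric",
    backgroundLevel = "numeric",
    extraNoiseSd = "numeric",
    fivePrimeExtraAttenuation = "numeric",
    seed = "integer"
  )
)

setValidity("DegradationConfig", function(object) {
  msg <- character()
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1]")
  if (object@backgroundLevel <= 0)
    msg <- c(msg, "backgroundLevel must be > 0")
  if (object@attenuationLog2Mean < 0)
    msg <- c(msg, "attenuationLog2Mean must be >= 0")
  if (object@attenuationLog2Sd < 0 || object@extraNoiseSd < 0 ||
      object@severityLogSd < 0)
    msg <- c(msg, "attenuation / severity / noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Two-class training design
#'
#' Identifies the control and perturbed samples of one pathway's training set
#' (e.g. GFP-infected controls versus RAS- or MYC-expressing replicates).
#'
#' @slot pathway pathway name.
#' @slot controlIds,perturbedIds disjoint, non-empty sample-id vectors.
#' @seealso [trainingDesign()]
#' @export
setClass("TrainingDesign",
  representation(
    pathway = "character",
    controlIds = "character",
    perturbedIds = "character"
  )
)

setValidity("TrainingDesign", function(object) {
  msg <- character()
  if (length(object@pathway) != 1L || !nzchar(object@pathway))
    msg <- c(msg, "pathway must be a single non-empty string")
  if (!length(object@controlIds) || !length(object@perturbedIds))
    msg <- c(msg, "both classes must be non-empty")
  if (length(intersect(object@controlIds, object@perturbedIds)))
    msg <- c(msg, "controlIds and perturbedIds must be disjoint")
  if (anyDuplicated(object@controlIds) || anyDuplicated(object@perturbedIds))
    msg <- c(msg, "sample ids within a class must be unique")
  if (length(msg)) msg else TRUE
})

#' Fitted pathway-activity signature
#'
#' A pathway signature couples the selected discriminative probes, their SVD
#' metagene basis, the posterior draws of the Bayesian probit regression on
#' the metagene factors, and the training normalization statistics needed to
#' project new samples.
#'
#' @slot pathway pathway name.
#' @slot probeIds the signature's probes, in selection (ranking) order.
#' @slot loadings probes x k matrix of left singular vectors (orthonormal
#'   columns, sign-fixed so each column's largest-magnitude entry is positive).
#' @slot singularValues the k singular values.
#' @slot k number of metagene factors.
#' @slot trainingFactors k x n_train factor scores of the training samples.
#' @slot trainingIds,trainingLabels training sample ids and 0/1 class labels.
#' @slot draws post-burn-in posterior draws, M x (k+1): intercept then the k
#'   factor coefficients.
#' @slot burnIn,priorSd,seed Gibbs sampler settings used for the fit.
#' @slot trainProbeMeans,trainProbeSds per-probe log2 mean and SD over the
#'   training samples (SD floored away from zero), used to normalize test
#'   samples.
#' @slot trainPooledLog2 sorted pooled training log2 values of the signature
#'   probes, the reference distribution of the quantile normalization mode.
#' @slot trainArrayMean,trainArraySd mean and SD of the pooled log2 values of
#'   the whole training array (all probes, all training samples).
#' @slot trainArrayProbeMeans per-probe log2 means over the training samples
#'   for every probe of the training array (not just the signature's), the
#'   reference of the array-scaling normalization mode.
#' @seealso [buildSignature()], [predictActivity()]
#' @export
setClass("PathwaySignature",
  representation(
    pathway = "character",
    probeIds = "character",
    loadings = "matrix",
    singularValues = "numeric",
    k = "integer",
    trainingFactors = "matrix",
    trainingIds = "character",
    trainingLabels = "integer",
    draws = "matrix",
    burnIn = "integer",
    priorSd = "numeric",
    seed = "integer",
    trainProbeMeans = "numeric",
    trainProbeSds = "numeric",
    trainPooledLog2 = "numeric",
    trainArrayMean = "numeric",
    trainArraySd = "numeric",
    trainArrayProbeMeans = "numeric"
  )
)

setValidity("PathwaySignature", function(object) {
  msg <- character()
  p <- length(object@probeIds)
  k <- object@k
  if (anyDuplicated(object@probeIds)) msg <- c(msg, "duplicate signature probes")
  if (!identical(dim(object@loadings), c(p, as.integer(k))))
    msg <- c(msg, "loadings must be |probeIds| x k")
  if (length(object@singularValues) != k || any(object@singularValues < 0))
    msg <- c(msg, "need k non-negative singular values")
  ortho <- crossprod(object@loadings)
  if (max(abs(ortho - diag(k))) > 1e-8)
    msg <- c(msg, "loading columns must be orthonormal (tol 1e-8)")
  if (nrow(object@trainingFactors) != k)
    msg <- c(msg, "trainingFactors must have k rows")
  if (ncol(object@trainingFactors) != length(object@trainingIds))
    msg <- c(msg, "trainingFactors must have one column per training sample")
  if (!all(object@trainingLabels %in% c(0L, 1L)))
    msg <- c(msg, "trainingLabels must be 0/1")
  if (ncol(object@draws) != k + 1L)
    msg <- c(msg, "draws must have k+1 columns (intercept + coefficients)")
  if (nrow(object@draws) < 1L || !all(is.finite(object@draws)))
    msg <- c(msg, "posterior draws must be non-empty and finite")
  if (length(object@trainProbeMeans) != p || length(object@trainProbeSds) != p)
    msg <- c(msg, "training normalization statistics must cover every probe")
  if (any(object@trainProbeSds <= 0))
    msg <- c(msg, "trainProbeSds must be > 0")
  if (length(object@trainArraySd) != 1L || object@trainArraySd <= 0)
    msg <- c(msg, "trainArraySd must be a single positive value")
  if (!length(object@trainArrayProbeMeans) ||
      is.null(names(object@trainArrayProbeMeans)))
    msg <- c(msg, "trainArrayProbeMeans must be a named per-probe vector")
  if (length(msg)) msg else TRUE
})

#' Matched versus unmatched correlation result
#'
#' Pearson correlations of whole-genome log2 expression between two sample
#' sets: one coefficient per annotated pair ("matched") and one for every
#' other cross combination ("unmatched").
#'
#' @slot matchedR named vector, one correlation per pair id.
#' @slot unmatchedR named vector over all non-pair cross combinations.
#' @seealso [matchedUnmatched()]
#' @export
setClass("ConcordanceResult",
  representation(matchedR = "numeric", unmatchedR = "numeric")
)

setValidity("ConcordanceResult", function(object) {
  r <- c(object@matchedR, object@unmatchedR)
  if (length(r) && any(r < -1 - 1e-12 | r > 1 + 1e-12))
    "correlations must lie in [-1, 1]"
  else TRUE
})
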