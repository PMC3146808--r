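#' Create a simulation configuration
#'
#' Defaults describe a down-scaled U133A-like study: 10,000 probes (including
#' the two 3'/5' control probe pairs), 150 signature probes per pathway with a
#' 2.0 log2-unit perturbation effect, probe base abundances around
#' `Normal(7, 2)` on the log2 scale (the SD matches the dynamic range of
#' MAS5-scale arrays, whose 5th-95th signal percentiles span roughly 7 log2
#' units), replicate noise SD 0.3, re-amplification assay noise SD 0.15 and
#' between-line/patient biological SD 0.3 (so that whole-genome correlations
#' between unrelated fresh-frozen profiles fall in the low 0.9s, as observed
#' between arrays of distinct tumor lines).
#'
#' @param nProbes total probe count (the U133A 2.0 array has 22,277).
#' @param nSignatureProbes probes perturbed per pathway.
#' @param effectSize log2 mean shift in perturbed samples.
#' @param baseLog2Mean,baseLog2Sd probe base abundance distribution (log2).
#' @param replicateNoiseSd per-replicate log2 noise.
#' @param reamplificationNoiseSd log2 noise of re-amplifying the same RNA.
#' @param biologicalSd between-group (line/patient) baseline log2 SD.
#' @param universeSeed seed fixing the probe universe shared by all data sets
#'   generated under one configuration.
#' @param seed seed for sample-level randomness.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 11)
#' @export
simulationConfig <- function(nProbes = 10000L,
                             nSignatureProbes = 150L,
                             effectSize = 2.0,
                             baseLog2Mean = 7.0,
                             baseLog2Sd = 2.0,
                             replicateNoiseSd = 0.3,
                             reamplificationNoiseSd = 0.15,
                             biologicalSd = 0.3,
                             universeSeed = 20111L,
                             seed = 1L) {
  new("SimulationConfig",
      nProbes = as.integer(nProbes),
      nSignatureProbes = as.integer(nSignatureProbes),
      effectSize = as.numeric(effectSize),
      baseLog2Mean = as.numeric(baseLog2Mean),
      baseLog2Sd = as.numeric(baseLog2Sd),
      replicateNoiseSd = as.numeric(replicateNoiseSd),
      reamplificationNoiseSd = as.numeric(reamplificationNoiseSd),
      biologicalSd = as.numeric(biologicalSd),
      universeSeed = as.integer(universeSeed),
      seed = as.integer(seed))
}

#' Create an FFPE degradation configuration
#'
#' Defaults are calibrated so that degraded synthetic arrays reproduce the
#' qualitative QC shifts of real FFPE arrays relative to their fresh-frozen
#' partners: depressed percent-present calls, inflated scaling factors, and
#' 3'/5' control ratios well above the conventional quality cutoff of 3.
#'
#' @param attenuationLog2Mean mean per-probe log2 signal loss.
#' @param attenuationLog2Sd probe-to-probe SD of the loss (truncated at 0 so
#'   degradation never amplifies signal).
#' @param severityLogSd SD of the log of the per-sample severity multiplier
#'   (block-to-block variation in fixation damage).
#' @param dropoutRate marginal per-cell probability of collapse to
#'   background; the weakest signals collapse first.
#' @param backgroundLevel linear intensity of dropped probes (jittered).
#' @param extraNoiseSd additional per-cell log2 noise.
#' @param fivePrimeExtraAttenuation extra log2 loss of 5' control probes; the
#'   implied geometric-mean 3'/5' ratio is `2^fivePrimeExtraAttenuation`.
#' @param seed seed for the degradation randomness.
#' @return a [DegradationConfig-class] object.
#' @examples
#' degradationConfig(seed = 7)
#' @export
degradationConfig <- function(attenuationLog2Mean = 2.0,
                              attenuationLog2Sd = 1.0,
                              severityLogSd = 0.15,
                              dropoutRate = 0.35,
                              backgroundLevel = 30,
                              extraNoiseSd = 0.5,
                              fivePrimeExtraAttenuation = 3.0,
                              seed = 1L) {
  new("DegradationConfig",
      attenuationLog2Mean = as.numeric(attenuationLog2Mean),
      attenuationLog2Sd = as.numeric(attenuationLog2Sd),
      severityLogSd = as.numeric(severityLogSd),
      dropoutRate = as.numeric(dropoutRate),
      backgroundLevel = as.numeric(backgroundLevel),
      extraNoiseSd = as.numeric(extraNoiseSd),
      fivePrimeExtraAttenuation = as.numeric(fivePrimeExtraAttenuation),
      seed = as.integer(seed))
}

#' Create a two-class training design
#'
#' @param pathway pathway name (e.g. `"RAS"`).
#' @param controlIds,perturbedIds disjoint non-empty sample-id vectors.
#' @return a [TrainingDesign-class] object.
#' @examples
#' trainingDesign("RAS", paste0("GFP_", 1:8), paste0("RAS_", 1:8))
#' @export
trainingDesign <- function(pathway, controlIds, perturbedIds) {
  new("TrainingDesign",
      pathway = as.character(pathway),
      controlIds = as.character(controlIds),
      perturbedIds = as.character(perturbedIds))
}

#' Derive a deterministic stage seed from a master seed
#'
#' Mixes a master seed with a stage label so that pipeline stages draw from
#' reproducible, independent random streams and can be rerun in isolation.
#' The result is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @examples
#' deriveSeed(1, "xenografts")
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- (as.double(master) %% 2147483647) * 48271
  for (v in utf8ToInt(stage)) h <- (h * 69621 + v * 16807) %% 2147483647
  as.integer(h %% 2147483562 + 1)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
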