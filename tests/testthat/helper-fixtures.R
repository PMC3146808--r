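# Small simulation settings used throughout the unit tests; acceptance tests
# use the package defaults (the full study conditions).
smallConfig <- function(seed = 1L, ...) {
  simulationConfig(nProbes = 500L, nSignatureProbes = 40L, seed = seed, ...)
}

smallDegradation <- function(seed = 1L, ...) {
  degradationConfig(seed = seed, ...)
}

identityDegradation <- function(seed = 1L) {
  degradationConfig(attenuationLog2Mean = 0, attenuationLog2Sd = 0,
                    severityLogSd = 0, dropoutRate = 0, extraNoiseSd = 0,
                    fivePrimeExtraAttenuation = 0, seed = seed)
}

# tiny named expression matrix with all values positive
toyMatrix <- function(nr = 3L, nc = 2L, seed = 99L) {
  set.seed(seed)
  matrix(2^rnorm(nr * nc, 7, 1), nr, nc,
         dimnames = list(sprintf("p%02d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

# quick signature build with reduced MCMC for unit tests
quickSignature <- function(ts, nProbes = 30L, k = 2L, seed = 5L, ...) {
  # short chains trip the Geweke convergence warning by design; irrelevant
  # for the structural properties these fixtures support
  suppressWarnings(
    buildSignature(ts$se, ts$design, nProbes = nProbes, k = k,
                   nIter = 1500L, burnIn = 500L, seed = seed, ...))
}
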