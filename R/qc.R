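#' Percent-present calls
#'
#' Fraction of probes per sample whose intensity exceeds a detection
#' threshold, expressed in percent.  A simple intensity cutoff stands in for
#' probe-level detection calls (no PM/MM data at the probe-set level); with
#' the default generator the conventional choice is twice the degradation
#' background level.
#'
#' @param se expression `SummarizedExperiment` or probes x samples matrix.
#' @param threshold positive linear intensity cutoff.
#' @return named numeric vector, one percentage in `[0, 100]` per sample.
#' @export
percentPresent <- function(se, threshold = 60) {
  stopifnot(threshold > 0)
  values <- if (methods::is(se, "SummarizedExperiment")) exprsMatrix(se)
            else as.matrix(se)
  100 * colMeans(values > threshold)
}

#' MAS5-style scaling factor
#'
#' The multiplier that brings a sample's trimmed mean intensity to a common
#' target: `target / trimmedMean`, with symmetric trimming of the lowest and
#' highest `trim` fractions.  High values indicate globally weak signal.
#'
#' @param sample numeric intensity vector (length >= 10).
#' @param target target intensity (default 500, the MAS5 convention).
#' @param trim symmetric trim fraction in `[0, 0.5)` (default 0.02).
#' @return positive scalar.
#' @examples
#' scalingFactor(rep(250, 100))  # 2
#' @export
scalingFactor <- function(sample, target = 500, trim = 0.02) {
  stopifnot(target > 0, trim >= 0, trim < 0.5)
  sample <- as.numeric(sample)
  if (length(sample) < 10L)
    stop("need at least 10 intensities to compute a scaling factor")
  m <- mean(sample, trim = trim)
  if (!is.finite(m) || m <= 0)
    stop("degenerate intensity vector: trimmed mean is not positive")
  target / m
}

#' 3'/5' control probe ratio
#'
#' Ratio of the 3' to the 5' control probe intensity for one sample; values
#' above 3 conventionally indicate degraded RNA, because reverse
#' transcription initiates at the 3' end of a transcript.
#'
#' @param sample named intensity vector (one array).
#' @param pair `c(probe_3p, probe_5p)` names present in `sample`.
#' @return positive scalar.
#' @examples
#' threeFiveRatio(c(a3 = 300, a5 = 100), c("a3", "a5"))  # 3
#' @export
threeFiveRatio <- function(sample, pair) {
  stopifnot(length(pair) == 2L)
  missing <- setdiff(pair, names(sample))
  if (length(missing))
    stop("control probe(s) absent: ", paste(missing, collapse = ", "))
  unname(sample[pair[1L]] / sample[pair[2L]])
}

#' Scaled log2 percentile summary of an array
#'
#' For one sample, the 5th, 25th, 50th, 75th and 95th percentiles of the
#' intensities are each divided by the sample's scaling factor and
#' log2-transformed, giving the box-plot statistic used to compare signal
#' distributions across arrays.  Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param sample numeric intensity vector.
#' @param scalingFactor the sample's scaling factor (positive).
#' @return named numeric vector of the five values, non-decreasing.
#' @export
distributionSummary <- function(sample, scalingFactor) {
  stopifnot(is.numeric(scalingFactor), length(scalingFactor) == 1L,
            scalingFactor > 0)
  q <- stats::quantile(as.numeric(sample), c(.05, .25, .50, .75, .95),
                       type = 7, names = FALSE)
  out <- log2(q / scalingFactor)
  names(out) <- c("p05", "p25", "p50", "p75", "p95")
  out
}

#' Per-sample QC report
#'
#' Combines [percentPresent()], [scalingFactor()], [threeFiveRatio()] (for
#' each declared control pair) and [distributionSummary()] into one table
#' with a row per sample, mirroring the column semantics of array QC tables.
#'
#' @param se expression `SummarizedExperiment`.
#' @param threshold detection threshold for percent-present.
#' @param target,trim scaling-factor settings.
#' @param controlPairs named list of `c(probe_3p, probe_5p)` pairs.
#' @return a `DataFrame` with columns `sample_id`, `percent_present`,
#'   `scaling_factor`, one `ratio_3p5p_<name>` per control pair, and the five
#'   scaled log2 percentiles.
#' @export
qcReport <- function(se, threshold = 60, target = 500, trim = 0.02,
                     controlPairs = controlProbePairs()) {
  values <- exprsMatrix(se)
  pp <- percentPresent(values, threshold)
  sf <- apply(values, 2L, scalingFactor, target = target, trim = trim)
  out <- S4Vectors::DataFrame(sample_id = colnames(values),
                              percent_present = unname(pp),
                              scaling_factor = unname(sf),
                              row.names = colnames(values))
  for (nm in names(controlPairs)) {
    out[[paste0("ratio_3p5p_", nm)]] <-
      apply(values, 2L, threeFiveRatio, pair = controlPairs[[nm]])
  }
  ds <- t(vapply(seq_len(ncol(values)),
                 function(j) distributionSummary(values[, j], sf[j]),
                 numeric(5)))
  for (j in seq_len(5)) out[[colnames(ds)[j]]] <- ds[, j]
  out
}
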