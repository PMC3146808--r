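#' @rdname PathwaySignature-class
#' @param object,x a `PathwaySignature` or `ConcordanceResult`.
#' @export
setGeneric("pathwayName", function(x) standardGeneric("pathwayName"))

#' @rdname PathwaySignature-class
#' @export
setGeneric("signatureProbes", function(x) standardGeneric("signatureProbes"))

#' @rdname PathwaySignature-class
#' @export
setGeneric("metageneLoadings", function(x) standardGeneric("metageneLoadings"))

#' @rdname PathwaySignature-class
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @rdname PathwaySignature-class
#' @export
setGeneric("factorCount", function(x) standardGeneric("factorCount"))

#' @rdname ConcordanceResult-class
#' @export
setGeneric("matchedR", function(x) standardGeneric("matchedR"))

#' @rdname ConcordanceResult-class
#' @export
setGeneric("unmatchedR", function(x) standardGeneric("unmatchedR"))

#' @rdname PathwaySignature-class
#' @export
setMethod("pathwayName", "PathwaySignature", function(x) x@pathway)

#' @rdname PathwaySignature-class
#' @export
setMethod("signatureProbes", "PathwaySignature", function(x) x@probeIds)

#' @rdname PathwaySignature-class
#' @export
setMethod("metageneLoadings", "PathwaySignature", function(x) x@loadings)

#' @rdname PathwaySignature-class
#' @export
setMethod("posteriorDraws", "PathwaySignature", function(x) x@draws)

#' @rdname PathwaySignature-class
#' @export
setMethod("factorCount", "PathwaySignature", function(x) x@k)

#' @rdname ConcordanceResult-class
#' @export
setMethod("matchedR", "ConcordanceResult", function(x) x@matchedR)

#' @rdname ConcordanceResult-class
#' @export
setMethod("unmatchedR", "ConcordanceResult", function(x) x@unmatchedR)

#' @rdname PathwaySignature-class
#' @export
setMethod("show", "PathwaySignature", function(object) {
  cat("PathwaySignature for pathway", sQuote(object@pathway), "\n")
  cat("  probes:", length(object@probeIds),
      " metagene factors (k):", object@k, "\n")
  cat("  training samples:", length(object@trainingIds),
      sprintf(" (%d control / %d perturbed)",
              sum(object@trainingLabels == 0L),
              sum(object@trainingLabels == 1L)), "\n")
  cat("  posterior draws:", nrow(object@draws),
      " (burn-in", object@burnIn, "discarded, prior SD",
      format(object@priorSd), ")\n")
  invisible(object)
})

#' @rdname ConcordanceResult-class
#' @export
setMethod("show", "ConcordanceResult", function(object) {
  s <- summary(object)
  cat("ConcordanceResult\n")
  cat(sprintf("  matched:   n = %d, mean r = %.3f, range [%.3f, %.3f]\n",
              length(object@matchedR), s$matched_mean,
              s$matched_range[1], s$matched_range[2]))
  cat(sprintf("  unmatched: n = %d, mean r = %.3f, range [%.3f, %.3f]\n",
              length(object@unmatchedR), s$unmatched_mean,
              s$unmatched_range[1], s$unmatched_range[2]))
  invisible(object)
})

#' @describeIn ConcordanceResult-class matched/unmatched means and ranges as a
#'   list (`matched_mean`, `matched_range`, `unmatched_mean`,
#'   `unmatched_range`).
#' @param ... ignored.
#' @export
setMethod("summary", "ConcordanceResult", function(object, ...) {
  list(
    matched_mean = mean(object@matchedR),
    matched_range = range(object@matchedR),
    unmatched_mean = mean(object@unmatchedR),
    unmatched_range = range(object@unmatchedR)
  )
})
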