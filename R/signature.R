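#' Rank probes by two-class differential expression
#'
#' Probes are scored by the absolute pooled-variance two-sample t statistic
#' on log2 intensities (perturbed minus control) and the top `nProbes` are
#' returned in rank order.  A floor of 1e-6 is added to the pooled SD so
#' zero-variance probes yield large but finite statistics rather than NaN.
#' Ties are broken by probe id, lexicographically.
#'
#' @param se training expression `SummarizedExperiment`.
#' @param design a [TrainingDesign-class]; both classes need >= 2 samples.
#' @param nProbes how many probes to keep (<= total probes).
#' @return character vector of probe ids, in decreasing |t| order.
#' @export
selectSignatureProbes <- function(se, design, nProbes) {
  methods::validObject(design)
  values <- exprsMatrix(se)
  ids <- c(design@controlIds, design@perturbedIds)
  missing <- setdiff(ids, colnames(values))
  if (length(missing))
    stop("design samples absent from matrix: ", paste(missing, collapse = ", "))
  if (length(design@controlIds) < 2L || length(design@perturbedIds) < 2L)
    stop("both classes need at least 2 samples")
  if (nProbes > nrow(values))
    stop("nProbes exceeds the number of probes")
  x0 <- log2(values[, design@controlIds, drop = FALSE])
  x1 <- log2(values[, design@perturbedIds, drop = FALSE])
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  sp <- sqrt(((n0 - 1L) * v0 + (n1 - 1L) * v1) / (n0 + n1 - 2L)) + 1e-6
  tstat <- (m1 - m0) / (sp * sqrt(1 / n0 + 1 / n1))
  ord <- order(-abs(tstat), rownames(values))
  rownames(values)[ord][seq_len(nProbes)]
}

#' Truncated SVD metagene basis of a probe subset
#'
#' Computes the rank-`k` singular value decomposition of a log2-transformed,
#' per-probe-centered training submatrix.  The metagene loadings are the
#' first `k` left singular vectors; the training factor scores are the
#' projections `t(U) %*% X` (equal to `d * t(V)`).  The sign of each loading
#' column is fixed so its largest-magnitude element is positive, making the
#' basis reproducible across linear-algebra backends.
#'
#' @param centered probes x samples numeric matrix, log2, per-probe centered.
#' @param k number of factors (must not exceed the matrix rank).
#' @return list with `loadings` (probes x k), `singularValues` (length k)
#'   and `trainingFactors` (k x samples).
#' @export
computeMetagenes <- function(centered, k) {
  centered <- as.matrix(centered)
  sv <- svd(centered)
  rank <- sum(sv$d > max(dim(centered)) * .Machine$double.eps * sv$d[1L])
  if (k > rank)
    stop("k (", k, ") exceeds the matrix rank (", rank, ")")
  U <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  V <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) -1 else 1
  }, numeric(1))
  U <- sweep(U, 2L, flip, `*`)
  V <- sweep(V, 2L, flip, `*`)
  rownames(U) <- rownames(centered)
  fac <- t(V * rep(d, each = nrow(V)))          # k x n, = d * t(V)
  colnames(fac) <- colnames(centered)
  list(loadings = U, singularValues = d, trainingFactors = fac)
}

#' Build a pathway-activity signature
#'
#' Composes the signature pipeline: probe selection by differential
#' expression ([selectSignatureProbes()]), log2 transform, per-probe
#' centering (means and SD bookkeeping retained for test normalization), SVD
#' metagene extraction ([computeMetagenes()]) and the Bayesian probit fit on
#' the training factors ([fitProbitGibbs()]).
#'
#' @param se training expression `SummarizedExperiment`.
#' @param design a [TrainingDesign-class].
#' @param nProbes signature size (e.g. 150 at the default simulation scale;
#'   full-array signatures in this family use 200-500 genes).
#' @param k number of metagene factors (default 3).
#' @param priorSd,nIter,burnIn,seed Gibbs sampler settings, see
#'   [fitProbitGibbs()].  The default prior SD of 1 keeps posterior class
#'   probabilities calibrated (away from hard 0/1 saturation) on the small,
#'   cleanly separable training sets this design produces; the sampler
#'   itself accepts any positive prior SD.
#' @return a [PathwaySignature-class] object.
#' @examples
#' ts <- simulateTrainingSet(simulationConfig(nProbes = 300, seed = 4), "RAS")
#' sig <- buildSignature(ts$se, ts$design, nProbes = 50, k = 2,
#'                       nIter = 1500, burnIn = 500, seed = 9)
#' sig
#' @export
buildSignature <- function(se, design, nProbes = 150L, k = 3L,
                           priorSd = 1, nIter = 11000L, burnIn = 1000L,
                           seed = 1L) {
  probes <- selectSignatureProbes(se, design, nProbes)
  ids <- c(design@controlIds, design@perturbedIds)
  labels <- c(rep(0L, length(design@controlIds)),
              rep(1L, length(design@perturbedIds)))
  if (k > min(nProbes, length(ids)))
    stop("k exceeds min(nProbes, n_train)")
  allLog2 <- log2(exprsMatrix(se)[, ids, drop = FALSE])
  x <- allLog2[probes, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- pmax(apply(x, 1L, stats::sd), 1e-6)
  centered <- x - mu
  mg <- computeMetagenes(centered, k)
  draws <- fitProbitGibbs(mg$trainingFactors, labels, priorSd = priorSd,
                          nIter = nIter, burnIn = burnIn, seed = seed)
  new("PathwaySignature",
      pathway = design@pathway,
      probeIds = probes,
      loadings = mg$loadings,
      singularValues = mg$singularValues,
      k = as.integer(k),
      trainingFactors = mg$trainingFactors,
      trainingIds = ids,
      trainingLabels = labels,
      draws = unclass(draws)[, , drop = FALSE],
      burnIn = as.integer(burnIn),
      priorSd = as.numeric(priorSd),
      seed = as.integer(seed),
      trainProbeMeans = mu,
      trainProbeSds = sdv,
      trainPooledLog2 = sort(as.numeric(x)),
      trainArrayMean = mean(allLog2),
      trainArraySd = stats::sd(as.numeric(allLog2)),
      trainArrayProbeMeans = rowMeans(allLog2))
}

#' Project samples onto a signature's metagene factors
#'
#' Test samples are normalized against the training statistics and projected
#' onto the metagene loadings, `f = t(U) %*% x_tilde`.  Two normalization
#' modes are provided because array normalization of investigational samples
#' is protocol-dependent:
#'
#' * `"standardize"` (default): per-probe log2 z-score against the training
#'   mean and SD, mapped back onto the training spread (multiplied by the
#'   training SD), i.e. effectively the training-mean-centered log2 value.
#'   A training sample projected this way reproduces its training factors.
#' * `"arrayscale"`: each test array is rescaled by a single multiplicative
#'   constant -- the log2 analogue of MAS5-style global scaling to a common
#'   target -- chosen so that the array's mean log2 deviation from the
#'   training per-probe means is zero over all supplied probes (all probes
#'   shared with the training array, not just the signature's; when absent
#'   masking is on, only probes called present enter the estimate, so a
#'   background floor cannot drag it).  This absorbs array-wide intensity
#'   shifts of globally attenuated FFPE arrays while leaving per-probe
#'   contrasts untouched; supply whole-array matrices, not signature
#'   subsets, in this mode.
#' * `"quantile"`: the sample's signature-probe values are replaced by the
#'   quantiles of the pooled training distribution at their within-sample
#'   ranks before centering, making the projection invariant to any
#'   monotone transform of the test sample.
#'
#' In every mode, probes whose raw intensity falls at or below
#' `absentThreshold` can be masked as undetected: a probe called absent on a
#' degraded array carries background, not signal, so its normalized value is
#' replaced by the training mean (centered value zero) before projection.
#' An absent probe then contributes no evidence in either direction, and a
#' heavily degraded array is shrunk toward the factor origin rather than
#' pushed toward whichever class the background floor happens to resemble.
#' Masking is off by default.
#'
#' @param sig a [PathwaySignature-class].
#' @param se expression `SummarizedExperiment` (or named matrix/vector)
#'   containing every signature probe.
#' @param mode `"standardize"`, `"arrayscale"` or `"quantile"`.
#' @param absentThreshold linear intensity at or below which a signature
#'   probe is treated as undetected (`NULL` disables masking).
#' @return k x samples matrix of factor scores.
#' @export
projectSamples <- function(sig, se,
                           mode = c("standardize", "arrayscale", "quantile"),
                           absentThreshold = NULL) {
  mode <- match.arg(mode)
  values <- if (methods::is(se, "SummarizedExperiment")) exprsMatrix(se)
            else if (is.null(dim(se))) matrix(se, ncol = 1L,
                                              dimnames = list(names(se), "sample"))
            else as.matrix(se)
  missing <- setdiff(sig@probeIds, rownames(values))
  if (length(missing))
    stop("signature probes absent from matrix: ",
         paste(missing, collapse = ", "))
  x <- log2(values[sig@probeIds, , drop = FALSE])
  if (mode == "standardize") {
    z <- (x - sig@trainProbeMeans) / sig@trainProbeSds
    xt <- z * sig@trainProbeSds
  } else if (mode == "arrayscale") {
    common <- intersect(rownames(values), names(sig@trainArrayProbeMeans))
    if (length(common) < length(sig@probeIds))
      stop("arrayscale mode needs the training array's probes in the test matrix")
    dev <- log2(values[common, , drop = FALSE]) -
      sig@trainArrayProbeMeans[common]
    shift <- if (is.null(absentThreshold)) colMeans(dev)
    else {
      present <- values[common, , drop = FALSE] > absentThreshold
      colSums(dev * present) / pmax(colSums(present), 1L)
    }
    xt <- sweep(x, 2L, shift) - sig@trainProbeMeans
  } else {
    pooled <- sig@trainPooledLog2
    xt <- apply(x, 2L, function(v) {
      r <- rank(v, ties.method = "average")
      mapped <- stats::quantile(pooled, probs = (r - 0.5) / length(v),
                                type = 7, names = FALSE)
      mapped - sig@trainProbeMeans
    })
    dimnames(xt) <- dimnames(x)
  }
  if (!is.null(absentThreshold)) {
    xt[values[sig@probeIds, , drop = FALSE] <= absentThreshold] <- 0
  }
  f <- crossprod(sig@loadings, xt)
  rownames(f) <- paste0("factor", seq_len(sig@k))
  f
}

#' Predict posterior pathway-activity probabilities
#'
#' For each sample, the posterior probability of pathway activity is the
#' mean over posterior draws of `pnorm(alpha + beta' f)` at the sample's
#' factor scores; the 95% credible interval comes from the 2.5 and 97.5
#' percentiles of the per-draw probabilities (widened, if necessary, to
#' contain the posterior mean).
#'
#' @param sig a [PathwaySignature-class].
#' @param se expression `SummarizedExperiment` of investigational samples.
#' @param mode normalization mode, see [projectSamples()].
#' @param absentThreshold optional detection threshold below which signature
#'   probes are masked from the projection, see [projectSamples()].
#' @return a `DataFrame` with columns `sample_id`, `probability`, `ci_low`,
#'   `ci_high`.
#' @examples
#' ts <- simulateTrainingSet(simulationConfig(nProbes = 300, seed = 4), "RAS")
#' sig <- buildSignature(ts$se, ts$design, nProbes = 50, k = 2,
#'                       nIter = 1500, burnIn = 500, seed = 9)
#' predictActivity(sig, ts$se)
#' @export
predictActivity <- function(sig, se,
                            mode = c("standardize", "arrayscale", "quantile"),
                            absentThreshold = NULL) {
  f <- projectSamples(sig, se, mode = match.arg(mode),
                      absentThreshold = absentThreshold)
  eta <- sig@draws %*% rbind(1, f)              # M x n
  probs <- stats::pnorm(eta)
  p <- colMeans(probs)
  ci <- apply(probs, 2L, stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  S4Vectors::DataFrame(
    sample_id = colnames(f),
    probability = unname(p),
    ci_low = pmin(ci[1L, ], p),
    ci_high = pmax(ci[2L, ], p),
    row.names = colnames(f))
}

#' Leave-one-out validation of a signature
#'
#' Each training sample is predicted by a signature rebuilt from scratch
#' (probe selection, SVD and probit fit) on the remaining samples.
#'
#' @inheritParams buildSignature
#' @param mode normalization mode for the held-out projection.
#' @return a `DataFrame` with columns `sample_id`, `label` and `probability`.
#' @export
leaveOneOut <- function(se, design, nProbes = 150L, k = 3L, priorSd = 1,
                        nIter = 11000L, burnIn = 1000L, seed = 1L,
                        mode = "standardize") {
  ids <- c(design@controlIds, design@perturbedIds)
  if (length(ids) < 5L) stop("need at least 5 training samples")
  labels <- stats::setNames(
    c(rep(0L, length(design@controlIds)), rep(1L, length(design@perturbedIds))),
    ids)
  prob <- vapply(ids, function(held) {
    d <- trainingDesign(design@pathway,
                        setdiff(design@controlIds, held),
                        setdiff(design@perturbedIds, held))
    sig <- buildSignature(se[, setdiff(ids, held)], d, nProbes = nProbes,
                          k = k, priorSd = priorSd, nIter = nIter,
                          burnIn = burnIn,
                          seed = deriveSeed(seed, paste0("loo-", held)))
    predictActivity(sig, se[, held, drop = FALSE], mode = mode)$probability
  }, numeric(1))
  S4Vectors::DataFrame(sample_id = ids, label = unname(labels[ids]),
                       probability = unname(prob), row.names = ids)
}

signatureFormatTag <- "pathsig-signature/1"

#' Serialize a signature to JSON
#'
#' All numeric content is written at full double precision together with a
#' format tag, so signatures round-trip exactly.
#'
#' @param sig a [PathwaySignature-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(sig, path) {
  obj <- list(
    format = signatureFormatTag,
    pathway = sig@pathway,
    probe_ids = sig@probeIds,
    loadings = sig@loadings,
    singular_values = sig@singularValues,
    k = sig@k,
    training_factors = sig@trainingFactors,
    training_ids = sig@trainingIds,
    training_labels = sig@trainingLabels,
    draws = sig@draws,
    burn_in = sig@burnIn,
    prior_sd = sig@priorSd,
    seed = sig@seed,
    train_probe_means = as.numeric(sig@trainProbeMeans),
    train_probe_sds = as.numeric(sig@trainProbeSds),
    train_pooled_log2 = sig@trainPooledLog2,
    train_array_mean = sig@trainArrayMean,
    train_array_sd = sig@trainArraySd,
    array_probe_ids = names(sig@trainArrayProbeMeans),
    train_array_probe_means = as.numeric(sig@trainArrayProbeMeans))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, signatureFormatTag))
    stop("not a recognized signature file (format tag ",
         deparse(obj$format), ")")
  loadings <- as.matrix(obj$loadings)
  rownames(loadings) <- obj$probe_ids
  fac <- as.matrix(obj$training_factors)
  colnames(fac) <- obj$training_ids
  new("PathwaySignature",
      pathway = obj$pathway,
      probeIds = obj$probe_ids,
      loadings = loadings,
      singularValues = as.numeric(obj$singular_values),
      k = as.integer(obj$k),
      trainingFactors = fac,
      trainingIds = obj$training_ids,
      trainingLabels = as.integer(obj$training_labels),
      draws = as.matrix(obj$draws),
      burnIn = as.integer(obj$burn_in),
      priorSd = as.numeric(obj$prior_sd),
      seed = as.integer(obj$seed),
      trainProbeMeans = stats::setNames(as.numeric(obj$train_probe_means),
                                        obj$probe_ids),
      trainProbeSds = stats::setNames(as.numeric(obj$train_probe_sds),
                                      obj$probe_ids),
      trainPooledLog2 = as.numeric(obj$train_pooled_log2),
      trainArrayMean = as.numeric(obj$train_array_mean),
      trainArraySd = as.numeric(obj$train_array_sd),
      trainArrayProbeMeans = stats::setNames(
        as.numeric(obj$train_array_probe_means), obj$array_probe_ids))
}
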