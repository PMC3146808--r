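#' Bayesian probit regression via latent-variable Gibbs sampling
#'
#' Fits the binary probit model `P(y = 1 | f) = pnorm(alpha + beta' f)` with
#' independent `Normal(0, priorSd^2)` priors on the intercept and each
#' coefficient, using the Albert–Chib data-augmentation Gibbs sampler: latent
#' `z_i ~ Normal(alpha + beta' f_i, 1)` truncated to `(0, Inf)` when
#' `y_i = 1` and to `(-Inf, 0]` when `y_i = 0`, with `(alpha, beta)` then
#' drawn from their conjugate multivariate-normal full conditional.
#' Truncated-normal draws use a log-space inverse-CDF so the sampler stays
#' numerically exact even when the linear predictor is far from the
#' truncation point (as happens for separable training data).
#'
#' @param factors k x n matrix of metagene factor scores (columns = samples).
#' @param labels 0/1 vector of length n; both classes must be present.
#' @param priorSd prior standard deviation (default 10, weakly informative).
#' @param nIter total Gibbs iterations (default 11000).
#' @param burnIn discarded initial iterations (default 1000).
#' @param seed RNG seed; the fit is deterministic given it.
#' @return matrix of `nIter - burnIn` rows and `k + 1` columns
#'   (`alpha`, `beta1`, ..., `betak`), with attributes `burnIn`, `priorSd`,
#'   `seed` and `geweke` (per-parameter Geweke z scores; |z| > 3 triggers a
#'   warning, not an error).
#' @references Albert, J. H. and Chib, S. (1993) Bayesian analysis of binary
#'   and polychotomous response data. JASA 88, 669-679.
#' @examples
#' f <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), 1)
#' draws <- fitProbitGibbs(f, c(0, 0, 0, 1, 1, 1), nIter = 2000,
#'                         burnIn = 500, seed = 1)
#' colMeans(draws)
#' @export
fitProbitGibbs <- function(factors, labels, priorSd = 10,
                           nIter = 11000L, burnIn = 1000L, seed = 1L) {
  factors <- as.matrix(factors)
  labels <- as.numeric(labels)
  n <- ncol(factors)
  k <- nrow(factors)
  if (length(labels) != n)
    stop("labels must match the number of factor columns")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) != 2L)
    stop("labels must be 0/1 with both classes present")
  if (n < 4L) stop("need at least 4 samples")
  stopifnot(priorSd > 0, nIter > burnIn, burnIn >= 0)

  W <- cbind(1, t(factors))                       # n x (k+1)
  prec <- crossprod(W) + diag(k + 1L) / priorSd^2
  V <- chol2inv(chol(prec))
  Lt <- chol(V)                                   # t(Lt) %*% Lt = V
  A <- V %*% t(W)                                 # posterior mean = A z
  pos <- labels == 1

  withSeed(seed, {
    b <- numeric(k + 1L)
    keep <- matrix(NA_real_, nIter - burnIn, k + 1L,
                   dimnames = list(NULL, c("alpha", paste0("beta", seq_len(k)))))
    for (it in seq_len(nIter)) {
      mu <- drop(W %*% b)
      z <- rtruncnormLatent(mu, pos)
      m <- drop(A %*% z)
      b <- m + drop(crossprod(Lt, stats::rnorm(k + 1L)))
      if (it > burnIn) keep[it - burnIn, ] <- b
    }
    gz <- apply(keep, 2L, gewekeZ)
    if (any(abs(gz) > 3, na.rm = TRUE))
      warning("Geweke diagnostic flags possible non-convergence for: ",
              paste(names(gz)[abs(gz) > 3], collapse = ", "))
    structure(keep, burnIn = as.integer(burnIn), priorSd = priorSd,
              seed = as.integer(seed), geweke = gz)
  })
}

# Draw z_i ~ N(mu_i, 1) truncated to (0, Inf) where pos, (-Inf, 0] elsewhere.
# Log-space inverse CDF: numerically stable for |mu| up to hundreds.
rtruncnormLatent <- function(mu, pos) {
  u <- stats::runif(length(mu))
  z <- numeric(length(mu))
  if (any(pos)) {
    # want P(Z > z) = (1-u) * P(Z > -mu) for standardized Z
    lp <- stats::pnorm(-mu[pos], lower.tail = FALSE, log.p = TRUE)
    z[pos] <- mu[pos] + stats::qnorm(log1p(-u[pos]) + lp,
                                     lower.tail = FALSE, log.p = TRUE)
  }
  if (any(!pos)) {
    # want P(Z <= z) = u * P(Z <= -mu)
    lp <- stats::pnorm(-mu[!pos], log.p = TRUE)
    z[!pos] <- mu[!pos] + stats::qnorm(log(u[!pos]) + lp, log.p = TRUE)
  }
  z
}

# Geweke convergence z score: compare the mean of the first 10% of a chain
# with the mean of the last 50%, variances estimated by batch means.
gewekeZ <- function(x) {
  n <- length(x)
  if (n < 200L) return(NA_real_)
  a <- x[seq_len(floor(0.1 * n))]
  b <- x[seq.int(floor(0.5 * n) + 1L, n)]
  va <- batchMeansVar(a)
  vb <- batchMeansVar(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

# Squared standard error of the mean of a correlated chain via batch means.
batchMeansVar <- function(x, nBatch = 20L) {
  n <- length(x)
  size <- floor(n / nBatch)
  if (size < 2L) return(stats::var(x) / n)
  m <- colMeans(matrix(x[seq_len(size * nBatch)], size, nBatch))
  stats::var(m) / nBatch
}

#' Monte-Carlo standard errors of posterior summaries
#'
#' Batch-means standard errors for the posterior mean and posterior SD of
#' each column of a draws matrix, accounting for autocorrelation of the
#' Gibbs chain.  The SE of the posterior SD is obtained by the delta method
#' from batch-means SEs of the first and second moments (batch means of the
#' second moment are unbiased, unlike within-batch SDs, which are biased
#' low when batches are shorter than the mixing time).
#'
#' @param draws draws matrix (rows = iterations).
#' @param nBatch number of batches (default 40; use long batches for slowly
#'   mixing chains).
#' @return list with vectors `mean`, `meanSE`, `sd`, `sdSE`.
#' @export
mcmcSummary <- function(draws, nBatch = 40L) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  size <- floor(n / nBatch)
  idx <- seq_len(size * nBatch)
  batch <- rep(seq_len(nBatch), each = size)
  means <- colMeans(draws)
  sds <- apply(draws, 2L, stats::sd)
  bm <- apply(draws[idx, , drop = FALSE], 2L,
              function(x) tapply(x, batch, mean))
  b2 <- apply(draws[idx, , drop = FALSE]^2, 2L,
              function(x) tapply(x, batch, mean))
  meanSE <- apply(bm, 2L, stats::sd) / sqrt(nBatch)
  m2SE <- apply(b2, 2L, stats::sd) / sqrt(nBatch)
  sdSE <- (m2SE + 2 * abs(means) * meanSE) / (2 * sds)
  list(mean = means, meanSE = meanSE, sd = sds, sdSE = sdSE)
}
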