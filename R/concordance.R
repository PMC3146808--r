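#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()]: the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a Student t distribution with
#' `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with elements `r`, `p` and `n`.
#' @examples
#' pearsonWithPValue(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearsonWithPValue <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Matched versus unmatched whole-genome correlations
#'
#' Computes Pearson correlations of log2 intensities over all shared probes
#' for every cross combination of samples from `a` and `b`.  Combinations
#' linked by a common `pair_id` in the two colData tables form the matched
#' set; all others are unmatched.
#'
#' @param a,b expression `SummarizedExperiment`s whose colData carries
#'   `pair_id`; probes are aligned with [alignMatrices()] first.
#' @param pairing optional named character vector mapping sample ids of `a`
#'   to sample ids of `b`, overriding the colData pairing.
#' @return a [ConcordanceResult-class].
#' @export
matchedUnmatched <- function(a, b, pairing = NULL) {
  al <- alignMatrices(a, b)
  xa <- log2(exprsMatrix(al$a))
  xb <- log2(exprsMatrix(al$b))
  if (is.null(pairing)) {
    pa <- SummarizedExperiment::colData(al$a)$pair_id
    pb <- SummarizedExperiment::colData(al$b)$pair_id
    if (is.null(pa) || is.null(pb))
      stop("no pairing supplied and colData lacks pair_id")
    names(pa) <- colnames(xa); names(pb) <- colnames(xb)
    pa <- pa[!is.na(pa)]; pb <- pb[!is.na(pb)]
    if (!all(pa %in% pb))
      stop("unresolvable pair ids: ",
           paste(setdiff(pa, pb), collapse = ", "))
    pairing <- stats::setNames(names(pb)[match(pa, pb)], names(pa))
  }
  if (!all(names(pairing) %in% colnames(xa)) ||
      !all(pairing %in% colnames(xb)))
    stop("pairing refers to samples absent from the matrices")
  R <- stats::cor(xa, xb)                       # n_a x n_b
  pairIdx <- cbind(match(names(pairing), colnames(xa)),
                   match(pairing, colnames(xb)))
  matched <- R[pairIdx]
  names(matched) <- names(pairing)
  mask <- matrix(TRUE, nrow(R), ncol(R), dimnames = dimnames(R))
  mask[pairIdx] <- FALSE
  unmatched <- R[mask]
  names(unmatched) <- outer(rownames(R), colnames(R), paste,
                            sep = " vs ")[mask]
  new("ConcordanceResult", matchedR = matched, unmatchedR = unmatched)
}

#' SD filter and two-way mean centering
#'
#' Keeps the `nKeep` probes with the highest across-sample SD of log2
#' intensities (ties broken by probe id), then centers the log2 submatrix in
#' a single pass: first each probe row by its mean, then each sample column
#' by its mean.  This is the Cluster-3.0-style preparation for heatmap
#' clustering; the result is centered, so it is returned as a plain matrix
#' rather than an intensity container.
#'
#' @param se expression `SummarizedExperiment`.
#' @param nKeep number of probes to retain.
#' @return numeric matrix (`nKeep` x samples) of filtered, centered log2
#'   values.
#' @export
sdFilterAndCenter <- function(se, nKeep = 1000L) {
  values <- exprsMatrix(se)
  if (nKeep > nrow(values)) stop("nKeep exceeds the number of probes")
  x <- log2(values)
  sdv <- apply(x, 1L, stats::sd)
  keep <- rownames(x)[order(-sdv, rownames(x))][seq_len(nKeep)]
  x <- x[keep, , drop = FALSE]
  x <- x - rowMeans(x)                          # genes
  sweep(x, 2L, colMeans(x))                     # then arrays
}

#' Uncentered correlation similarity between sample columns
#'
#' The cosine-like similarity `sum(u * v) / sqrt(sum(u^2) * sum(v^2))`
#' without mean subtraction, as used by Cluster 3.0.
#'
#' @param x numeric matrix, samples in columns.
#' @return samples x samples similarity matrix.
#' @export
uncenteredCorrelation <- function(x) {
  x <- as.matrix(x)
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0))
    stop("all-zero sample vector(s): ",
         paste(colnames(x)[norms == 0], collapse = ", "))
  crossprod(x) / tcrossprod(norms)
}

#' Average-linkage clustering with uncentered correlation
#'
#' Samples are clustered agglomeratively (UPGMA, [stats::hclust()] with
#' `method = "average"`) on distances `1 - uncentered correlation`.  Columns
#' are pre-sorted lexicographically so merge order is deterministic under
#' ties.  Merge heights are clipped to `[0, 2]`.
#'
#' @param x numeric matrix with samples in columns (typically the output of
#'   [sdFilterAndCenter()], or log2 intensities).
#' @return an `hclust` object.
#' @seealso [writeDendrogram()] for Newick export.
#' @export
clusterSamples <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  x <- x[, order(colnames(x)), drop = FALSE]
  sim <- uncenteredCorrelation(x)
  d <- stats::as.dist(pmin(pmax(1 - sim, 0), 2))
  stats::hclust(d, method = "average")
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc an `hclust` object from [clusterSamples()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component scores of samples
#'
#' SVD of the per-probe (row) centered log2 expression matrix; sample scores
#' are the projections onto the right singular vectors, and variance
#' fractions are the squared singular values over their total.
#'
#' @param se expression `SummarizedExperiment`.
#' @param nComponents number of components to return.
#' @return list with `scores` (samples x nComponents) and
#'   `varianceExplained` (non-increasing fractions summing to <= 1).
#' @export
pcaScores <- function(se, nComponents = 2L) {
  x <- log2(exprsMatrix(se))
  x <- x - rowMeans(x)
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds the matrix dimensions")
  sv <- svd(x)
  frac <- sv$d^2 / sum(sv$d^2)
  scores <- t(x) %*% sv$u[, seq_len(nComponents), drop = FALSE]
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(nComponents)))
  list(scores = scores, varianceExplained = frac[seq_len(nComponents)])
}

#' Per-patient concordance of FF and FFPE predictions
#'
#' A patient is concordant when the difference between the FFPE lesion's
#' predicted pathway-activity probability and at least one fresh-frozen
#' lesion's probability does not exceed the threshold, i.e. when the minimum
#' absolute difference over the patient's FF lesions is `<= threshold`.  The
#' mean absolute difference is also reported.  The summary concordance rate
#' is rounded to the nearest integer percent (5 of 6 patients gives 83).
#'
#' @param ffProb named list (by patient) of numeric FF lesion probabilities,
#'   or a data.frame/DataFrame with columns `group_id` and `probability`.
#' @param ffpeProb named numeric vector of one FFPE probability per patient.
#' @param threshold concordance threshold (default 0.3).
#' @return list with `perPatient` (a `DataFrame` with `patient`,
#'   `min_abs_diff`, `mean_abs_diff`, `concordant`) and `summary`
#'   (`concordance_rate` in integer percent, `mean_difference`,
#'   `difference_range` of the per-patient mean differences).
#' @examples
#' patientConcordance(list(A = c(0.1, 0.45)), c(A = 0.5))
#' @export
patientConcordance <- function(ffProb, ffpeProb, threshold = 0.3) {
  if (!is.list(ffProb) || is.data.frame(ffProb)) {
    df <- as.data.frame(ffProb)
    ffProb <- split(df$probability, df$group_id)
  }
  patients <- names(ffpeProb)
  if (is.null(patients) || !all(patients %in% names(ffProb)))
    stop("every FFPE patient needs at least one FF lesion probability")
  stats <- lapply(patients, function(p) {
    ff <- ffProb[[p]]
    if (!length(ff)) stop("patient ", p, " has no FF lesion")
    d <- abs(ffpeProb[[p]] - ff)
    c(min = min(d), mean = mean(d))
  })
  mn <- vapply(stats, `[[`, numeric(1), "min")
  mean_ <- vapply(stats, `[[`, numeric(1), "mean")
  conc <- mn <= threshold
  list(
    perPatient = S4Vectors::DataFrame(
      patient = patients,
      min_abs_diff = mn,
      mean_abs_diff = mean_,
      concordant = conc,
      row.names = patients),
    summary = list(
      concordance_rate = round(100 * mean(conc)),
      mean_difference = mean(mean_),
      difference_range = range(mean_)))
}
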