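#' Assemble an expression SummarizedExperiment
#'
#' Wraps a probes x samples matrix of positive linear-scale intensities in a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"exprs"`,
#' enforcing the container invariants: unique probe and sample ids and
#' strictly positive, finite values.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   rownames (probe ids) and colnames (sample ids).
#' @param colData optional `DataFrame`/`data.frame` of sample annotation with
#'   one row per sample.
#' @return a `SummarizedExperiment`.
#' @examples
#' m <- matrix(2^rnorm(6, 7), 3, 2,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:2)))
#' makeExpressionSet(m)
#' @export
makeExpressionSet <- function(values, colData = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry probe ids (rownames) and sample ids (colnames)")
  checkExpressionValues(values)
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    colData <- S4Vectors::DataFrame(colData)
    rownames(colData) <- colnames(values)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = colData)
}

# Invariant checks shared by the constructor and the reader; errors identify
# the offending probe/sample.
checkExpressionValues <- function(values) {
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate probe ids: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(values))
    stop("expression values must be numeric")
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "non-positive or non-numeric intensity at probe '%s', sample '%s' (value %s); %d offending cell(s) in total",
      rownames(values)[i[1]], colnames(values)[i[2]],
      format(values[bad[1L]]), length(bad)))
  }
  invisible(TRUE)
}

#' Extract the expression matrix from a SummarizedExperiment
#'
#' @param se a `SummarizedExperiment` with assay `"exprs"` (the first assay is
#'   used as fallback).
#' @return the probes x samples numeric matrix.
#' @export
exprsMatrix <- function(se) {
  stopifnot(methods::is(se, "SummarizedExperiment"))
  nm <- SummarizedExperiment::assayNames(se)
  if (!is.null(nm) && "exprs" %in% nm)
    SummarizedExperiment::assay(se, "exprs")
  else SummarizedExperiment::assay(se, 1L)
}

#' Read a probe-by-sample expression matrix from TSV
#'
#' The format is a tab-separated table whose header row holds sample ids and
#' whose first column holds probe ids; the body is numeric (scientific
#' notation accepted), strictly positive, on a linear MAS5-like scale.
#' Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @return a `SummarizedExperiment` with assay `"exprs"`.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L)
    stop("expression TSV needs a probe-id column plus at least one sample")
  probes <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- matrix(NA_real_, nrow(body), ncol(body),
                   dimnames = list(probes, colnames(df)[-1L]))
  suppressWarnings(storage.mode(body) <- "double")
  notnum <- which(is.na(body))
  if (length(notnum)) {
    i <- arrayInd(notnum[1L], dim(body))
    stop(sprintf("non-numeric intensity at probe '%s', sample '%s'",
                 probes[i[1]], colnames(values)[i[2]]))
  }
  values[] <- body
  checkExpressionValues(values)
  makeExpressionSet(values)
}

#' Write an expression matrix to TSV
#'
#' Intensities are written at full double precision (up to 17 significant
#' digits) so that write followed by read is the identity.
#'
#' @param se a `SummarizedExperiment` (or plain named matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  values <- if (methods::is(se, "SummarizedExperiment")) exprsMatrix(se)
            else as.matrix(se)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(values)), collapse = "\t"), con)
  body <- apply(format(values, digits = 17, trim = TRUE, scientific = NA),
                1L, paste, collapse = "\t")
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

annotationColumns <- c("sample_id", "class_label", "group_id", "pair_id",
                       "preservation")

#' Read or write a sample annotation table
#'
#' Sample annotation is a TSV with columns `sample_id`, `class_label` (0/1 or
#' empty), `group_id` (cell line or patient, or empty), `pair_id` (links a
#' fresh-frozen sample to its FFPE partner, or empty) and `preservation`
#' (`fresh_frozen`, `ffpe` or `cell_line`).  Empty strings encode absent
#' optional fields and are read back as `NA`.
#'
#' @param path TSV path.
#' @return for `readSampleAnnotation`, a [S4Vectors::DataFrame] keyed by
#'   `sample_id`.
#' @export
readSampleAnnotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  missing <- setdiff(annotationColumns, colnames(df))
  if (length(missing))
    stop("annotation TSV lacks column(s): ", paste(missing, collapse = ", "))
  df[df == ""] <- NA
  out <- S4Vectors::DataFrame(
    sample_id = df$sample_id,
    class_label = as.integer(df$class_label),
    group_id = df$group_id,
    pair_id = df$pair_id,
    preservation = df$preservation,
    row.names = df$sample_id)
  checkAnnotation(out)
  out
}

#' @rdname readSampleAnnotation
#' @param annotation a `DataFrame`/`data.frame` with the columns above.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  if (!"sample_id" %in% colnames(df)) df$sample_id <- rownames(df)
  for (col in setdiff(annotationColumns, colnames(df))) df[[col]] <- NA
  df <- df[, annotationColumns]
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

checkAnnotation <- function(ann) {
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample ids in annotation")
  if (!all(is.na(ann$class_label) | ann$class_label %in% c(0L, 1L)))
    stop("class_label must be 0, 1 or absent")
  pid <- ann$pair_id[!is.na(ann$pair_id)]
  if (length(pid)) {
    tab <- table(ann$pair_id, ann$preservation)
    ok <- all(rowSums(tab) == 2L) &&
      all(c("fresh_frozen", "ffpe") %in% colnames(tab)) &&
      all(tab[, "fresh_frozen"] == 1L & tab[, "ffpe"] == 1L)
    if (!ok)
      stop("each pair_id must link exactly one fresh_frozen and one ffpe sample")
  }
  invisible(TRUE)
}

#' Restrict two expression matrices to their common probes
#'
#' Both matrices are subset to the intersection of their probe ids, in the
#' probe order of `a`; values are permuted consistently.  The operation is
#' idempotent.
#'
#' @param a,b `SummarizedExperiment`s sharing at least 2 probe ids.
#' @return a list with elements `a` and `b`, both on the common probe set.
#' @export
alignMatrices <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < 2L)
    stop("matrices share fewer than 2 probe ids (", length(common), " found)")
  list(a = a[common, ], b = b[common, ])
}
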