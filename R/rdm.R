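#' Representational dissimilarity matrix (RDM) container
#'
#' An RDM is a square symmetric numeric matrix of pairwise dissimilarities
#' between stimulus conditions, with condition labels as dimnames and a
#' `metric` attribute recording how it was computed. Cross-validated
#' distance estimates are unbiased and may be negative, so negativity is
#' allowed when `metric = "crossvalidated"`; all other metrics require a
#' zero diagonal.
#'
#' @param mat square numeric matrix of dissimilarities.
#' @param labels character vector of condition labels (defaults to existing
#'   rownames, else `cond01`, `cond02`, ...).
#' @param metric one of `"euclidean"`, `"crossvalidated"`,
#'   `"percent-choice"`, `"correlation"`.
#' @return a numeric matrix of class `rdm` with a `metric` attribute.
#' @export
rdm <- function(mat, labels = NULL,
                metric = c("euclidean", "crossvalidated",
                           "percent-choice", "correlation")) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat))
    stop("an RDM must be square")
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("an RDM must be symmetric")
  mat <- (mat + t(mat)) / 2
  if (is.null(labels)) {
    labels <- rownames(mat)
    if (is.null(labels))
      labels <- sprintf("cond%02d", seq_len(nrow(mat)))
  }
  if (length(labels) != nrow(mat))
    stop("label length does not match matrix size")
  if (metric != "crossvalidated" && any(abs(diag(mat)) > 1e-8))
    stop("non-cross-validated RDMs must have a zero diagonal")
  dimnames(mat) <- list(labels, labels)
  structure(mat, metric = metric, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d conditions, metric = %s\n",
              nrow(x), attr(x, "metric")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Vectorize the strict lower triangle of an RDM
#'
#' Condition order follows the matrix rows; the strict lower triangle
#' (excluding the diagonal) is the canonical pair vectorization used by
#' every similarity and regression routine in the package.
#'
#' @param x an `rdm` or square symmetric matrix.
#' @return numeric vector of length `n*(n-1)/2`.
#' @export
rdm_vec <- function(x) {
  x <- as.matrix(x)
  x[lower.tri(x)]
}

#' Pair index table for an n-condition RDM
#'
#' Row/column indices of the strict lower triangle, in the same order as
#' [rdm_vec()].
#'
#' @param n number of conditions.
#' @return data.frame with integer columns `i` (row) and `j` (column), i > j.
#' @keywords internal
pair_index <- function(n) {
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

#' Write an RDM as labeled delimited text
#'
#' Tab-separated square matrix with row and column condition labels; the
#' metric tag is stored in a `# metric:` header comment.
#'
#' @param x an `rdm`.
#' @param path output file.
#' @export
write_rdm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(x, "metric")), con)
  df <- data.frame(condition = rownames(x), unclass(x),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RDM written by [write_rdm()]
#'
#' Validates squareness and symmetry on read.
#'
#' @param path file written by [write_rdm()].
#' @return an `rdm`.
#' @export
read_rdm <- function(path) {
  header <- readLines(path, n = 1L)
  metric <- if (grepl("^# metric:", header))
    trimws(sub("^# metric:", "", header)) else "euclidean"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(mat), labels))
    stop("row and column labels disagree")
  rdm(mat, labels = labels, metric = metric)
}

#' Correlate two RDMs over their condition pairs
#'
#' Pearson correlation over the strict-lower-triangle vectorization,
#' together with its Fisher Z transform (`atanh`). Correlations at machine
#' +-1 are clipped to `1 - 1e-12` in absolute value before the transform so
#' Z stays finite; a warning records the clip.
#'
#' @param rdm_a,rdm_b RDMs over the same condition set.
#' @return list with elements `r` and `z`.
#' @export
rdm_correlation <- function(rdm_a, rdm_b) {
  va <- rdm_vec(rdm_a)
  vb <- rdm_vec(rdm_b)
  if (length(va) != length(vb))
    stop("RDMs cover different numbers of condition pairs")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero-variance dissimilarity vector: correlation undefined")
  r <- stats::cor(va, vb)
  list(r = r, z = fisher_z(r))
}

#' Fisher Z transform with finite-value clipping
#'
#' @param r correlation coefficient(s).
#' @return `atanh(r)` after clipping `|r|` at `1 - 1e-12`.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-12
  if (any(abs(r) > lim, na.rm = TRUE)) {
    warning("correlation at machine +-1 clipped before Fisher Z")
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

#' Inverse Fisher Z transform
#'
#' @param z Fisher Z value(s).
#' @return `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)
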