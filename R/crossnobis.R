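#' Run-wise pattern dataset
#'
#' Container for one simulated participant/region: per-run
#' condition-by-voxel pattern estimates plus residual time courses used for
#' noise-covariance estimation. All runs must share the condition set and
#' voxel count. `T > V` is not required: the shrinkage covariance
#' estimator handles ill-conditioned sample covariances.
#'
#' @param patterns list of condition-by-voxel matrices, one per run, with
#'   condition labels as rownames.
#' @param residuals list of timepoint-by-voxel residual matrices, one per
#'   run.
#' @return object of class `run_dataset`.
#' @export
run_dataset <- function(patterns, residuals) {
  if (length(patterns) < 2) stop("need at least 2 runs")
  if (length(patterns) != length(residuals))
    stop("patterns and residuals must have one entry per run")
  d <- dim(patterns[[1]])
  if (!all(vapply(patterns, function(m) all(dim(m) == d), logical(1))))
    stop("all runs must share condition set and voxel count")
  if (!all(vapply(residuals, ncol, integer(1)) == d[2]))
    stop("residual voxel count does not match patterns")
  structure(list(patterns = patterns, residuals = residuals,
                 n_runs = length(patterns), n_conditions = d[1],
                 n_voxels = d[2],
                 labels = rownames(patterns[[1]])),
            class = "run_dataset")
}

#' @export
print.run_dataset <- function(x, ...) {
  cat(sprintf("run_dataset: %d runs, %d conditions, %d voxels\n",
              x$n_runs, x$n_conditions, x$n_voxels))
  invisible(x)
}

#' Estimate a noise covariance matrix from residual time courses
#'
#' `"shrinkage"` regularizes the sample covariance toward its diagonal with
#' an analytic (Ledoit-Wolf-style) intensity, guaranteeing a
#' positive-definite estimate even when timepoints are fewer than voxels.
#' `"full"` returns the plain sample covariance and errors if it is
#' singular.
#'
#' @param residuals timepoint-by-voxel matrix (>= 2 rows).
#' @param estimator `"shrinkage"` (default) or `"full"`.
#' @return object of class `noise_cov`: list with `sigma` (V x V),
#'   `estimator`, and `lambda` (shrinkage intensity; 0 for full).
#' @export
estimate_covariance <- function(residuals,
                                estimator = c("shrinkage", "full")) {
  estimator <- match.arg(estimator)
  X <- as.matrix(residuals)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 timepoints")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (n - 1)
  if (estimator == "full") {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev))
      stop("sample covariance is singular; use the shrinkage estimator")
    return(structure(list(sigma = S, estimator = "full", lambda = 0),
                     class = "noise_cov"))
  }
  # variance of the off-diagonal sample covariances (Schafer-Strimmer)
  sw <- crossprod(Xc)                     # sum_k w_kij
  sw2 <- crossprod(Xc^2)                  # sum_k w_kij^2
  var_s <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  off <- !diag(ncol(S))
  denom <- sum(S[off]^2)
  lambda <- if (denom > 0) sum(var_s[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  sigma <- (1 - lambda) * S + lambda * diag(diag(S))
  d <- diag(sigma)
  if (any(d <= 0)) diag(sigma) <- pmax(d, 1e-12 * max(d, 1))
  structure(list(sigma = sigma, estimator = "shrinkage", lambda = lambda),
            class = "noise_cov")
}

# Contrast rows for all condition pairs (or a subset), optionally after the
# mean-removal control: (1) each condition pattern is set to spatial mean
# zero; (2) per pair, the least-squares contribution of the pair-mean
# pattern is projected out of the contrast.
pair_contrasts <- function(M, pairs, mean_removal = FALSE) {
  if (mean_removal) M <- M - rowMeans(M)
  C <- M[pairs$i, , drop = FALSE] - M[pairs$j, , drop = FALSE]
  if (mean_removal) {
    P <- (M[pairs$i, , drop = FALSE] + M[pairs$j, , drop = FALSE]) / 2
    pp <- rowSums(P^2)
    coef <- ifelse(pp > 0, rowSums(C * P) / pp, 0)
    C <- C - coef * P
  }
  C
}

# Core crossnobis engine shared by cv_distance and cv_rdm. Per
# leave-one-run-out fold: noise covariance from concatenated training-run
# residuals; discriminant weights w = solve(Sigma, training contrast),
# optionally unit-length normalized; fold estimate = w . test contrast.
# A zero training contrast leaves the discriminant undefined; the RDM path
# returns the continuous limit 0 (identical patterns are at distance 0),
# while an explicit single-pair query raises a degenerate-pair error.
crossnobis_engine <- function(data, pairs, estimator = "shrinkage",
                              mean_removal = FALSE, normalize = TRUE,
                              cross_validated = TRUE,
                              degenerate = c("error", "zero")) {
  if (!inherits(data, "run_dataset")) stop("data must be a run_dataset")
  degenerate <- match.arg(degenerate)
  project <- function(W, C_test) {
    if (normalize) {
      nw <- sqrt(rowSums(W^2))
      zero <- nw == 0
      if (any(zero) && degenerate == "error")
        stop("degenerate pair: zero discriminant weights")
      nw[zero] <- 1
      W <- W / nw
    }
    unname(rowSums(W * C_test))
  }
  if (!cross_validated) {
    M <- Reduce(`+`, data$patterns) / data$n_runs
    cov <- estimate_covariance(do.call(rbind, data$residuals), estimator)
    C <- pair_contrasts(M, pairs, mean_removal)
    return(project(t(solve(cov$sigma, t(C))), C))
  }
  est <- numeric(nrow(pairs))
  for (r in seq_len(data$n_runs)) {
    train <- setdiff(seq_len(data$n_runs), r)
    M_tr <- Reduce(`+`, data$patterns[train]) / length(train)
    cov <- estimate_covariance(do.call(rbind, data$residuals[train]),
                               estimator)
    C_tr <- pair_contrasts(M_tr, pairs, mean_removal)
    C_te <- pair_contrasts(data$patterns[[r]], pairs, mean_removal)
    est <- est + project(t(solve(cov$sigma, t(C_tr))), C_te)
  }
  est / data$n_runs
}

#' Cross-validated discriminant distance for one condition pair
#'
#' Crossnobis estimate: for each leave-one-run-out fold, discriminant
#' weights are the training-mean pattern contrast multiplied by the inverse
#' noise covariance (estimated from the training runs' residuals),
#' transformed to unit length, and projected onto the test run's contrast;
#' the fold estimates are averaged. The estimate is unbiased (centered on
#' 0) when the conditions do not differ and may be negative.
#'
#' With `cross_validated = FALSE`, `normalize = FALSE` and the `"full"`
#' covariance estimator, the statistic equals the squared Mahalanobis
#' distance between the mean patterns (as computed by
#' [stats::mahalanobis()]).
#'
#' @param data a [run_dataset()].
#' @param pair length-2 vector of condition indices or labels.
#' @param estimator covariance estimator, `"shrinkage"` or `"full"`.
#' @param mean_removal apply the region-mean-removal control (see
#'   [cv_rdm()]).
#' @param normalize unit-length normalize the discriminant weights
#'   (default TRUE).
#' @param cross_validated use leave-one-run-out folds (default TRUE).
#' @return a single signed distance estimate.
#' @export
cv_distance <- function(data, pair, estimator = "shrinkage",
                        mean_removal = FALSE, normalize = TRUE,
                        cross_validated = TRUE) {
  if (length(pair) != 2) stop("pair must have length 2")
  if (is.character(pair)) pair <- match(pair, data$labels)
  if (anyNA(pair)) stop("unknown condition label")
  pairs <- data.frame(i = pair[1], j = pair[2])
  crossnobis_engine(data, pairs, estimator = estimator,
                    mean_removal = mean_removal, normalize = normalize,
                    cross_validated = cross_validated)
}

#' Cross-validated distance matrix over all condition pairs
#'
#' Applies [cv_distance()] to every unordered condition pair (276 pairs for
#' the 24-condition design). The `mean_removal` control removes effects
#' attributable to the regional-mean response: each condition pattern is
#' first set to spatial mean zero (removing additive offsets between
#' conditions), then, per pair, the linear contribution of the pair-mean
#' pattern is regressed out of each pattern (removing multiplicative
#' scaling of a shared pattern); both steps are applied to training and
#' test data before contrasts. Pairs whose training contrast is exactly
#' zero (identical patterns) are reported at the continuous limit 0.
#'
#' @inheritParams cv_distance
#' @return an `rdm` with metric `"crossvalidated"` (entries may be
#'   negative; diagonal 0).
#' @export
cv_rdm <- function(data, estimator = "shrinkage", mean_removal = FALSE,
                   normalize = TRUE, cross_validated = TRUE) {
  n <- data$n_conditions
  pairs <- pair_index(n)
  est <- crossnobis_engine(data, pairs, estimator = estimator,
                           mean_removal = mean_removal,
                           normalize = normalize,
                           cross_validated = cross_validated,
                           degenerate = "zero")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- est
  m <- m + t(m)
  rdm(m, labels = data$labels, metric = "crossvalidated")
}

#' Write a run dataset as delimited text
#'
#' One `run##_patterns.tsv` and `run##_residuals.tsv` per run plus a
#' `manifest.tsv` recording dimensions.
#'
#' @param data a [run_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_run_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_len(data$n_runs)) {
    utils::write.table(
      data.frame(condition = data$labels, data$patterns[[r]],
                 check.names = FALSE),
      file.path(dir, sprintf("run%02d_patterns.tsv", r)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data$residuals[[r]],
      file.path(dir, sprintf("run%02d_residuals.tsv", r)),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(
    data.frame(n_runs = data$n_runs, n_conditions = data$n_conditions,
               n_voxels = data$n_voxels),
    file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read a run dataset written by [write_run_dataset()]
#'
#' @param dir directory written by [write_run_dataset()].
#' @return a [run_dataset()].
#' @export
read_run_dataset <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"))
  patterns <- residuals <- vector("list", man$n_runs)
  for (r in seq_len(man$n_runs)) {
    pat <- utils::read.delim(file.path(dir, sprintf("run%02d_patterns.tsv",
                                                    r)),
                             check.names = FALSE)
    m <- as.matrix(pat[, -1, drop = FALSE])
    rownames(m) <- as.character(pat[[1]])
    patterns[[r]] <- m
    residuals[[r]] <- as.matrix(utils::read.delim(
      file.path(dir, sprintf("run%02d_residuals.tsv", r)), header = FALSE))
  }
  run_dataset(patterns, residuals)
}
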