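make_dataset <- function(B, n_runs = 4, noise_sd = 0.5, n_t = 60,
                         seed = 1) {
  withr::with_seed(seed, {
    V <- ncol(B)
    pats <- lapply(seq_len(n_runs), function(r) {
      out <- B + noise_sd * matrix(rnorm(length(B)), nrow(B), V)
      rownames(out) <- rownames(B)
      out
    })
    res <- lapply(seq_len(n_runs), function(r)
      noise_sd * matrix(rnorm(n_t * V), n_t, V))
    run_dataset(pats, res)
  })
}

test_that("run_dataset validates run structure", {
  B <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(run_dataset(list(B), list(B)), "at least 2 runs")
  ds <- make_dataset(B)
  expect_equal(ds$n_runs, 4)
  expect_equal(ds$labels, c("a", "b"))
})

test_that("covariance estimation: white residuals give a near-diagonal
           estimate and shrinkage is always invertible", {
  res <- withr::with_seed(2, matrix(rnorm(5000 * 6, sd = 2), 5000, 6))
  cv <- estimate_covariance(res, "full")
  expect_equal(diag(cv$sigma), rep(4, 6), tolerance = 0.1)
  expect_lt(max(abs(cv$sigma[!diag(6)])), 0.2)
  # shrinkage with fewer timepoints than voxels stays positive-definite
  res_small <- withr::with_seed(3, matrix(rnorm(10 * 40), 10, 40))
  sh <- estimate_covariance(res_small, "shrinkage")
  ev <- eigen(sh$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(estimate_covariance(res_small, "full"), "singular")
  expect_identical(estimate_covariance(res, "shrinkage"),
                   estimate_covariance(res, "shrinkage"))
})

test_that("noiseless patterns return the Euclidean pattern distance", {
  B <- matrix(c(1, 0, 0,
                0, 2, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  ds <- withr::with_seed(4, run_dataset(
    replicate(3, B, simplify = FALSE),
    replicate(3, matrix(rnorm(4000 * 3), 4000, 3), simplify = FALSE)))
  expect_equal(cv_distance(ds, c("a", "b")), sqrt(5), tolerance = 1e-2)
})

test_that("same-data full-covariance statistic equals the brute-force
           Mahalanobis distance", {
  B <- withr::with_seed(5, matrix(rnorm(8), 2, 4,
                                  dimnames = list(c("a", "b"), NULL)))
  ds <- make_dataset(B, n_runs = 3, n_t = 200, seed = 6)
  stat <- cv_distance(ds, c("a", "b"), estimator = "full",
                      normalize = FALSE, cross_validated = FALSE)
  M <- Reduce(`+`, ds$patterns) / ds$n_runs
  S <- estimate_covariance(do.call(rbind, ds$residuals), "full")$sigma
  oracle <- stats::mahalanobis(M["a", ], M["b", ], S)
  expect_equal(stat, unname(oracle), tolerance = 1e-8)
})

test_that("cross-validated distances are centered on zero under the null", {
  null_est <- withr::with_seed(7, replicate(300, {
    ds <- run_dataset(
      lapply(1:8, function(r) matrix(rnorm(2 * 20), 2, 20,
                                     dimnames = list(c("a", "b"), NULL))),
      lapply(1:8, function(r) matrix(rnorm(40 * 20), 40, 20)))
    cv_distance(ds, c("a", "b"))
  }))
  expect_lt(abs(mean(null_est)), 3 * sd(null_est) / sqrt(300))
})

test_that("mean removal nulls additive offsets and multiplicative scaling", {
  a <- withr::with_seed(8, rnorm(30))
  B_add <- rbind(a = a, b = a + 2)
  B_mul <- rbind(a = a, b = 3 * a)
  for (B in list(B_add, B_mul)) {
    ds <- make_dataset(B, n_runs = 4, noise_sd = 0, n_t = 100, seed = 9)
    d <- cv_distance(ds, c("a", "b"), mean_removal = TRUE,
                     normalize = FALSE)
    expect_equal(d, 0, tolerance = 1e-10)
  }
  # without mean removal the same pairs are clearly separated
  ds <- make_dataset(B_add, n_runs = 4, noise_sd = 0, n_t = 100, seed = 9)
  expect_gt(cv_distance(ds, c("a", "b")), 1)
})

test_that("mean removal leaves RDMs without additive/multiplicative
           structure nearly unchanged", {
  # condition patterns with no shared mean structure
  B <- withr::with_seed(20, matrix(rnorm(24 * 40), 24, 40,
                                   dimnames = list(sprintf("c%02d", 1:24),
                                                   NULL)))
  ds <- make_dataset(B, n_runs = 8, noise_sd = 0.3, n_t = 60, seed = 21)
  r_off <- cv_rdm(ds)
  r_on <- cv_rdm(ds, mean_removal = TRUE)
  expect_gt(rdm_correlation(r_off, r_on)$r, 0.9)
})

test_that("cv_rdm covers all pairs and is invariant to run order", {
  p <- test_participant()
  ds <- simulate_runs(p, n_runs = 6, n_voxels = 30, noise_sd = 1,
                      seed = 22)
  r1 <- cv_rdm(ds)
  expect_length(rdm_vec(r1), 276)
  perm <- c(4, 1, 6, 3, 2, 5)
  ds_perm <- run_dataset(ds$patterns[perm], ds$residuals[perm])
  r2 <- cv_rdm(ds_perm)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-10)
})

test_that("cv_distance grows monotonically with true signal", {
  levels <- seq(0.5, 5, length.out = 10)
  est <- vapply(seq_along(levels), function(k) {
    B <- matrix(0, 2, 20, dimnames = list(c("a", "b"), NULL))
    B[2, ] <- levels[k] / sqrt(20)
    ds <- make_dataset(B, n_runs = 8, noise_sd = 0.3, n_t = 80,
                       seed = 100 + k)
    cv_distance(ds, c("a", "b"))
  }, numeric(1))
  expect_gt(cor(est, levels, method = "spearman"), 0.99)
})

test_that("run datasets round-trip through the text serialization", {
  p <- test_participant()
  ds <- simulate_runs(p, n_runs = 3, n_voxels = 8, n_timepoints = 10,
                      seed = 23)
  dir <- withr::local_tempdir()
  write_run_dataset(ds, dir)
  back <- read_run_dataset(dir)
  expect_equal(back$patterns, ds$patterns, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$residuals, ds$residuals, tolerance = 1e-8,
               ignore_attr = TRUE)
})
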