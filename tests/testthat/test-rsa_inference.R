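test_that("predictor partition matches the law of cosines and is complete", {
  g <- test_grid()
  des <- build_rsa_predictors(g, viewpoints = FALSE)
  ref <- reference_rdm(g, viewpoints = FALSE)
  sq <- rdm_vec(ref)^2
  # completeness: eccentricity + direction = squared reference at every pair
  expect_equal(des$X[, "eccentricity"] + des$X[, "direction"], sq,
               tolerance = 1e-12, ignore_attr = TRUE)
  faces <- g$faces
  pairs <- des$pairs
  # same-eccentricity pair 60 degrees apart at eccentricity e:
  # ecc entry 0, direction entry 2 e^2 (1 - cos 60)
  k <- which(faces$ecc[pairs$i] == 1 & faces$ecc[pairs$j] == 1 &
               abs(faces$angle_deg[pairs$i] -
                     faces$angle_deg[pairs$j]) == 60)[1]
  expect_equal(unname(des$X[k, "eccentricity"]), 0)
  expect_equal(unname(des$X[k, "direction"]), 2 * (1 - cos(pi / 3)),
               tolerance = 1e-12)
  # collinear pair at 0.3 and 1.0: ecc (0.7)^2, direction 0
  k2 <- which(faces$angle_deg[pairs$i] == faces$angle_deg[pairs$j] &
                abs(faces$ecc[pairs$i] - faces$ecc[pairs$j]) == 0.7)[1]
  expect_equal(unname(des$X[k2, "eccentricity"]), 0.49, tolerance = 1e-12)
  expect_equal(unname(des$X[k2, "direction"]), 0, tolerance = 1e-12)
})

test_that("regressing the squared reference RDM on its own partition
           returns [1, 1, 0] with no residual", {
  for (r in c(1, 2.7)) for (seed in c(1, 33)) {
    g <- build_polar_grid(r, sample_slice(50, seed = seed))
    des <- build_rsa_predictors(g)
    fit <- fit_rsa_regression(reference_rdm(g), des)
    expect_equal(unname(fit$estimates_squared),
                 c(1, 1, 0, 1, 1, 0), tolerance = 1e-10)
    expect_lt(max(abs(fit$residuals)), 1e-10)
    expect_equal(unname(fit$estimates[c(1, 2, 4, 5)]), rep(1, 4),
                 tolerance = 1e-10)
    expect_lt(max(abs(fit$estimates[c(3, 6)])), 1e-6)
  }
})

test_that("sign-preserving transforms round-trip and scale as sqrt", {
  g <- test_grid()
  des <- build_rsa_predictors(g)
  ref <- reference_rdm(g)
  doubled <- rdm(sqrt(2) * unclass(ref))
  fit <- fit_rsa_regression(doubled, des)
  # dependent = 2x squared distances -> estimates sqrt(2)
  expect_equal(unname(fit$estimates[c(1, 2, 4, 5)]), rep(sqrt(2), 4),
               tolerance = 1e-8)
  # negative entries keep their sign through the square/sqrt round trip
  v <- c(-2, 0.5, 3)
  expect_equal(sign(v) * sqrt(abs(sign(v) * v^2)), v)
})

test_that("noise ceiling bounds behave in the limits and are ordered", {
  g <- test_grid()
  ref <- reference_rdm(g)
  tight <- withr::with_seed(10, lapply(1:6, function(i)
    rdm(unclass(ref) + 1e-4 * as.matrix(dist(matrix(rnorm(48), 24))))))
  nc <- noise_ceiling(tight)
  expect_gt(nc$lower, 0.999)
  expect_gt(nc$upper, nc$lower)
  rand <- withr::with_seed(11, lapply(1:8, function(i)
    euclidean_rdm(matrix(rnorm(24 * 5), 24))))
  nc_r <- noise_ceiling(rand)
  expect_lt(abs(nc_r$lower), 0.25)
  expect_gt(nc_r$upper, nc_r$lower)
  # ordering holds across many random draws
  ok <- withr::with_seed(12, replicate(200, {
    rdms <- lapply(1:4, function(i) euclidean_rdm(matrix(rnorm(36), 12)))
    nc <- noise_ceiling(rdms)
    nc$lower_z <= nc$upper_z
  }))
  expect_true(all(ok))
  expect_error(noise_ceiling(rand[1:2]), "at least 3")
})

test_that("grid search recovers the generating cell from noise-free model
           RDMs and never trains on the evaluated participant", {
  parts <- lapply(1:4, function(s)
    list(grid = test_grid(), unit_seed = 100 + s))
  truth <- list(o = 0.5, s = 0.5, p = 0.75)
  data_rdms <- lapply(parts, function(pp)
    model_rdm(ramp_model(truth$o, truth$s, truth$p), pp$grid,
              seed = pp$unit_seed))
  grid <- default_param_grid("ramp")
  # noise-free data correlate at machine 1 with the generating cell, so
  # the Fisher-Z clip warning is expected here
  fit <- suppressWarnings(
    grid_search_fit(data_rdms, coord_model_predictor("ramp"), grid,
                    parts))
  for (w in fit$winners) {
    expect_equal(grid$o[w], truth$o)
    expect_equal(grid$s[w], truth$s)
    expect_equal(grid$p[w], truth$p)
  }
  # structural no-leakage: replacing one participant's data changes only
  # selections made by other splits, never via its own training column
  data_mod <- data_rdms
  data_mod[[2]] <- euclidean_rdm(matrix(rnorm(24 * 3), 24))
  fit_mod <- suppressWarnings(
    grid_search_fit(data_mod, coord_model_predictor("ramp"), grid,
                    parts))
  expect_identical(fit_mod$winners[2], fit$winners[2])
})

test_that("the generating family generalizes better than a mismatched
           family and averaging helps when the truth averages", {
  parts <- lapply(1:5, function(s)
    list(grid = test_grid(), unit_seed = 200 + s))
  data_rdms <- withr::with_seed(13, lapply(parts, function(pp) {
    m <- model_rdm(ramp_model(o = 0.5, s = 0.5, p = 0.75), pp$grid,
                   seed = pp$unit_seed)
    rdm(unclass(m) + as.matrix(dist(matrix(0.1 * rnorm(48), 24))))
  }))
  small_ramp <- expand.grid(o = c(0, 0.5, 1), s = c(0.5, 1),
                            p = c(0, 0.5, 0.75, 1))
  small_ex <- expand.grid(w = c(0.5, 1, 2), d = c(0.5, 1),
                          p = c(0, 0.5, 0.75, 1))
  fit_ramp <- grid_search_fit(data_rdms, coord_model_predictor("ramp"),
                              small_ramp, parts)
  fit_ex <- grid_search_fit(data_rdms, coord_model_predictor("exemplar"),
                            small_ex, parts)
  expect_gt(fit_ramp$mean_z, fit_ex$mean_z)
  fit_noavg <- grid_search_fit(data_rdms,
                               coord_model_predictor("ramp", fix_p = 0),
                               small_ramp, parts)
  cmp <- compare_fits(fit_ramp, fit_noavg)
  expect_gt(cmp$mean_diff_z, 0)
  expect_lt(cmp$p, 0.05)
})

test_that("activation-profile similarity separates opposite eccentricity
           trends", {
  g <- test_grid()
  prof_ramp <- model_activation_profile(ramp_model(o = 1, s = 0.5), g,
                                        seed = 2)
  prof_ex <- model_activation_profile(exemplar_model(w = 1, d = 1), g,
                                      seed = 2)
  expect_equal(suppressWarnings(
    activation_similarity(prof_ramp,
                          list(prof_ramp, prof_ramp, prof_ramp))$per_r),
    rep(1, 3))
  data_profiles <- withr::with_seed(14, lapply(1:6, function(i)
    prof_ramp + 0.01 * rnorm(24)))
  pos <- activation_similarity(prof_ramp, data_profiles,
                               alternative = "greater")
  expect_gt(pos$mean_z, 0)
  expect_lt(pos$p, 0.05)
  neg <- activation_similarity(prof_ex, data_profiles)
  expect_lt(neg$mean_r, 0)
})

test_that("group_t handles degenerate inputs explicitly and responds to
           location shifts", {
  z <- group_t(rep(0, 5))
  expect_identical(z$p, 1)
  expect_true(is.na(z$t))
  shifted <- group_t(rep(0.3, 5))
  expect_identical(shifted$p, 0)
  x <- c(0.1, 0.3, 0.2, 0.25, 0.15)
  t1 <- group_t(x)$t
  t2 <- group_t(x + 0.5)$t
  expect_gt(t2, t1)
})

test_that("paired-contrast ANOVA agrees with stats::aov on the same data", {
  est <- withr::with_seed(15, data.frame(
    ecc_within = rnorm(8, 1), dir_within = rnorm(8, 0.6),
    ecc_across = rnorm(8, 0.9), dir_across = rnorm(8, 0.5)))
  res <- rm_anova_2x2(est)
  long <- data.frame(
    y = unlist(est),
    metric = rep(c("ecc", "dir", "ecc", "dir"), each = 8),
    vp = rep(c("w", "w", "a", "a"), each = 8),
    id = factor(rep(1:8, 4)))
  fit_aov <- summary(stats::aov(y ~ metric * vp + Error(id / (metric * vp)),
                                data = long))
  p_aov <- c(
    metric = fit_aov[["Error: id:metric"]][[1]]["metric", "Pr(>F)"],
    viewpoint = fit_aov[["Error: id:vp"]][[1]]["vp", "Pr(>F)"],
    interaction = fit_aov[["Error: id:metric:vp"]][[1]]["metric:vp",
                                                        "Pr(>F)"])
  expect_equal(res$p, unname(p_aov), tolerance = 1e-10)
  # main-effect contrast equals the paired T on (ecc - dir) means
  tt <- t.test((est$ecc_within + est$ecc_across) / 2 -
                 (est$dir_within + est$dir_across) / 2)
  expect_equal(res$t[res$effect == "metric"], unname(tt$statistic),
               tolerance = 1e-12)
})

test_that("fold-dependence simulation is seed-reproducible and powered
           under strong signal", {
  r1 <- simulate_fold_dependence(signal_levels = c(0, 3), n_sims = 100,
                                 n_participants = 5, seed = 16)
  r2 <- simulate_fold_dependence(signal_levels = c(0, 3), n_sims = 100,
                                 n_participants = 5, seed = 16)
  expect_identical(r1, r2)
  strong <- r1[r1$signal1 == 3 & r1$signal2 == 0, ]
  expect_gt(strong$reject_model1, 0.95)
  expect_error(simulate_fold_dependence(n_sims = 50), ">= 100")
})
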