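test_that("participants are reproducible, share the reference geometry,
           and differ in stimuli", {
  p1 <- generate_participant(1, resolution = 48)
  p1b <- generate_participant(1, resolution = 48)
  p2 <- generate_participant(2, resolution = 48)
  expect_identical(p1$images, p1b$images)
  expect_identical(p1$grid$coords_2d, p1b$grid$coords_2d)
  expect_length(p1$images, 24)
  expect_equal(unclass(reference_rdm(p1$grid, embedded = TRUE)),
               unclass(reference_rdm(p2$grid, embedded = TRUE)),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(p1$images[["f01_L"]],
                                p2$images[["f01_L"]])))
})

test_that("stimulus images mirror exactly across viewpoint and share mean
           and RMS contrast", {
  imgs <- test_participant()$images
  res <- ncol(imgs[[1]])
  for (i in 1:12) {
    expect_identical(imgs[[2 * i]], imgs[[2 * i - 1]][, res:1])
  }
  means <- vapply(imgs, mean, numeric(1))
  sds <- vapply(imgs, sd, numeric(1))
  expect_lt(diff(range(means)), 1e-6)
  expect_lt(diff(range(sds)), 1e-6)
})

test_that("image content varies smoothly with face-space position", {
  p <- test_participant()
  pc <- pixelwise_correlation_rdm(p$images[seq(1, 23, 2)])
  ref <- reference_rdm(p$grid, viewpoints = FALSE)
  expect_gt(rdm_correlation(pc, ref)$r, 0.5)
})

test_that("simulated runs recover the model geometry in the noiseless
           limit and vanish under pure noise", {
  p <- test_participant()
  ds0 <- simulate_runs(p, n_runs = 4, n_voxels = 60, noise_sd = 0,
                       seed = 31)
  r0 <- cv_rdm(ds0)
  # the noiseless measurement equals the Euclidean RDM of the true voxel
  # patterns exactly; voxel pooling makes that a (deliberately) warped
  # image of the unit-space model RDM
  voxel_truth <- euclidean_rdm(attr(ds0, "true_patterns"))
  expect_equal(rdm_vec(r0), rdm_vec(voxel_truth), tolerance = 1e-6)
  truth_rdm <- model_rdm(p$ground_truth, p$grid, seed = p$unit_seed)
  expect_gt(cor(rdm_vec(r0), rdm_vec(truth_rdm), method = "spearman"),
            0.8)
  # noise >> signal: grand mean distance near 0
  est <- withr::with_seed(32, replicate(20, {
    ds <- simulate_runs(p, n_runs = 6, n_voxels = 30, noise_sd = 50,
                        seed = sample.int(1e6, 1))
    mean(rdm_vec(cv_rdm(ds)))
  }))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(20) + 0.05)
  expect_identical(simulate_runs(p, n_runs = 3, seed = 33)$patterns,
                   simulate_runs(p, n_runs = 3, seed = 33)$patterns)
})

test_that("a Gabor ground truth drives view-tolerant simulated regions", {
  bank <- test_bank()
  p <- test_participant()
  p$ground_truth <- gabor_model_spec(p_hemi = 0.5, p_global = 0.9)
  ds <- simulate_runs(p, n_runs = 4, n_voxels = 40, noise_sd = 0,
                      seed = 61)
  r <- cv_rdm(ds)
  mp <- mirror_pair_idx()
  # strong global pooling in the generating model makes mirror views of
  # one identity far more similar than average pairs
  expect_lt(mean(r[mp]) / mean(rdm_vec(r)), 0.5)
  pred <- gabor_model_predictor(bank)(
    data.frame(w1 = 1, w2 = 1, w3 = 1, w4 = 1, w5 = 1, p_hemi = 0.5,
               p_global = 0.9), p)
  expect_gt(rdm_correlation(r, pred)$r, 0.5)
})

test_that("pair-of-pairs task enumerates 2145 pairings and converges to
           the generating distances", {
  g <- test_grid()
  ref <- reference_rdm(g, viewpoints = FALSE)
  jd <- simulate_pair_of_pairs(ref, n_repeats = 1, tau = 0.1, seed = 41)
  expect_equal(nrow(jd$trials), 2145)
  expect_equal(jd$n_trials, 2145)
  expect_true(all(rdm_vec(jd$rdm) >= 0 & rdm_vec(jd$rdm) <= 100))
  # deterministic limit: percent-choice is a monotone transform of truth
  jd0 <- simulate_pair_of_pairs(ref, tau = 0, seed = 42)
  expect_equal(cor(rdm_vec(jd0$rdm), rdm_vec(ref), method = "spearman"),
               1, tolerance = 1e-10)
  # consistency grows with repeats
  r_few <- cor(rdm_vec(simulate_pair_of_pairs(ref, 1, tau = 2,
                                              seed = 43)$rdm),
               rdm_vec(ref))
  r_many <- cor(rdm_vec(simulate_pair_of_pairs(ref, 40, tau = 2,
                                               seed = 43)$rdm),
                rdm_vec(ref))
  expect_gt(r_many, r_few)
})

test_that("percent-choice RDMs from unwarped distances keep the balanced
           eccentricity/direction structure", {
  g <- test_grid()
  des <- build_rsa_predictors(g, viewpoints = FALSE)
  ratio_for <- function(dist_rdm) {
    jd <- simulate_pair_of_pairs(dist_rdm, n_repeats = 30, tau = 0.05,
                                 seed = 44)
    est <- fit_rsa_regression(jd$rdm, des)$estimates
    unname(est["eccentricity"] / est["direction"])
  }
  ref <- reference_rdm(g, viewpoints = FALSE)
  balanced <- ratio_for(ref)
  # bounded percent scale compresses large distances a little, so "equal"
  # means close to 1, and clearly distinct from a radially warped space
  expect_equal(balanced, 1, tolerance = 0.3)
  warped_sq <- 4 * des$X[, "eccentricity"] + des$X[, "direction"]
  m <- matrix(0, 12, 12)
  m[lower.tri(m)] <- sqrt(warped_sq)
  warped <- ratio_for(rdm(m + t(m), labels = rownames(ref)))
  expect_gt(warped, 1.5 * balanced)
})

test_that("trial sequences are first-order counterbalanced with augmented
           diagonals", {
  ts <- generate_trial_sequence(12, extra_diagonal = 1, seed = 51)
  expect_length(ts$sequence, 156)
  tm <- ts$transfer
  expect_true(all(tm[!diag(12)] == 1))
  expect_true(all(diag(tm) == 2))
  # smallest case: n = 2 without extra repetitions covers all 4 ordered
  # pairs in 4 trials
  ts2 <- generate_trial_sequence(2, extra_diagonal = 0, seed = 52)
  expect_length(ts2$sequence, 4)
  expect_true(all(ts2$transfer == 1))
  expect_error(generate_trial_sequence(1), ">= 2")
})

test_that("viewpoint randomization keeps 24-condition transfers
           homogeneous and collapses to the 12-condition backbone", {
  ts <- generate_trial_sequence(12, seed = 53)
  rv <- randomize_viewpoints(ts, seed = 54)
  expect_true(all(rv$transfer24[!diag(24)] <= 1))
  expect_equal((rv$sequence24 + 1) %/% 2, ts$sequence)
  expect_equal(sum(rv$transfer24), 156)
  rv2 <- randomize_viewpoints(ts, seed = 55)
  expect_false(identical(rv$sequence24, rv2$sequence24))
  expect_equal((rv2$sequence24 + 1) %/% 2, ts$sequence)
})

test_that("participant directories serialize grid, images and manifest", {
  p <- generate_participant(9, resolution = 48)
  dir <- withr::local_tempdir()
  write_participant(p, dir)
  expect_true(file.exists(file.path(dir, "grid.tsv")))
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_length(pngs, 24)
  img_back <- png::readPNG(file.path(dir, "f01_L.png"))
  expect_equal(img_back, pmin(pmax(p$images[["f01_L"]], 0), 1),
               tolerance = 1 / 255, ignore_attr = TRUE)
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^seed=9$", manifest)))
  expect_true(any(grepl("^ground_truth=ramp_model$", manifest)))
})
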