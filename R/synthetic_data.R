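# Sub-seed derivation: deterministic, distinct streams per component, kept
# below 2^31 - 1 so they remain valid R integer seeds.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483629)
}

#' Generate synthetic face-stimulus images for a participant
#'
#' Synthetic stand-in for rendered face stimuli (the photorealistic
#' morphable-model renders are out of scope). Each identity's image is a
#' deterministic smooth function of its D-dimensional face-space
#' coordinate: a participant-specific very smooth "norm" field (an oval
#' blob with little band-pass energy) plus D participant-specific
#' band-limited random fields (sinusoid mixtures with wavelengths inside
#' the Gabor banks' passband) weighted linearly by the embedded
#' coordinates, multiplied by a feathered oval aperture. The right
#' viewpoint is the exact horizontal mirror of the left. All 24 images are
#' normalized to identical mean intensity and root-mean-square contrast.
#' Because the identity content is band-limited while the norm is not,
#' band-pass contrast grows with face-space eccentricity at fixed RMS.
#'
#' @param grid a `face_grid`.
#' @param basis the participant's `slice_basis` (defines D).
#' @param seed integer seed for the participant-specific texture.
#' @param resolution image side in pixels (>= 32, default 96).
#' @param norm_strength amplitude of the norm field relative to a
#'   unit-eccentricity identity (default 2).
#' @param target_mean,target_sd common mean intensity and RMS contrast of
#'   the output images.
#' @return named list of 24 `resolution` x `resolution` matrices in
#'   condition order (`f01_L, f01_R, ...`).
#' @export
generate_face_images <- function(grid, basis, seed, resolution = 96,
                                 norm_strength = 2, target_mean = 0.5,
                                 target_sd = 0.08) {
  if (resolution < 32) stop("resolution must be >= 32")
  D <- basis$D
  n_waves <- 10
  ax <- seq(-1, 1, length.out = resolution)
  xg <- matrix(ax, resolution, resolution, byrow = TRUE)   # x across columns
  yg <- matrix(ax, resolution, resolution)
  build <- function() {
    # norm field: smooth oval blob, energy concentrated far below the
    # band-limited identity content
    base <- exp(-(xg^2 / 0.3 + yg^2 / 0.5))
    base <- (base - mean(base)) / stats::sd(base)
    fields <- matrix(0, resolution^2, D)
    for (d in seq_len(D)) {
      f <- 0
      freq <- stats::runif(n_waves, 4, 20)      # cycles per image
      theta <- stats::runif(n_waves, 0, pi)
      phase <- stats::runif(n_waves, 0, 2 * pi)
      amp <- stats::rnorm(n_waves) / sqrt(n_waves)
      for (m in seq_len(n_waves)) {
        f <- f + amp[m] * cos(pi * freq[m] *
                                (xg * cos(theta[m]) + yg * sin(theta[m])) +
                              phase[m])
      }
      fields[, d] <- as.vector((f - mean(f)) / stats::sd(f))
    }
    rho <- sqrt((xg / 0.75)^2 + (yg / 0.9)^2)
    mask <- stats::plogis((0.85 - rho) / 0.05)
    raw <- fields %*% t(grid$embedded) +
      norm_strength * as.vector(base)
    out <- vector("list", 24)
    names(out) <- condition_labels(grid)
    for (i in seq_len(12)) {
      img <- matrix(raw[, i], resolution, resolution) * mask
      img <- (img - mean(img)) / stats::sd(img) * target_sd + target_mean
      out[[2 * i - 1]] <- img
      out[[2 * i]] <- img[, resolution:1]     # horizontal mirror
    }
    out
  }
  withr::with_seed(seed, build())
}

#' Generate a synthetic participant
#'
#' One participant = a random slice orientation through the D-dimensional
#' reference space (so the 12-face grid RDM is identical across
#' participants while the stimuli are physically distinct), the polar face
#' grid, 24 synthetic stimulus images, a ground-truth encoding model, and
#' deterministic sub-seeds for unit sampling and run simulation. Fully
#' reproducible from `seed`.
#'
#' @param seed integer participant seed.
#' @param D reference-space dimensionality (default 50).
#' @param r mean eccentricity (default 1).
#' @param ground_truth an `encoding_model` generating this participant's
#'   responses (default: ramp model with strong population averaging).
#' @param resolution stimulus image side in pixels.
#' @param images generate the stimulus images (default TRUE; skip for
#'   coordinate-only analyses).
#' @return object of class `synthetic_participant`.
#' @export
generate_participant <- function(seed, D = 50, r = 1,
                                 ground_truth = ramp_model(o = 0, s = 1,
                                                           p = 0.9),
                                 resolution = 96, images = TRUE) {
  basis <- sample_slice(D, seed = derive_seed(seed, 1))
  grid <- build_polar_grid(r, basis)
  imgs <- if (images)
    generate_face_images(grid, basis, seed = derive_seed(seed, 2),
                         resolution = resolution)
  structure(list(seed = seed, D = D, r = r, basis = basis, grid = grid,
                 images = imgs, resolution = resolution,
                 ground_truth = ground_truth,
                 unit_seed = derive_seed(seed, 3),
                 run_seed = derive_seed(seed, 4)),
            class = "synthetic_participant")
}

#' @export
print.synthetic_participant <- function(x, ...) {
  cat(sprintf(
    "Synthetic participant (seed %d): D = %d, r = %g, %s images, truth = %s\n",
    x$seed, x$D, x$r, if (is.null(x$images)) "no" else "24",
    class(x$ground_truth)[1]))
  invisible(x)
}

#' Simulate run-wise fMRI-like pattern estimates
#'
#' Voxel patterns emulate local non-negative pooling of neuronal activity:
#' each voxel is a uniform non-negative weighted average of the
#' ground-truth model's unit responses (for a [gabor_model_spec()] ground
#' truth, of the pooled Gabor contrast energies of the participant's own
#' images). The true pattern matrix is scaled
#' to unit mean across-condition standard deviation so `noise_sd` is the
#' noise-to-signal ratio directly. Per run, the pattern estimates receive
#' additive Gaussian noise with mild spatial correlation
#' (`cov[i,j] = noise_sd^2 * rho^|i-j|`), and a residual time-course
#' matrix is drawn from the same covariance for noise-covariance
#' estimation.
#'
#' @param participant a `synthetic_participant`.
#' @param n_runs number of runs (default 16).
#' @param n_voxels voxels in the simulated region (default 100).
#' @param noise_sd noise standard deviation relative to pattern signal
#'   (default 1).
#' @param n_timepoints residual timepoints per run (default 100).
#' @param rho neighboring-voxel noise correlation (default 0.3).
#' @param seed integer seed (default: the participant's run seed).
#' @return a [run_dataset()]; attribute `true_patterns` holds the
#'   noiseless condition-by-voxel matrix.
#' @export
simulate_runs <- function(participant, n_runs = 16, n_voxels = 100,
                          noise_sd = 1, n_timepoints = 100, rho = 0.3,
                          seed = NULL) {
  if (is.null(seed)) seed <- participant$run_seed
  gt <- participant$ground_truth
  U <- if (inherits(gt, "gabor_model_spec")) {
    if (is.null(participant$images))
      stop("Gabor ground truth needs a participant with images")
    gabor_feature_vector(participant$images,
                         cached_filter_bank(participant$resolution), gt)
  } else {
    model_responses(gt, participant$grid, seed = participant$unit_seed)
  }
  build <- function() {
    W <- matrix(stats::runif(nrow(U) * n_voxels), nrow(U), n_voxels)
    B <- t(U) %*% W / nrow(U)
    sig <- mean(apply(B, 2, stats::sd))
    if (sig > 0) B <- B / sig
    R <- chol(rho^abs(outer(seq_len(n_voxels), seq_len(n_voxels), "-")))
    patterns <- residuals <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      patterns[[r]] <- B + noise_sd *
        (matrix(stats::rnorm(24 * n_voxels), 24, n_voxels) %*% R)
      rownames(patterns[[r]]) <- condition_labels(participant$grid)
      residuals[[r]] <- noise_sd *
        (matrix(stats::rnorm(n_timepoints * n_voxels), n_timepoints,
                n_voxels) %*% R)
    }
    out <- run_dataset(patterns, residuals)
    attr(out, "true_patterns") <- B
    out
  }
  withr::with_seed(seed, build())
}

#' Simulate the pair-of-pairs similarity judgment task
#'
#' Enumerates all pairings of the 66 face pairs (2145 per repeat); on each
#' trial the probability of choosing pair 1 as more dissimilar follows a
#' logistic link on the true distance difference,
#' `plogis((d1 - d2) / tau)`; `tau = 0` gives the deterministic argmax
#' (tied distances split exactly at chance). Choices aggregate into the
#' percent-choice RDM:
#' each entry is the percentage of its trials on which that pair was rated
#' relatively more dissimilar.
#'
#' @param distances a 12-condition `rdm` (or any RDM) of true distances.
#' @param n_repeats repeats of the full 2145-trial set (default 1).
#' @param tau decision noise (>= 0, default 0.1 in distance units).
#' @param seed optional integer seed.
#' @return object of class `judgment_dataset`: `trials` (pair indices and
#'   choice counts), `rdm` (percent-choice), `n_trials`.
#' @export
simulate_pair_of_pairs <- function(distances, n_repeats = 1, tau = 0.1,
                                   seed = NULL) {
  if (tau < 0) stop("tau must be >= 0")
  d <- rdm_vec(distances)
  n_pairs <- length(d)
  pairings <- utils::combn(n_pairs, 2)
  run <- function() {
    d1 <- d[pairings[1, ]]
    d2 <- d[pairings[2, ]]
    if (tau > 0) {
      prob <- stats::plogis((d1 - d2) / tau)
      chose1 <- stats::rbinom(length(prob), n_repeats, prob)
    } else {
      # deterministic limit: tied distances split exactly at chance
      chose1 <- n_repeats * ((d1 > d2) + 0.5 * (d1 == d2))
    }
    wins <- trials <- numeric(n_pairs)
    for (k in seq_len(ncol(pairings))) {
      a <- pairings[1, k]; b <- pairings[2, k]
      wins[a] <- wins[a] + chose1[k]
      wins[b] <- wins[b] + n_repeats - chose1[k]
      trials[a] <- trials[a] + n_repeats
      trials[b] <- trials[b] + n_repeats
    }
    pct <- 100 * wins / trials
    n <- nrow(distances)
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- pct
    m <- m + t(m)
    structure(list(
      trials = data.frame(pair1 = pairings[1, ], pair2 = pairings[2, ],
                          chose1 = chose1, n = n_repeats),
      rdm = rdm(m, labels = rownames(distances),
                metric = "percent-choice"),
      n_trials = ncol(pairings) * n_repeats), class = "judgment_dataset")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Transfer matrix of a condition sequence
#'
#' Counts of ordered condition-to-condition transitions; cyclic sequences
#' include the wrap-around transition.
#'
#' @param sequence integer condition indices.
#' @param n number of conditions.
#' @param cyclic include the last-to-first transition (default TRUE).
#' @return n x n integer matrix of transition counts.
#' @export
transfer_matrix <- function(sequence, n, cyclic = TRUE) {
  from <- sequence
  to <- c(sequence[-1], if (cyclic) sequence[1])
  if (!cyclic) from <- from[-length(from)]
  m <- matrix(0L, n, n)
  for (k in seq_along(from))
    m[from[k], to[k]] <- m[from[k], to[k]] + 1L
  m
}

#' Generate a first-order counterbalanced trial sequence
#'
#' De Bruijn-style sequence over `n_conditions` in which every ordered
#' condition pair occurs exactly once and every condition repeats itself
#' `1 + extra_diagonal` times (the extra diagonal repetitions make a
#' one-back task engaging and raise design efficiency). Constructed as a
#' seeded Eulerian circuit (Hierholzer's algorithm) over the complete
#' transition multigraph with augmented self-loops; the circuit always
#' exists because the graph is connected with balanced degrees. Trial
#' count is `n^2 + n * extra_diagonal` (156 for 12 conditions with one
#' extra repetition).
#'
#' @param n_conditions number of conditions (>= 2, default 12).
#' @param extra_diagonal extra self-transitions per condition (default 1).
#' @param seed optional integer seed (shuffles edge order).
#' @return object of class `trial_sequence`: `sequence` (cyclic condition
#'   indices), `n_conditions`, `transfer` (cyclic transfer matrix).
#' @export
generate_trial_sequence <- function(n_conditions = 12, extra_diagonal = 1,
                                    seed = NULL) {
  if (n_conditions < 2) stop("n_conditions must be >= 2")
  if (extra_diagonal < 0) stop("extra_diagonal must be >= 0")
  n <- n_conditions
  build <- function() {
    adj <- lapply(seq_len(n), function(i) {
      targets <- c(setdiff(seq_len(n), i), rep(i, 1 + extra_diagonal))
      sample(targets)
    })
    ptr <- rep(1L, n)
    stack <- 1L
    circuit <- integer(0)
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      if (ptr[v] <= length(adj[[v]])) {
        u <- adj[[v]][ptr[v]]
        ptr[v] <- ptr[v] + 1L
        stack <- c(stack, u)
      } else {
        circuit <- c(circuit, v)
        stack <- stack[-length(stack)]
      }
    }
    seqn <- rev(circuit)[-1]              # drop repeated start: cyclic form
    structure(list(sequence = seqn, n_conditions = n,
                   transfer = transfer_matrix(seqn, n)),
              class = "trial_sequence")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("Trial sequence: %d conditions, %d trials (cyclic)\n",
              x$n_conditions, length(x$sequence)))
  invisible(x)
}

#' Randomize viewpoints over a counterbalanced sequence
#'
#' Assigns a left/right viewpoint to every trial of a 12-condition
#' sequence and resamples until the resulting 24-condition transfer matrix
#' has all off-diagonal entries in {0, 1} (each stimulus-to-stimulus
#' transfer appears once or not at all), keeping run sequences homogeneous
#' for leave-one-run-out cross-validation.
#'
#' @param sequence a `trial_sequence` over 12 (or any) conditions.
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling budget (default 1000).
#' @return list: `sequence24` (24-condition indices, identity-major then
#'   viewpoint), `viewpoints` (`"L"`/`"R"` per trial), `transfer24`,
#'   `tries`.
#' @export
randomize_viewpoints <- function(sequence, seed = NULL, max_tries = 1000) {
  if (!inherits(sequence, "trial_sequence"))
    stop("sequence must be a trial_sequence")
  base <- sequence$sequence
  n24 <- 2 * sequence$n_conditions
  run <- function() {
    for (try in seq_len(max_tries)) {
      vp <- sample(1:2, length(base), replace = TRUE)
      seq24 <- 2L * (base - 1L) + vp
      tm <- transfer_matrix(seq24, n24)
      if (max(tm[!diag(n24)]) <= 1L) {
        return(list(sequence24 = seq24,
                    viewpoints = c("L", "R")[vp],
                    transfer24 = tm, tries = try))
      }
    }
    stop("viewpoint randomization failed within max_tries")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a participant's stimulus directory
#'
#' Grid as delimited text, the 24 stimulus images as 8-bit gray PNGs
#' (intensities clamped to [0, 1] at write time), and a plain key-value
#' manifest recording seeds and parameters.
#'
#' @param participant a `synthetic_participant` with images.
#' @param dir output directory (created if needed).
#' @export
write_participant <- function(participant, dir) {
  if (is.null(participant$images))
    stop("participant was generated without images")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(participant$grid, file.path(dir, "grid.tsv"))
  for (nm in names(participant$images)) {
    img <- pmin(pmax(participant$images[[nm]], 0), 1)
    png::writePNG(img, file.path(dir, paste0(nm, ".png")))
  }
  gt <- participant$ground_truth
  manifest <- c(
    sprintf("seed=%d", participant$seed),
    sprintf("D=%d", participant$D),
    sprintf("r=%g", participant$r),
    sprintf("resolution=%d", participant$resolution),
    sprintf("unit_seed=%d", participant$unit_seed),
    sprintf("run_seed=%d", participant$run_seed),
    sprintf("ground_truth=%s", class(gt)[1]),
    sprintf("ground_truth_params=%s",
            paste(sprintf("%s=%g", setdiff(names(gt), "n_units"),
                          unlist(gt[setdiff(names(gt), "n_units")])),
                  collapse = ",")))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
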