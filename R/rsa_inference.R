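#' Build the regression-RSA predictor set
#'
#' Partitions the squared reference distances into eccentricity and
#' direction components: for a condition pair with eccentricities
#' `(e_i, e_j)` the eccentricity predictor is `(e_i - e_j)^2` (the minimum
#' squared distance within the pair's eccentricity group, attained when
#' direction does not change), and the direction predictor is the squared
#' reference distance minus the eccentricity entry. The partition is
#' complete: eccentricity + direction equals the squared reference
#' distance at every pair. With `viewpoints = TRUE` each of the three
#' predictors (eccentricity, direction, constant) is split into
#' within-viewpoint and across-viewpoint copies (six columns over the 276
#' pairs); otherwise three columns over the 66 pairs.
#'
#' @param grid a `face_grid`.
#' @param viewpoints build the 24-condition, six-predictor design
#'   (default TRUE).
#' @return object of class `rsa_design`: list with `X` (pair-by-predictor
#'   matrix), `pairs`, and `labels`.
#' @export
build_rsa_predictors <- function(grid, viewpoints = TRUE) {
  ref <- reference_rdm(grid, viewpoints = viewpoints)
  labels <- rownames(ref)
  n <- nrow(ref)
  pairs <- pair_index(n)
  sq <- rdm_vec(ref)^2
  ecc_of <- if (viewpoints) rep(grid$faces$ecc, each = 2) else grid$faces$ecc
  ecc <- (ecc_of[pairs$i] - ecc_of[pairs$j])^2
  dir <- sq - ecc
  if (!viewpoints) {
    X <- cbind(eccentricity = ecc, direction = dir, constant = 1)
  } else {
    vp <- rep(c("L", "R"), times = n / 2)
    within <- vp[pairs$i] == vp[pairs$j]
    X <- cbind(ecc_within = ecc * within, dir_within = dir * within,
               const_within = as.numeric(within),
               ecc_across = ecc * !within, dir_across = dir * !within,
               const_across = as.numeric(!within))
  }
  structure(list(X = X, pairs = pairs, labels = labels),
            class = "rsa_design")
}

#' Fit the multiple-regression RSA model
#'
#' The dependent distances are squared with their sign preserved
#' (`sign(x) * x^2`, so cross-validated negative estimates keep their
#' sign), regressed on the design by ordinary least squares, and the
#' resulting parameter estimates are square-root transformed back with
#' their signs preserved (`sign(b) * sqrt(|b|)`). Fitting the squared
#' reference distance matrix itself returns eccentricity = 1,
#' direction = 1, constant = 0 with zero residual.
#'
#' @param data_rdm an `rdm` over the design's condition set.
#' @param design an `rsa_design` from [build_rsa_predictors()].
#' @return object of class `rsa_fit`: `estimates` (back-transformed,
#'   signed), `estimates_squared` (raw OLS coefficients), `fitted` and
#'   `residuals` (in squared-distance space).
#' @export
fit_rsa_regression <- function(data_rdm, design) {
  v <- rdm_vec(data_rdm)
  if (length(v) != nrow(design$X))
    stop("data RDM and design cover different pair sets")
  y <- sign(v) * v^2
  qrX <- qr(design$X)
  if (qrX$rank < ncol(design$X)) stop("rank-deficient design")
  b <- qr.coef(qrX, y)
  fitted <- drop(design$X %*% b)
  structure(list(estimates = sign(b) * sqrt(abs(b)),
                 estimates_squared = b, fitted = fitted,
                 residuals = y - fitted),
            class = "rsa_fit")
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat("Regression RSA fit (back-transformed estimates):\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Noise ceiling for distance-matrix correlations
#'
#' Bounds on the Fisher-Z correlation the true model could achieve given
#' between-participant variability. Lower bound: leave-one-participant-out
#' -- each participant's distances are correlated with the mean of the
#' other participants' distances. Upper bound: the same using the grand
#' mean including the participant (in-sample, optimistic). Averaging is on
#' the Fisher-Z scale; bounds are reported as r after the reverse
#' transform.
#'
#' @param participant_rdms list of >= 3 RDMs over the same conditions.
#' @return object of class `noise_ceiling`: list with `lower`, `upper`
#'   (r scale) and `lower_z`, `upper_z`.
#' @export
noise_ceiling <- function(participant_rdms) {
  n <- length(participant_rdms)
  if (n < 3) stop("need at least 3 participants")
  V <- vapply(participant_rdms, rdm_vec,
              numeric(length(rdm_vec(participant_rdms[[1]]))))
  grand <- rowMeans(V)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    lo[i] <- fisher_z(stats::cor(rowMeans(V[, -i, drop = FALSE]), V[, i]))
    hi[i] <- fisher_z(stats::cor(grand, V[, i]))
  }
  structure(list(lower = fisher_z_inv(mean(lo)),
                 upper = fisher_z_inv(mean(hi)),
                 lower_z = mean(lo), upper_z = mean(hi)),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("Noise ceiling (r): lower %.3f, upper %.3f\n",
              x$lower, x$upper))
  invisible(x)
}

#' Default parameter grids for model fitting
#'
#' Grid-search cells for each model family, expressed relative to the mean
#' eccentricity `r` of the face grid where the parameter carries
#' face-space units.
#'
#' @param family `"ramp"`, `"exemplar"` or `"gabor"`.
#' @param r mean eccentricity scale (default 1).
#' @return data.frame, one row per grid cell.
#' @export
default_param_grid <- function(family = c("ramp", "exemplar", "gabor"),
                               r = 1) {
  family <- match.arg(family)
  p_grid <- c(0, 0.25, 0.5, 0.75, 0.9, 1)
  switch(family,
    ramp = expand.grid(o = c(0, 0.5, 1, 2) * r,
                       s = c(0.1, 0.5, 1, 4) * r, p = p_grid,
                       KEEP.OUT.ATTRS = FALSE),
    exemplar = expand.grid(w = c(0.25, 0.5, 1, 2, 4) * r,
                           d = c(0.1, 0.5, 1, 3), p = p_grid,
                           KEEP.OUT.ATTRS = FALSE),
    gabor = {
      w <- c(0, 0.25, 0.5, 1)
      g <- expand.grid(w1 = w, w2 = w, w3 = w, w4 = w, w5 = w,
                       p_hemi = c(0, 0.5, 0.9, 1),
                       p_global = c(0, 0.5, 0.9, 1),
                       KEEP.OUT.ATTRS = FALSE)
      g[rowSums(g[, 1:5]) > 0, , drop = FALSE]
    })
}

#' RDM predictor for coordinate-input model families
#'
#' Returns a function `f(params, participant)` that builds the family's
#' encoding model from one parameter-grid row and predicts the RDM for the
#' participant's own stimulus grid (using the participant's unit seed, so
#' the prediction is deterministic per participant).
#'
#' @param family `"ramp"`, `"exemplar"` or `"exemplar_inverted"`.
#' @param n_units model units per prediction (default 1000).
#' @param fix_p optionally force the averaging strength to a fixed value
#'   (e.g. 0 for the averaging-disabled model variant); NULL uses the
#'   grid's `p`.
#' @return function suitable as `predict_rdm` in [grid_search_fit()].
#' @export
coord_model_predictor <- function(family = c("ramp", "exemplar",
                                             "exemplar_inverted"),
                                  n_units = 1000, fix_p = NULL) {
  family <- match.arg(family)
  function(params, participant) {
    p <- if (is.null(fix_p)) params$p else fix_p
    model <- switch(family,
      ramp = ramp_model(o = params$o, s = params$s, p = p,
                        n_units = n_units),
      exemplar = exemplar_model(w = params$w, d = params$d, p = p,
                                n_units = n_units),
      exemplar_inverted = exemplar_model(w = params$w, d = params$d,
                                         p = p, inverted = TRUE,
                                         n_units = n_units))
    model_rdm(model, participant$grid, seed = participant$unit_seed)
  }
}

#' Grid-search model fitting with leave-one-participant-out CV
#'
#' For every (participant, grid cell) the Fisher-Z correlation between the
#' cell's predicted RDM -- built from that participant's own stimuli, so
#' evaluation stimuli are never seen in fitting -- and the participant's
#' data RDM is computed once. Each leave-one-participant-out split then
#' selects the cell maximizing the mean Z over the training participants
#' (ties broken by the first cell in row-major grid order) and records the
#' left-out participant's Z for that cell. A participant's data never
#' enters their own training split.
#'
#' @param data_rdms list of participant data RDMs.
#' @param predict_rdm function `(params, participant) -> rdm`, e.g. from
#'   [coord_model_predictor()].
#' @param param_grid data.frame of grid cells (one row per cell).
#' @param participants list parallel to `data_rdms` passed through to
#'   `predict_rdm`; defaults to the participant index.
#' @return object of class `fit_result`: `z` (participant x cell matrix),
#'   `winners` (winning cell per split), `split_z`, `mean_z`, `mean_r`,
#'   and `param_grid`.
#' @export
grid_search_fit <- function(data_rdms, predict_rdm, param_grid,
                            participants = NULL) {
  P <- length(data_rdms)
  if (P < 2) stop("need at least 2 participants")
  if (nrow(param_grid) < 1) stop("empty parameter grid")
  if (is.null(participants)) participants <- as.list(seq_len(P))
  Z <- matrix(NA_real_, P, nrow(param_grid))
  for (i in seq_len(P)) {
    for (cll in seq_len(nrow(param_grid))) {
      pred <- predict_rdm(param_grid[cll, , drop = FALSE],
                          participants[[i]])
      Z[i, cll] <- rdm_correlation(pred, data_rdms[[i]])$z
    }
  }
  winners <- integer(P)
  split_z <- numeric(P)
  for (i in seq_len(P)) {
    train_mean <- colMeans(Z[-i, , drop = FALSE])
    winners[i] <- which.max(train_mean)
    split_z[i] <- Z[i, winners[i]]
  }
  structure(list(param_grid = param_grid, z = Z, winners = winners,
                 split_z = split_z, mean_z = mean(split_z),
                 mean_r = fisher_z_inv(mean(split_z))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Grid-search fit: %d cells, %d splits; group mean Z = %.3f (r = %.3f)\n",
    nrow(x$param_grid), length(x$split_z), x$mean_z, x$mean_r))
  cat("Winning cells per split:\n")
  print(cbind(split = seq_along(x$winners),
              x$param_grid[x$winners, , drop = FALSE]))
  invisible(x)
}

#' Compare two fitted models with a paired T test
#'
#' Two-tailed paired T test on the per-split Fisher-Z generalization
#' performance of two [grid_search_fit()] results over the same
#' participants.
#'
#' @param fit_a,fit_b `fit_result` objects with equal split counts.
#' @return list with `mean_diff_z`, `t`, `df`, `p`.
#' @export
compare_fits <- function(fit_a, fit_b) {
  if (length(fit_a$split_z) != length(fit_b$split_z))
    stop("fits cover different split counts")
  gt <- group_t(fit_a$split_z - fit_b$split_z)
  list(mean_diff_z = mean(fit_a$split_z - fit_b$split_z),
       t = gt$t, df = gt$df, p = gt$p)
}

#' Activation-profile similarity analysis
#'
#' Correlates a model's predicted population-mean activation profile with
#' each participant's regional-mean profile (profiles are Z-scored per
#' participant before correlating, which leaves the Pearson coefficient
#' unchanged but matches how profiles are visualized), Fisher-Z transforms
#' the coefficients and runs a group T test.
#'
#' @param model_profile numeric profile (one value per condition), or a
#'   list with one profile per participant.
#' @param data_profiles list of per-participant regional-mean profiles.
#' @param alternative T-test alternative (default `"two.sided"`).
#' @return list with `per_r`, `per_z`, `mean_z`, `mean_r`, `t`, `df`, `p`.
#' @export
activation_similarity <- function(model_profile, data_profiles,
                                  alternative = "two.sided") {
  P <- length(data_profiles)
  per_r <- numeric(P)
  for (i in seq_len(P)) {
    mp <- if (is.list(model_profile)) model_profile[[i]] else model_profile
    if (stats::sd(mp) == 0 || stats::sd(data_profiles[[i]]) == 0)
      stop("constant activation profile: correlation undefined")
    per_r[i] <- stats::cor(scale(mp)[, 1], scale(data_profiles[[i]])[, 1])
  }
  per_z <- fisher_z(per_r)
  gt <- group_t(per_z, alternative = alternative)
  list(per_r = per_r, per_z = per_z, mean_z = mean(per_z),
       mean_r = fisher_z_inv(mean(per_z)), t = gt$t, df = gt$df, p = gt$p)
}

#' One-sample group T test with explicit degenerate handling
#'
#' One-sample T test of per-participant statistics against `mu`. When the
#' inputs have zero spread the T statistic is undefined; that path is
#' handled explicitly: p = 1 (and t = NA) when every value equals `mu`,
#' otherwise t = +-Inf with the p value implied by the alternative.
#'
#' @param x per-participant values (length >= 2).
#' @param mu null value (default 0).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
group_t <- function(x, mu = 0,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2) stop("need at least 2 values")
  if (stats::sd(x) == 0) {
    if (all(x == mu))
      return(list(t = NA_real_, df = length(x) - 1, p = 1, mean = mu))
    tt <- sign(mean(x) - mu) * Inf
    p <- switch(alternative,
                two.sided = 0,
                greater = if (tt > 0) 0 else 1,
                less = if (tt < 0) 0 else 1)
    return(list(t = tt, df = length(x) - 1, p = p, mean = mean(x)))
  }
  ht <- stats::t.test(x, mu = mu, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(x))
}

#' Two-factor repeated-measures ANOVA on regression-RSA estimates
#'
#' 2 x 2 design (face-space metric: eccentricity vs direction; viewpoint:
#' within vs across) implemented via paired contrasts: each main effect
#' and the interaction is a one-sample T test on the corresponding
#' per-participant contrast score, the exact repeated-measures
#' decomposition for a 2 x 2 within-participant design.
#'
#' @param estimates participant-by-4 matrix or data.frame with columns
#'   `ecc_within`, `dir_within`, `ecc_across`, `dir_across`.
#' @return data.frame with one row per effect (metric, viewpoint,
#'   interaction): contrast mean, t, df, p.
#' @export
rm_anova_2x2 <- function(estimates) {
  estimates <- as.data.frame(estimates)
  need <- c("ecc_within", "dir_within", "ecc_across", "dir_across")
  if (!all(need %in% names(estimates)))
    stop("estimates must have columns ", paste(need, collapse = ", "))
  con <- list(
    metric = (estimates$ecc_within + estimates$ecc_across) / 2 -
      (estimates$dir_within + estimates$dir_across) / 2,
    viewpoint = (estimates$ecc_within + estimates$dir_within) / 2 -
      (estimates$ecc_across + estimates$dir_across) / 2,
    interaction = (estimates$ecc_within - estimates$dir_within) -
      (estimates$ecc_across - estimates$dir_across))
  out <- lapply(names(con), function(nm) {
    gt <- group_t(con[[nm]])
    data.frame(effect = nm, mean_contrast = mean(con[[nm]]),
               t = gt$t, df = gt$df, p = gt$p)
  })
  do.call(rbind, out)
}

#' Fold-dependence false-positive simulation
#'
#' Leave-one-participant-out generalization estimates are partially
#' dependent (splits share training participants), which could inflate
#' false-positive rates of T tests over splits. This simulation measures
#' the actual rejection probabilities: two arbitrary fixed model RDMs are
#' drawn per simulation, each family carries a small nuisance grid (the
#' model mixed with a family-specific distractor RDM at the `mix_grid`
#' proportions) selected on the training participants, and per-split
#' Fisher-Z performance is tested with one-tailed T tests against 0 (per
#' model) and a two-tailed paired T test of zero model difference, at
#' p < 0.05. With both signal levels 0 the difference-test rejection rate
#' estimates the procedure's null calibration.
#'
#' @param signal_levels numeric vector; all ordered pairs are simulated.
#' @param n_sims simulations per signal pair (>= 100).
#' @param n_participants simulated participants per dataset.
#' @param n_conditions conditions per RDM (default 12).
#' @param noise_sd between-participant noise standard deviation.
#' @param mix_grid nuisance-grid mixing proportions (default 0, 0.1, 0.2:
#'   candidate predictions within a family stay highly correlated, as
#'   neighboring cells of a real parameter grid are; larger proportions
#'   make the candidate set more diverse and strengthen the fold
#'   dependence).
#' @param seed optional integer seed.
#' @return data.frame: signal1, signal2, rejection rates for model-1 > 0,
#'   model-2 > 0, and the model-difference test.
#' @export
simulate_fold_dependence <- function(signal_levels = c(0, 0.5),
                                     n_sims = 1000, n_participants = 6,
                                     n_conditions = 12, noise_sd = 1,
                                     mix_grid = c(0, 0.1, 0.2),
                                     seed = NULL) {
  if (n_sims < 100) stop("n_sims must be >= 100")
  run <- function() {
    n_pairs <- n_conditions * (n_conditions - 1) / 2
    combos <- expand.grid(signal1 = signal_levels,
                          signal2 = signal_levels,
                          KEEP.OUT.ATTRS = FALSE)
    res <- lapply(seq_len(nrow(combos)), function(ci) {
      s <- unlist(combos[ci, ])
      rej <- matrix(FALSE, n_sims, 3)
      for (sim in seq_len(n_sims)) {
        m <- replicate(2, stats::runif(n_pairs))
        dstr <- replicate(2, stats::runif(n_pairs))
        cand <- lapply(1:2, function(k)
          vapply(mix_grid, function(g) (1 - g) * m[, k] + g * dstr[, k],
                 numeric(n_pairs)))
        data_v <- vapply(seq_len(n_participants), function(i)
          s[1] * m[, 1] + s[2] * m[, 2] +
            stats::rnorm(n_pairs, sd = noise_sd), numeric(n_pairs))
        split_z <- matrix(NA_real_, n_participants, 2)
        for (k in 1:2) {
          Z <- fisher_z(stats::cor(data_v, cand[[k]]))
          for (i in seq_len(n_participants)) {
            win <- which.max(colMeans(Z[-i, , drop = FALSE]))
            split_z[i, k] <- Z[i, win]
          }
        }
        rej[sim, 1] <- group_t(split_z[, 1],
                               alternative = "greater")$p < 0.05
        rej[sim, 2] <- group_t(split_z[, 2],
                               alternative = "greater")$p < 0.05
        rej[sim, 3] <- group_t(split_z[, 1] - split_z[, 2])$p < 0.05
      }
      data.frame(signal1 = s[1], signal2 = s[2],
                 reject_model1 = mean(rej[, 1]),
                 reject_model2 = mean(rej[, 2]),
                 reject_difference = mean(rej[, 3]))
    })
    do.call(rbind, res)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
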