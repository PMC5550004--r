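#' Sigmoidal ramp tuning response
#'
#' Response of a ramp-tuned unit at signed position `x` along its preferred
#' face-space direction: `1 / (1 + exp((-x + o) / s))`. `o` is the
#' horizontal offset (0 places the midpoint at the norm of the space;
#' positive values shift the midpoint away from the norm) and `s` the
#' saturation (large values give a near-linear response over the stimulus
#' domain, values near zero a step).
#'
#' @param x signed position(s) along the preferred direction, face-space
#'   units.
#' @param o horizontal offset, face-space units.
#' @param s saturation, face-space units (> 0).
#' @return response(s) in (0, 1).
#' @export
ramp_response <- function(x, o, s) {
  if (s <= 0) stop("saturation s must be > 0")
  1 / (1 + exp((-x + o) / s))
}

#' Measurement-level population averaging
#'
#' Models local averaging of neuronal responses in imaging voxels by
#' translating each unit's response toward the population mean:
#' `y_final = (y_raw - y_mean) * (1 - p) + y_mean`, where `y_mean` is the
#' per-stimulus mean over units. `p = 0` leaves responses untouched;
#' `p = 1` makes every unit return the population mean. The per-stimulus
#' mean is preserved exactly for any `p`; the across-unit spread is scaled
#' by `(1 - p)`.
#'
#' @param responses unit-by-stimulus numeric matrix.
#' @param p averaging strength in `[0, 1]`.
#' @return matrix of the same shape.
#' @export
population_average <- function(responses, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  responses <- as.matrix(responses)
  mu <- colMeans(responses)
  sweep(responses, 2, mu, "-") * (1 - p) +
    matrix(mu, nrow(responses), ncol(responses), byrow = TRUE)
}

#' Sample a ramp-unit population
#'
#' `n_units` preferred directions drawn uniformly on the unit circle of the
#' 2D face-space slice.
#'
#' @param n_units number of model units (>= 1).
#' @param seed optional integer seed.
#' @return `n_units` x 2 matrix of unit-length direction vectors.
#' @export
sample_ramp_population <- function(n_units, seed = NULL) {
  if (n_units < 1) stop("n_units must be >= 1")
  draw <- function() {
    theta <- stats::runif(n_units, 0, 2 * pi)
    cbind(cos(theta), sin(theta))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Radial quantile anchor: the point of the tuning-center distance
# distribution that a standard-normal Z = 2.32 maps to. Under the "radial"
# reading the distance of an isotropic 2D Gaussian is Rayleigh(sigma), whose
# pnorm(2.32) quantile is sigma * sqrt(-2 * log(1 - pnorm(2.32))); under the
# "marginal" reading the anchor sits at 2.32 per-axis standard deviations.
exemplar_anchor_factor <- function(reading = c("radial", "marginal")) {
  reading <- match.arg(reading)
  if (reading == "radial") sqrt(-2 * log(1 - stats::pnorm(2.32))) else 2.32
}

#' Sample exemplar tuning centers
#'
#' Centers are drawn from an isotropic 2D Gaussian centered on the norm,
#' scaled so that the Z = 2.32 point of the radial-distance distribution
#' lies at `d * caricature_ecc` (`d = 0.1` places that tail at 10% of the
#' caricature eccentricity, `d = 3` at 300%). The inverted variant maps
#' each radial distance `t` to `T - t`, where `T` is the Z = 2.32 point,
#' and truncates negative results to zero (about 1% of exemplars).
#'
#' @param n_units number of centers.
#' @param d width of the center distribution, relative to the caricature
#'   eccentricity (> 0).
#' @param caricature_ecc eccentricity of the caricature faces (> 0).
#' @param inverted use the inverted-distance variant.
#' @param reading whether Z = 2.32 anchors the radial distance distribution
#'   (`"radial"`, default) or the 1D marginal (`"marginal"`).
#' @param seed optional integer seed.
#' @return `n_units` x 2 matrix of centers; attribute `truncated_frac`
#'   records the truncated fraction for the inverted variant.
#' @export
sample_exemplar_centers <- function(n_units, d, caricature_ecc,
                                    inverted = FALSE,
                                    reading = c("radial", "marginal"),
                                    seed = NULL) {
  reading <- match.arg(reading)
  if (d <= 0) stop("d must be > 0")
  if (caricature_ecc <= 0) stop("caricature_ecc must be > 0")
  anchor <- d * caricature_ecc
  sigma <- anchor / exemplar_anchor_factor(reading)
  draw <- function() {
    pts <- matrix(stats::rnorm(2 * n_units, sd = sigma), ncol = 2)
    if (!inverted) {
      attr(pts, "truncated_frac") <- 0
      return(pts)
    }
    t0 <- sqrt(rowSums(pts^2))
    t1 <- anchor - t0
    trunc <- t1 < 0
    t1[trunc] <- 0
    scale <- ifelse(t0 > 0, t1 / t0, 0)
    pts <- pts * scale
    attr(pts, "truncated_frac") <- mean(trunc)
    pts
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Gaussian exemplar tuning response
#'
#' Isotropic Gaussian fall-off around the unit's preferred coordinate,
#' parameterized by full width at half maximum: response is 1 at the center
#' and 0.5 at radius `w / 2`.
#'
#' @param x stimulus coordinate(s): length-2 vector or n x 2 matrix.
#' @param center length-2 preferred coordinate.
#' @param w full width at half maximum (> 0), face-space units.
#' @return response(s) in (0, 1].
#' @export
exemplar_response <- function(x, center, w) {
  if (w <= 0) stop("tuning width w must be > 0")
  x <- matrix(x, ncol = 2)
  d2 <- (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2
  exp(-d2 * 4 * log(2) / w^2)
}

#' Sigmoidal-ramp encoding model
#'
#' A population of `n_units` ramp-tuned units with random preferred
#' directions in the face-space slice, followed by measurement-level
#' population averaging of strength `p`.
#'
#' @param o horizontal offset, face-space units.
#' @param s saturation, face-space units (> 0).
#' @param p population-averaging strength in `[0, 1]`.
#' @param n_units number of model units (default 1000).
#' @return object of class `c("ramp_model", "encoding_model")`.
#' @export
ramp_model <- function(o = 0, s = 1, p = 0, n_units = 1000) {
  if (s <= 0) stop("s must be > 0")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  structure(list(o = o, s = s, p = p, n_units = n_units),
            class = c("ramp_model", "encoding_model"))
}

#' Exemplar encoding model (Gaussian or inverted-Gaussian)
#'
#' A population of `n_units` exemplar-tuned units whose preferred
#' coordinates are drawn from an isotropic Gaussian around the norm (see
#' [sample_exemplar_centers()]), with Gaussian response fall-off of full
#' width at half maximum `w`, followed by population averaging.
#'
#' @param w tuning full width at half maximum, face-space units (> 0).
#' @param d center-distribution width relative to caricature eccentricity.
#' @param p population-averaging strength in `[0, 1]`.
#' @param inverted use the inverted-distance center distribution.
#' @param n_units number of model units (default 1000).
#' @return object of class `c("exemplar_model", "encoding_model")`.
#' @export
exemplar_model <- function(w = 1, d = 1, p = 0, inverted = FALSE,
                           n_units = 1000) {
  if (w <= 0) stop("w must be > 0")
  if (d <= 0) stop("d must be > 0")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  structure(list(w = w, d = d, p = p, inverted = inverted,
                 n_units = n_units),
            class = c("exemplar_model", "encoding_model"))
}

#' Raw unit responses of a coordinate-input encoding model
#'
#' Unit-by-condition matrix of responses to the 24 grid conditions (both
#' viewpoints of an identity receive the identity's coordinate, so
#' coordinate-input models are view-tolerant by construction). Population
#' averaging is not applied here; see [model_responses()].
#'
#' @param model an `encoding_model`.
#' @param grid a `face_grid`.
#' @param seed optional integer seed for the unit population.
#' @return `n_units` x 24 matrix, condition labels as colnames.
#' @export
model_raw_responses <- function(model, grid, seed = NULL) {
  UseMethod("model_raw_responses")
}

#' @export
model_raw_responses.ramp_model <- function(model, grid, seed = NULL) {
  dirs <- sample_ramp_population(model$n_units, seed = seed)
  coords <- condition_coords(grid)
  x <- dirs %*% t(coords)                # signed position per unit/condition
  resp <- ramp_response(x, model$o, model$s)
  colnames(resp) <- rownames(coords)
  resp
}

#' @export
model_raw_responses.exemplar_model <- function(model, grid, seed = NULL) {
  centers <- sample_exemplar_centers(model$n_units, d = model$d,
                                     caricature_ecc = 1.7 * grid$r,
                                     inverted = model$inverted, seed = seed)
  coords <- condition_coords(grid)
  d2 <- outer(rowSums(centers^2), rep(1, nrow(coords))) +
    outer(rep(1, nrow(centers)), rowSums(coords^2)) -
    2 * centers %*% t(coords)
  d2[d2 < 0] <- 0
  resp <- exp(-d2 * 4 * log(2) / model$w^2)
  colnames(resp) <- rownames(coords)
  resp
}

#' Measured unit responses (after population averaging)
#'
#' @inheritParams model_raw_responses
#' @return `n_units` x 24 matrix after averaging with the model's `p`.
#' @export
model_responses <- function(model, grid, seed = NULL) {
  population_average(model_raw_responses(model, grid, seed = seed), model$p)
}

#' Predicted RDM of an encoding model
#'
#' Euclidean distances between the post-averaging population response
#' vectors for every condition pair.
#'
#' @inheritParams model_raw_responses
#' @return a 24-condition `rdm`.
#' @export
model_rdm <- function(model, grid, seed = NULL) {
  resp <- model_responses(model, grid, seed = seed)
  euclidean_rdm(t(resp))
}

#' Predicted population-mean activation profile
#'
#' Per-condition mean response over all model units. Population averaging
#' preserves the mean, so the profile is identical for any `p`.
#'
#' @inheritParams model_raw_responses
#' @return named numeric vector, one value per condition.
#' @export
model_activation_profile <- function(model, grid, seed = NULL) {
  colMeans(model_raw_responses(model, grid, seed = seed))
}
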