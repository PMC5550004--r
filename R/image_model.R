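#' Build a 5-bank Gabor filter bank
#'
#' Banks vary in spatial scale: wavelengths default to octave spacing
#' `image_size / (3 * 2^(0:4))` pixels (32, 16, 8, 4, 2 at 96 px), with
#' Gaussian envelope `sigma = wavelength / 2` and grid spacing of one
#' wavelength, so lower-frequency banks have coarser (fewer) spatial
#' positions. Each position carries `n_orient` orientations x 2 phases (a
#' quadrature pair). Every filter is zero-mean (DC-free) and unit-norm over
#' its support; filters whose envelope crosses the image border are clipped
#' to the image and re-normalized so both properties hold exactly.
#'
#' @param image_size side of the square input images in pixels (>= 32).
#' @param n_banks number of spatial-frequency banks (default 5).
#' @param n_orient orientations per position (default 8, at 22.5 degree
#'   steps; the set is closed under left-right mirroring).
#' @param wavelengths optional vector of `n_banks` wavelengths in pixels
#'   (all must be >= 2, the Nyquist limit).
#' @return object of class `gabor_bank`: sparse filter matrix (2 phase rows
#'   per energy feature, pixels as columns), per-feature metadata
#'   (bank, orientation, center, hemifield), and bank geometry.
#' @export
build_filter_bank <- function(image_size = 96, n_banks = 5, n_orient = 8,
                              wavelengths = NULL) {
  if (image_size < 32) stop("image_size must be >= 32")
  if (is.null(wavelengths))
    wavelengths <- image_size / (3 * 2^(seq_len(n_banks) - 1))
  if (length(wavelengths) != n_banks)
    stop("need one wavelength per bank")
  if (any(wavelengths < 2))
    stop("image too small: wavelength below the 2-pixel Nyquist limit")
  thetas <- pi * (seq_len(n_orient) - 1) / n_orient
  midline <- (image_size + 1) / 2

  rows <- list(); cols <- list(); vals <- list()
  meta <- list()
  feat <- 0L
  for (b in seq_len(n_banks)) {
    lam <- wavelengths[b]
    sigma <- lam / 2
    h <- ceiling(3 * sigma)
    n_pos <- floor(image_size / lam)
    start <- (image_size - (n_pos - 1) * lam) / 2
    centers <- round(start + (seq_len(n_pos) - 1) * lam)
    off <- expand.grid(dy = -h:h, dx = -h:h)
    env <- exp(-(off$dx^2 + off$dy^2) / (2 * sigma^2))
    for (oi in seq_len(n_orient)) {
      carrier <- 2 * pi * (off$dx * cos(thetas[oi]) +
                           off$dy * sin(thetas[oi])) / lam
      base <- list(env * cos(carrier), env * sin(carrier))
      # interior (unclipped) filters share normalized values
      norm_base <- lapply(base, function(v) {
        v <- v - mean(v); v / sqrt(sum(v^2))
      })
      for (cx in centers) for (cy in centers) {
        px <- cx + off$dx
        py <- cy + off$dy
        ok <- px >= 1 & px <= image_size & py >= 1 & py <= image_size
        pix <- (px[ok] - 1L) * image_size + py[ok]
        feat <- feat + 1L
        meta[[feat]] <- c(b, oi, cx, cy)
        for (ph in 1:2) {
          v <- if (all(ok)) norm_base[[ph]] else {
            vv <- base[[ph]][ok]
            vv <- vv - mean(vv)
            vv / sqrt(sum(vv^2))
          }
          k <- length(rows) + 1L
          rows[[k]] <- rep.int(2L * (feat - 1L) + ph, length(pix))
          cols[[k]] <- pix
          vals[[k]] <- v
        }
      }
    }
  }
  meta <- as.data.frame(do.call(rbind, meta))
  names(meta) <- c("bank", "orientation", "x", "y")
  meta$hemifield <- ifelse(meta$x <= midline, "left", "right")
  filters <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(2L * feat, image_size^2))
  structure(list(image_size = image_size, n_banks = n_banks,
                 n_orient = n_orient, wavelengths = wavelengths,
                 filters = filters, features = meta),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(
    "Gabor bank: %d px, %d banks (wavelengths %s), %d orientations, %d energy features\n",
    x$image_size, x$n_banks, paste(signif(x$wavelengths, 3), collapse = "/"),
    x$n_orient, nrow(x$features)))
  invisible(x)
}

#' Contrast energy of a quadrature filter pair
#'
#' Phase-invariant magnitude: `sqrt(a^2 + b^2)` over the two 90-degree
#' phase-shifted responses.
#'
#' @param resp_phase0,resp_phase90 responses of the two phases.
#' @return non-negative energies.
#' @export
contrast_energy <- function(resp_phase0, resp_phase90) {
  sqrt(resp_phase0^2 + resp_phase90^2)
}

#' Gabor model measurement parameters
#'
#' @param bank_weights 5 non-negative bank weights (at least one positive).
#' @param p_hemi hemifield-pool averaging strength in `[0, 1]`.
#' @param p_global global-pool averaging strength in `[0, 1]`.
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(bank_weights = rep(1, 5), p_hemi = 0,
                         p_global = 0) {
  if (any(bank_weights < 0) || all(bank_weights == 0))
    stop("bank weights must be non-negative with at least one positive")
  if (p_hemi < 0 || p_hemi > 1 || p_global < 0 || p_global > 1)
    stop("averaging strengths must be in [0, 1]")
  structure(list(bank_weights = bank_weights, p_hemi = p_hemi,
                 p_global = p_global), class = "gabor_params")
}

#' Gabor feature vectors for a set of images
#'
#' Pipeline per image: quadrature filter responses -> contrast energy per
#' (bank, orientation, position) -> bank weighting -> hemifield-specific
#' population averaging (features split by whether the filter center falls
#' left or right of the vertical midline; strength `p_hemi`) -> global
#' population averaging toward the all-feature mean (strength `p_global`).
#' Both pooling stages use the same mean-preserving translation as
#' [population_average()].
#'
#' @param images a single matrix or list of square grayscale matrices
#'   matching the bank's `image_size`.
#' @param bank a `gabor_bank`.
#' @param params a `gabor_params`.
#' @return feature-by-image matrix (energy features as rows).
#' @export
gabor_feature_vector <- function(images, bank, params = gabor_params()) {
  if (is.matrix(images)) images <- list(images)
  sz <- bank$image_size
  ok <- vapply(images, function(im)
    is.matrix(im) && all(dim(im) == sz), logical(1))
  if (!all(ok)) stop("image resolution does not match the filter bank")
  pix <- vapply(images, as.vector, numeric(sz^2))
  resp <- as.matrix(bank$filters %*% pix)
  odd <- seq(1, nrow(resp), by = 2)
  energy <- contrast_energy(resp[odd, , drop = FALSE],
                            resp[odd + 1, , drop = FALSE])
  energy <- energy * params$bank_weights[bank$features$bank]
  for (side in c("left", "right")) {
    idx <- bank$features$hemifield == side
    energy[idx, ] <- population_average(energy[idx, , drop = FALSE],
                                        params$p_hemi)
  }
  population_average(energy, params$p_global)
}

#' Predicted RDM of the Gabor filter model
#'
#' Euclidean distances between weighted, pooled feature vectors.
#'
#' @param images list of 24 (or any >= 2) grayscale matrices; names become
#'   condition labels.
#' @param bank a `gabor_bank`.
#' @param params a `gabor_params`.
#' @return an `rdm`.
#' @export
gabor_rdm <- function(images, bank, params = gabor_params()) {
  feat <- gabor_feature_vector(images, bank, params)
  colnames(feat) <- names(images)
  euclidean_rdm(t(feat))
}

#' Predicted population-mean activation profile of the Gabor model
#'
#' Mean weighted contrast energy over all features per image; both pooling
#' stages preserve this mean, so the profile is independent of `p_hemi` and
#' `p_global`.
#'
#' @inheritParams gabor_rdm
#' @return named numeric vector, one value per image.
#' @export
gabor_activation_profile <- function(images, bank,
                                     params = gabor_params()) {
  feat <- gabor_feature_vector(images, bank, params)
  stats::setNames(colMeans(feat), names(images))
}

#' Gabor ground-truth specification for run simulation
#'
#' Marks a [gabor_params()] configuration as the generating model of a
#' simulated region (e.g. an early-visual-cortex-like region, where the
#' winning account is image-based): simulated voxels then pool the
#' weighted, pooled Gabor contrast energies of the participant's own
#' stimulus images.
#'
#' @inheritParams gabor_params
#' @return object of class `c("gabor_model_spec", "gabor_params")`.
#' @export
gabor_model_spec <- function(bank_weights = rep(1, 5), p_hemi = 0.5,
                             p_global = 0.9) {
  out <- gabor_params(bank_weights, p_hemi, p_global)
  class(out) <- c("gabor_model_spec", class(out))
  out
}

# filter banks are expensive to build; cache per image size
bank_cache <- new.env(parent = emptyenv())
cached_filter_bank <- function(image_size) {
  key <- as.character(image_size)
  if (is.null(bank_cache[[key]]))
    bank_cache[[key]] <- build_filter_bank(image_size)
  bank_cache[[key]]
}

#' RDM predictor for the Gabor model family
#'
#' Returns a function `f(params, participant)` for [grid_search_fit()]:
#' one parameter-grid row (`w1 ... w5`, `p_hemi`, `p_global`) is turned
#' into [gabor_params()] and the RDM is predicted from the participant's
#' own stimulus images, so evaluation stimuli are never seen in fitting.
#'
#' @param bank a `gabor_bank` matching the participants' image resolution
#'   (default: a cached bank built for 96 px).
#' @return function suitable as `predict_rdm` in [grid_search_fit()].
#' @export
gabor_model_predictor <- function(bank = NULL) {
  function(params, participant) {
    if (is.null(bank)) bank <- cached_filter_bank(participant$resolution)
    gp <- gabor_params(
      bank_weights = unlist(params[paste0("w", 1:5)]),
      p_hemi = params$p_hemi, p_global = params$p_global)
    gabor_rdm(participant$images, bank, gp)
  }
}

#' Pixelwise-correlation control predictor
#'
#' Fixed (0-parameter) image-based predictor: one minus the Pearson
#' correlation between pixel-intensity vectors, entries in `[0, 2]`.
#'
#' @param images list of >= 2 equal-resolution grayscale matrices with
#'   non-constant intensities; names become condition labels.
#' @return an `rdm` with metric `"correlation"`.
#' @export
pixelwise_correlation_rdm <- function(images) {
  if (length(images) < 2) stop("need at least 2 images")
  dims <- vapply(images, function(im) paste(dim(im), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1) stop("images differ in resolution")
  pix <- vapply(images, as.vector, numeric(length(images[[1]])))
  if (any(apply(pix, 2, stats::sd) == 0))
    stop("constant image: correlation distance undefined")
  d <- 1 - stats::cor(pix)
  diag(d) <- 0
  colnames(d) <- rownames(d) <- names(images)
  rdm(d, metric = "correlation")
}
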