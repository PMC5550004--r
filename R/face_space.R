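#' Sample a random 2D slice through a D-dimensional face space
#'
#' Draws a uniformly distributed (rotation-invariant) orthonormal 2-frame:
#' two independent standard-normal D-vectors are orthonormalized by
#' Gram-Schmidt. The plane is centered on the norm (origin) of the space;
#' face-space geometry on the slice is independent of its orientation, so
#' physically distinct stimulus sets share one underlying similarity
#' structure.
#'
#' @param D dimensionality of the reference space (>= 2).
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return object of class `slice_basis`: list with `D` and `basis`
#'   (D x 2 matrix of orthonormal columns).
#' @export
sample_slice <- function(D, seed = NULL) {
  if (!is.numeric(D) || length(D) != 1L || D < 2 || D != round(D))
    stop("D must be a single integer >= 2")
  draw <- function() {
    repeat {
      v <- matrix(stats::rnorm(2 * D), nrow = D, ncol = 2)
      b1 <- v[, 1] / sqrt(sum(v[, 1]^2))
      b2 <- v[, 2] - sum(b1 * v[, 2]) * b1
      n2 <- sqrt(sum(b2^2))
      if (is.finite(n2) && n2 > 1e-12) {
        return(cbind(b1, b2 / n2, deparse.level = 0))
      }
    }
  }
  basis <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(D = as.integer(D), basis = basis), class = "slice_basis")
}

#' Build the 12-face polar grid on a face-space slice
#'
#' Faces occupy all combinations of three eccentricity levels (30%, 100%
#' and 170% of the mean eccentricity `r`) and four directions at 60 degree
#' separation spanning a half-circle (0, 60, 120, 180 degrees). Identity
#' index runs eccentricity-major within direction. Both viewpoints of an
#' identity share the same face-space coordinate; viewpoint enters only at
#' the image/measurement level.
#'
#' @param r mean eccentricity (reference scale, > 0). Model parameters
#'   elsewhere in the package are expressed relative to `r`.
#' @param basis a `slice_basis` from [sample_slice()].
#' @return object of class `face_grid`: list with `r`, `faces`
#'   (data.frame: identity, ecc_level, ecc, angle_deg, x, y), `coords_2d`
#'   (12 x 2), `embedded` (12 x D), `viewpoints` (`c("L","R")`), and
#'   `basis`.
#' @export
build_polar_grid <- function(r, basis) {
  if (!inherits(basis, "slice_basis")) stop("basis must be a slice_basis")
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("r must be a single positive number")
  ecc_scale <- c(sub = 0.3, typical = 1.0, caricature = 1.7)
  angles <- c(0, 60, 120, 180)
  faces <- expand.grid(ecc_level = names(ecc_scale), angle_deg = angles,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  faces <- faces[order(faces$angle_deg, match(faces$ecc_level,
                                              names(ecc_scale))), ]
  faces$identity <- seq_len(nrow(faces))
  faces$ecc <- r * ecc_scale[faces$ecc_level]
  theta <- faces$angle_deg * pi / 180
  faces$x <- faces$ecc * cos(theta)
  faces$y <- faces$ecc * sin(theta)
  rownames(faces) <- NULL
  faces <- faces[, c("identity", "ecc_level", "angle_deg", "ecc", "x", "y")]
  coords_2d <- as.matrix(faces[, c("x", "y")])
  rownames(coords_2d) <- sprintf("f%02d", faces$identity)
  embedded <- coords_2d %*% t(basis$basis)
  rownames(embedded) <- rownames(coords_2d)
  structure(list(r = r, faces = faces, coords_2d = coords_2d,
                 embedded = embedded, viewpoints = c("L", "R"),
                 basis = basis),
            class = "face_grid")
}

#' Condition labels for a face grid
#'
#' 24 labels (12 identities x 2 viewpoints), identity-major then viewpoint:
#' `f01_L, f01_R, f02_L, ...`. This order is the package-wide convention
#' for 24-condition RDMs. With `viewpoints = FALSE`, the 12 identity
#' labels.
#'
#' @param grid a `face_grid`.
#' @param viewpoints include the viewpoint factor (default TRUE).
#' @return character vector of length 24 (or 12).
#' @export
condition_labels <- function(grid, viewpoints = TRUE) {
  ids <- sprintf("f%02d", grid$faces$identity)
  if (!viewpoints) return(ids)
  as.vector(t(outer(ids, grid$viewpoints, paste, sep = "_")))
}

#' Condition-level coordinate matrix
#'
#' Face-space coordinates for each of the 24 conditions (both viewpoints of
#' an identity share the identity's coordinate).
#'
#' @param grid a `face_grid`.
#' @param embedded return the D-dimensional embedding rather than the 2D
#'   slice coordinates.
#' @return 24 x 2 (or 24 x D) matrix with condition labels as rownames.
#' @export
condition_coords <- function(grid, embedded = FALSE) {
  base <- if (embedded) grid$embedded else grid$coords_2d
  out <- base[rep(seq_len(nrow(base)), each = 2), , drop = FALSE]
  rownames(out) <- condition_labels(grid)
  out
}

#' Euclidean distance RDM from a point set
#'
#' @param coords numeric matrix, one point per row (>= 2 rows).
#' @return an `rdm` with metric `"euclidean"`.
#' @export
euclidean_rdm <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 points")
  if (anyNA(coords)) stop("coordinates contain NA")
  d <- as.matrix(stats::dist(coords))
  rdm(d, labels = rownames(coords), metric = "euclidean")
}

#' Reference RDM of a face grid
#'
#' Euclidean distances between the grid coordinates; with
#' `viewpoints = TRUE` the 24-condition matrix (viewpoints of one identity
#' at distance zero).
#'
#' @param grid a `face_grid`.
#' @param viewpoints build the 24-condition version (default TRUE).
#' @param embedded compute from the D-dimensional embedding (isometric to
#'   the 2D slice; default FALSE).
#' @return an `rdm`.
#' @export
reference_rdm <- function(grid, viewpoints = TRUE, embedded = FALSE) {
  coords <- if (viewpoints) condition_coords(grid, embedded = embedded)
            else if (embedded) grid$embedded else grid$coords_2d
  euclidean_rdm(coords)
}

#' Write a face grid as delimited text
#'
#' One row per face: identity, ecc_level, angle_deg, ecc, x, y, then the D
#' embedded coordinates (`e1 ... eD`).
#'
#' @param grid a `face_grid`.
#' @param path output file.
#' @export
write_grid <- function(grid, path) {
  emb <- grid$embedded
  colnames(emb) <- sprintf("e%d", seq_len(ncol(emb)))
  df <- cbind(grid$faces, as.data.frame(emb, row.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
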