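# Domain types and coordinate conventions shared by every module.
#
# Coordinates: pixel indices are 0-based; continuous positions live in pixel
# units with x along the column axis, y along the row axis, origin at the
# top-left image corner. Pixel (row r, col c) covers the half-open square
# [c, c+1) x [r, r+1), so its center is (c + 0.5, r + 0.5).

#' Fluorophore state codes
#'
#' Integer codes for the three photophysical states of a model fluorophore:
#' emitting (light), not emitting (dark but recoverable) and bleached
#' (permanently dark, absorbing).
#'
#' @format Integer scalars.
#' @export
STATE_EMITTING <- 1L

#' @rdname STATE_EMITTING
#' @export
STATE_DARK <- 2L

#' @rdname STATE_EMITTING
#' @export
STATE_BLEACHED <- 3L

#' Construct a frame stack
#'
#' Bundles a time-ordered sequence of diffraction-limited fluorescence frames
#' with its pixel geometry. Frames are stored as a 3D array indexed
#' `[row, col, frame]`.
#'
#' @param frames 3D numeric array `[H, W, K]`, or a list of `K` identical-size
#'   matrices. Values must be finite and non-negative (apply any camera
#'   baseline subtraction before construction).
#' @param pixel_size_nm Physical size of one camera pixel, nanometres.
#' @return An object of class `frame_stack` with elements `frames`,
#'   `pixel_size_nm`.
#' @export
frame_stack <- function(frames, pixel_size_nm = 100) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must have identical shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3D array [row, col, frame]")
  if (dim(frames)[3] < 1L) stop("a frame stack needs at least one frame")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  if (min(frames) < 0) stop("frame intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a positive scalar")
  storage.mode(frames) <- "double"
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm),
            class = "frame_stack")
}

#' @rdname frame_stack
#' @param x A `frame_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  dim(x$frames)[3]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px (1 px = %g nm)\n",
              d[3], d[1], d[2], x$pixel_size_nm))
  invisible(x)
}

#' Photophysics transition probabilities
#'
#' Per-frame transition probabilities of the three-state fluorophore chain:
#' `alpha` is P(emitting -> emitting), `beta` is P(not emitting -> emitting)
#' and `p_bleach` is P(not emitting -> bleached). The remaining mass stays in
#' the current state; bleached is absorbing.
#'
#' The chain is not parameterised anywhere as printed constants in the field's
#' descriptions of 3B-style engines, so the defaults here are package choices
#' (documented in the methods vignette) and every entry point accepts
#' alternatives.
#'
#' @param alpha Probability of remaining emitting, in `[0, 1]`.
#' @param beta Probability of switching from not emitting to emitting.
#' @param p_bleach Probability of bleaching from the not-emitting state;
#'   `beta + p_bleach` must not exceed 1.
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(alpha = 0.84, beta = 0.1, p_bleach = 0.01) {
  for (p in c(alpha, beta, p_bleach))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("transition probabilities must be scalars in [0, 1]")
  if (beta + p_bleach > 1)
    stop("beta + p_bleach must be <= 1 (not-emitting row mass)")
  structure(list(alpha = alpha, beta = beta, p_bleach = p_bleach),
            class = "photophysics_params")
}

#' Three-state transition matrix
#'
#' Row-stochastic transition matrix over (emitting, not emitting, bleached)
#' implied by a [photophysics_params()] object. Bleached is absorbing and is
#' reachable only from the not-emitting state.
#'
#' @param params A `photophysics_params` object.
#' @return 3 x 3 numeric matrix, rows = source state, cols = target state.
#' @export
transition_matrix <- function(params) {
  stopifnot(inherits(params, "photophysics_params"))
  m <- rbind(
    c(params$alpha, 1 - params$alpha, 0),
    c(params$beta, 1 - params$beta - params$p_bleach, params$p_bleach),
    c(0, 0, 1))
  dimnames(m) <- list(c("emitting", "dark", "bleached"),
                      c("emitting", "dark", "bleached"))
  m
}

#' Gaussian point spread function model
#'
#' An isotropic 2D Gaussian PSF described by its width sigma in nanometres;
#' the full width at half maximum is the derived quantity
#' `fwhm = 2 sqrt(2 ln 2) sigma`.
#'
#' @param sigma_nm Gaussian width (standard deviation) in nanometres.
#' @return An object of class `psf_model` with `sigma_nm` and `fwhm_nm`.
#' @export
psf_model <- function(sigma_nm = 100) {
  if (!is.numeric(sigma_nm) || length(sigma_nm) != 1L || !is.finite(sigma_nm) ||
      sigma_nm <= 0)
    stop("'sigma_nm' must be a positive scalar")
  structure(list(sigma_nm = sigma_nm, fwhm_nm = sigma_to_fwhm(sigma_nm)),
            class = "psf_model")
}

#' Convert between FWHM and Gaussian sigma
#'
#' For a Gaussian profile, `fwhm = 2 sqrt(2 ln 2) sigma ~= 2.3548 sigma`.
#'
#' @param fwhm_nm,sigma_nm Positive widths (any length unit; nm by
#'   convention here).
#' @return The converted width.
#' @export
fwhm_to_sigma <- function(fwhm_nm) {
  if (!is.numeric(fwhm_nm) || any(!is.finite(fwhm_nm)) || any(fwhm_nm <= 0))
    stop("FWHM must be positive and finite")
  fwhm_nm / (2 * sqrt(2 * log(2)))
}

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma_nm) {
  if (!is.numeric(sigma_nm) || any(!is.finite(sigma_nm)) || any(sigma_nm <= 0))
    stop("sigma must be positive and finite")
  sigma_nm * (2 * sqrt(2 * log(2)))
}

#' Center of a pixel in continuous coordinates
#'
#' Pixel indices are 0-based; pixel (r, c) covers the half-open square
#' `[c, c+1) x [r, r+1)` so its center is `(c + 0.5, r + 0.5)`.
#'
#' @param row,col 0-based pixel indices.
#' @param image_size_px Integer vector `(H, W)` giving the image bounds.
#' @return Named numeric vector `c(x = , y = )` in pixel units.
#' @export
pixel_center <- function(row, col, image_size_px) {
  stopifnot(length(image_size_px) == 2L)
  if (row != floor(row) || col != floor(col))
    stop("pixel indices must be integers")
  if (row < 0 || col < 0 || row >= image_size_px[1] || col >= image_size_px[2])
    stop(sprintf("pixel (%d, %d) outside a %d x %d image",
                 row, col, image_size_px[1], image_size_px[2]))
  c(x = col + 0.5, y = row + 0.5)
}

#' Ground-truth structure of fluorescent molecules
#'
#' A set of continuous molecule positions (pixel units) with per-molecule
#' expected photon counts per emitting frame. Used as simulation ground truth
#' and as the reference for position statistics.
#'
#' @param x_px,y_px Continuous positions in pixel units.
#' @param brightness Expected photon count per emitting frame (> 0);
#'   recycled.
#' @param image_size_px Optional `(H, W)` bounds; when given, positions must
#'   lie inside them.
#' @return A `data.frame` of class `fid_structure` with columns
#'   `x_px`, `y_px`, `brightness`.
#' @export
structure_set <- function(x_px, y_px, brightness = 500, image_size_px = NULL) {
  if (length(x_px) != length(y_px)) stop("x_px and y_px lengths differ")
  if (length(x_px) == 0L) stop("a structure needs at least one molecule")
  brightness <- rep_len(brightness, length(x_px))
  if (any(!is.finite(brightness)) || any(brightness <= 0))
    stop("brightness must be positive and finite")
  if (!is.null(image_size_px)) {
    if (any(x_px < 0) || any(y_px < 0) ||
        any(x_px > image_size_px[2]) || any(y_px > image_size_px[1]))
      stop("molecule positions fall outside the image bounds")
  }
  out <- data.frame(x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                    brightness = brightness)
  class(out) <- c("fid_structure", "data.frame")
  out
}

# Deterministic sub-stream seed derived from a master seed and a stream
# name; keeps results of the simulate / prior / engine stages independently
# reproducible while all flowing from one master seed. Result is < 2^31.
derive_seed <- function(master_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master_seed) * 48271 + h * 7919) %% 2147483647)
}
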