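# Reconstruction-quality evaluation: global structural similarity (SSIM),
# distance-to-structure statistics of birth proposals, and retained /
# discarded position accounting.

#' SSIM stabilizing constants
#'
#' Conventional constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic
#' range `L` (images here are normalized to `[0, 1]`, so `L = 1`).
#'
#' @param dynamic_range Intensity scale `L` of the compared images.
#' @param c1,c2 Stabilizing constants; defaults derive from `L`.
#' @return An object of class `ssim_params`.
#' @export
ssim_params <- function(dynamic_range = 1,
                        c1 = (0.01 * dynamic_range)^2,
                        c2 = (0.03 * dynamic_range)^2) {
  if (c1 <= 0 || c2 <= 0) stop("SSIM constants must be positive")
  structure(list(c1 = c1, c2 = c2, dynamic_range = dynamic_range),
            class = "ssim_params")
}

#' Structural similarity of two images
#'
#' Single-window (whole-image) SSIM: with means `mu`, population variances
#' `sigma^2` and covariance `sigma_xy` over all pixels,
#' `SSIM = ((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'         ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`.
#' An optional local variant averages the same statistic over sliding
#' Gaussian-weighted windows.
#'
#' @param x,y Numeric matrices of identical shape, normalized to
#'   `[0, dynamic_range]`.
#' @param params An [ssim_params()].
#' @param window `NULL` for the global statistic (default); an odd window
#'   side length (e.g. 11) for the sliding-window mean SSIM.
#' @return Scalar in `(-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params(), window = NULL) {
  if (!identical(dim(x), dim(y))) stop("images must have identical shape")
  if (is.null(window)) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    return(((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
             ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2)))
  }
  if (window %% 2 != 1 || window < 3) stop("'window' must be odd and >= 3")
  w <- stats::dnorm(seq(-(window %/% 2), window %/% 2), sd = 1.5)
  w <- w / sum(w)
  smooth <- function(m) sep_filter(m, w)
  mx <- smooth(x); my <- smooth(y)
  vx <- smooth(x * x) - mx^2
  vy <- smooth(y * y) - my^2
  cxy <- smooth(x * y) - mx * my
  mean(((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
         ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2)))
}

# Separable correlation with kernel w, replicated edges.
sep_filter <- function(m, w) {
  hw <- (length(w) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - hw, n + hw), 1L), n)
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  out <- matrix(0, nrow(m), ncol(m))
  tmp <- matrix(0, nrow(m), ncol(mp))
  for (i in seq_along(w))
    tmp <- tmp + w[i] * mp[seq_len(nrow(m)) + i - 1L, ]
  for (i in seq_along(w))
    out <- out + w[i] * tmp[, seq_len(ncol(m)) + i - 1L]
  out
}

#' Render the reference image of a ground-truth structure
#'
#' Molecules are splatted as unit impulses on the upsampled reconstruction
#' grid, blurred with a small Gaussian and max-normalized — the fixed
#' reference against which snapshots are scored.
#'
#' @param structure A [structure_set()].
#' @param image_size_px `(H, W)` of the camera frame.
#' @param upsample Super-resolution factor of the reconstruction grid.
#' @param blur_sigma_px Blur width in camera-pixel units.
#' @param brightness_weighted Weight impulses by molecule brightness.
#' @return Matrix `(H*upsample) x (W*upsample)` normalized to `[0, 1]`.
#' @export
reference_image <- function(structure, image_size_px, upsample = 10,
                            blur_sigma_px = 0.5, brightness_weighted = FALSE) {
  stopifnot(inherits(structure, "fid_structure"))
  img <- matrix(0, image_size_px[1] * upsample, image_size_px[2] * upsample)
  amp <- if (brightness_weighted) structure$brightness else
    rep(1, nrow(structure))
  img <- add_gaussian_spots(img, structure$x_px * upsample,
                            structure$y_px * upsample, amp,
                            blur_sigma_px * upsample)
  img / max(img)
}

#' SSIM across a series of reconstruction snapshots
#'
#' Scores each intermediate reconstruction against a fixed reference image,
#' in iteration order.
#'
#' @param snapshots List of `list(iteration =, image =)` as stored in a
#'   `reconstruction_state`, or a `reconstruction_state` itself.
#' @param reference Reference image matrix (same shape as the snapshots),
#'   e.g. from [reference_image()].
#' @param params An [ssim_params()].
#' @return Data frame with columns `iteration`, `ssim`.
#' @export
ssim_curve <- function(snapshots, reference, params = ssim_params()) {
  if (inherits(snapshots, "reconstruction_state"))
    snapshots <- snapshots$snapshots
  if (length(snapshots) == 0L) stop("no snapshots to evaluate")
  data.frame(
    iteration = vapply(snapshots, function(s) as.numeric(s$iteration), 0),
    ssim = vapply(snapshots, function(s) ssim(s$image, reference, params), 0))
}

#' Distance from positions to the nearest true molecule
#'
#' Euclidean distance in pixel units from each query position to its nearest
#' ground-truth molecule, plus the count and fraction closer than a
#' threshold (1 pixel by default, i.e. 100 nm at the usual pixel size).
#'
#' @param positions Data frame with `x_px`, `y_px` (e.g. an
#'   `initial_positions_log`), or a 2-column matrix.
#' @param truth A [structure_set()].
#' @param threshold_px Distance threshold for the "close" fraction.
#' @return List with `distances`, `n_within`, `fraction_within`.
#' @export
distance_to_structure <- function(positions, truth, threshold_px = 1) {
  stopifnot(inherits(truth, "fid_structure"))
  if (nrow(truth) == 0L) stop("ground-truth structure is empty")
  if (is.matrix(positions))
    positions <- data.frame(x_px = positions[, 1], y_px = positions[, 2])
  if (nrow(positions) == 0L)
    return(list(distances = numeric(0), n_within = 0L,
                fraction_within = NA_real_))
  dx <- outer(positions$x_px, truth$x_px, "-")
  dy <- outer(positions$y_px, truth$y_px, "-")
  d <- sqrt(do.call(pmin, as.data.frame(dx^2 + dy^2)))
  list(distances = d, n_within = sum(d < threshold_px),
       fraction_within = mean(d < threshold_px))
}

#' Retained / discarded position accounting
#'
#' Counts birth proposals by outcome and reports the discard rate
#' (`discarded / total`, missing when there were no proposals).
#'
#' @param x A `reconstruction_state`, a ledger data frame with an `outcome`
#'   column, or a named vector/list with `retained` and `discarded` counts.
#' @return List with `retained`, `discarded`, `total`, `discard_rate`.
#' @export
ledger_summary <- function(x) {
  if (inherits(x, "reconstruction_state")) {
    retained <- nrow(x$retained_log)
    discarded <- nrow(x$discarded_log)
  } else if (is.data.frame(x)) {
    retained <- sum(x$outcome == "retained")
    discarded <- sum(x$outcome == "discarded")
  } else {
    retained <- as.numeric(x[["retained"]])
    discarded <- as.numeric(x[["discarded"]])
  }
  total <- retained + discarded
  list(retained = retained, discarded = discarded, total = total,
       discard_rate = if (total > 0) discarded / total else NA_real_)
}
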