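# Rendering the retained-position history into a super-resolved
# probability-map image.

#' Reconstruction rendering configuration
#'
#' @param upsample Integer super-resolution factor (default 10: a 100 nm
#'   camera pixel becomes a 10 nm rendering pixel).
#' @param blur_sigma_px Gaussian smoothing width in camera-pixel units,
#'   applied on the upsampled grid.
#' @param burn_in Fraction of the earliest iterations whose retained
#'   positions are excluded.
#' @param brightness_weighted Weight positions by fluorophore brightness.
#' @return An object of class `render_config`.
#' @export
render_config <- function(upsample = 10, blur_sigma_px = 0.5,
                          burn_in = 0.25, brightness_weighted = FALSE) {
  if (upsample < 1 || upsample != floor(upsample))
    stop("'upsample' must be a positive integer")
  if (burn_in < 0 || burn_in >= 1) stop("'burn_in' must be in [0, 1)")
  if (blur_sigma_px <= 0) stop("'blur_sigma_px' must be positive")
  structure(list(upsample = as.integer(upsample),
                 blur_sigma_px = blur_sigma_px, burn_in = burn_in,
                 brightness_weighted = brightness_weighted),
            class = "render_config")
}

#' Render a super-resolved reconstruction
#'
#' Accumulates the optimized positions of retained birth proposals (after
#' burn-in) on an upsampled grid, each as a pixel-integrated Gaussian of
#' width `blur_sigma_px`, then max-normalizes to `[0, 1]`. Before
#' normalization the total mass equals the number of rendered positions
#' (up to boundary truncation), so relative line intensities reflect how
#' often the engine retained positions there.
#'
#' @param state A `reconstruction_state`, or a data frame of positions with
#'   columns `x_px`, `y_px` (and optionally `iteration`, `brightness`).
#' @param image_size_px `(H, W)` of the camera frame.
#' @param cfg A [render_config()].
#' @param normalize Max-normalize the output (default); `FALSE` returns the
#'   raw position-density image.
#' @param quiet Suppress the empty-ledger warning.
#' @return Matrix `(H*upsample) x (W*upsample)`.
#' @export
render_reconstruction <- function(state, image_size_px = NULL,
                                  cfg = render_config(), normalize = TRUE,
                                  quiet = FALSE) {
  if (inherits(state, "reconstruction_state")) {
    if (is.null(image_size_px)) image_size_px <- state$image_size_px
    pos <- state$retained_log
    if (nrow(pos) > 0) {
      cut <- cfg$burn_in * state$iteration
      pos <- pos[pos$iteration > cut, , drop = FALSE]
    }
    pos <- data.frame(x_px = pos$opt_x, y_px = pos$opt_y,
                      brightness = pos$opt_b)
  } else {
    pos <- as.data.frame(state)
    if (!is.null(pos$iteration) && nrow(pos) > 0) {
      cut <- cfg$burn_in * max(pos$iteration)
      pos <- pos[pos$iteration > cut, , drop = FALSE]
    }
  }
  if (is.null(image_size_px)) stop("'image_size_px' is required")
  H <- image_size_px[1] * cfg$upsample
  W <- image_size_px[2] * cfg$upsample
  img <- matrix(0, H, W)
  if (nrow(pos) == 0L) {
    if (!quiet) warning("no retained positions after burn-in; zero image")
    return(img)
  }
  amp <- if (cfg$brightness_weighted && !is.null(pos$brightness))
    pos$brightness / mean(pos$brightness) else rep(1, nrow(pos))
  img <- add_gaussian_spots(img, pos$x_px * cfg$upsample,
                            pos$y_px * cfg$upsample, amp,
                            cfg$blur_sigma_px * cfg$upsample)
  if (normalize && max(img) > 0) img <- img / max(img)
  img
}
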