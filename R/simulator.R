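# Simulation of dense blinking/bleaching emitter data: ground-truth
# structures, three-state hidden-Markov state trajectories, pixel-integrated
# Gaussian optics and Poisson + Gaussian camera noise.

#' Camera noise parameters
#'
#' @param background Mean background level, counts/pixel/frame (Poisson).
#' @param read_sigma Standard deviation of Gaussian readout noise, counts.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(background = 5, read_sigma = 2) {
  if (background < 0 || read_sigma < 0)
    stop("noise parameters must be non-negative")
  structure(list(background = background, read_sigma = read_sigma),
            class = "noise_params")
}

#' Specification of a simulated ground-truth structure
#'
#' Three structure families: `grid` (3 horizontal + 3 vertical evenly spaced
#' lines spanning the field, uniform brightness), `gradient_grid` (same
#' geometry with brightness decaying linearly from the left edge to
#' `gradient_min_fraction` at the right edge), and `concentric_rings`
#' (rings centered in the field with radial spacing `ring_spacing_nm`).
#' Molecules are placed every `molecule_spacing_nm` along each line or ring.
#'
#' @param kind One of `"grid"`, `"gradient_grid"`, `"concentric_rings"`.
#' @param image_size_px Integer `(H, W)` field size in pixels.
#' @param molecule_spacing_nm Spacing between neighbouring molecules along a
#'   curve, nanometres.
#' @param gradient_min_fraction Brightness fraction at the right edge for
#'   `gradient_grid`, in `(0, 1]`.
#' @param ring_spacing_nm Radial spacing between neighbouring rings.
#' @param pixel_size_nm Pixel size, nanometres.
#' @param brightness Expected photon count per emitting frame per molecule.
#' @return An object of class `structure_spec`.
#' @export
structure_spec <- function(kind = c("grid", "gradient_grid",
                                    "concentric_rings"),
                           image_size_px = c(40, 40),
                           molecule_spacing_nm = 50,
                           gradient_min_fraction = 0.2,
                           ring_spacing_nm = 200,
                           pixel_size_nm = 100,
                           brightness = 500) {
  kind <- match.arg(kind)
  if (molecule_spacing_nm <= 0 || ring_spacing_nm <= 0)
    stop("spacings must be positive")
  if (gradient_min_fraction <= 0 || gradient_min_fraction > 1)
    stop("'gradient_min_fraction' must be in (0, 1]")
  structure(list(kind = kind, image_size_px = as.integer(image_size_px),
                 molecule_spacing_nm = molecule_spacing_nm,
                 gradient_min_fraction = gradient_min_fraction,
                 ring_spacing_nm = ring_spacing_nm,
                 pixel_size_nm = pixel_size_nm, brightness = brightness),
            class = "structure_spec")
}

#' Build a ground-truth structure from a specification
#'
#' @param spec A [structure_spec()].
#' @return A [structure_set()] of molecule positions (pixel units) and
#'   brightness.
#' @export
build_structure <- function(spec) {
  stopifnot(inherits(spec, "structure_spec"))
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  sp <- spec$molecule_spacing_nm / spec$pixel_size_nm  # molecule spacing, px
  if (spec$kind %in% c("grid", "gradient_grid")) {
    if (sp > W || sp > H)
      stop("molecule spacing exceeds the field; structure would be empty")
    rows_y <- H * (1:3) / 4   # 3 horizontal lines, evenly spaced
    cols_x <- W * (1:3) / 4   # 3 vertical lines
    along_x <- seq(sp / 2, W - sp / 2, by = sp)
    along_y <- seq(sp / 2, H - sp / 2, by = sp)
    x <- c(rep(along_x, times = 3), rep(cols_x, each = length(along_y)))
    y <- c(rep(rows_y, each = length(along_x)), rep(along_y, times = 3))
    b <- rep(spec$brightness, length(x))
    if (spec$kind == "gradient_grid") {
      f <- spec$gradient_min_fraction
      scale <- 1 + (f - 1) * (x - min(x)) / (max(x) - min(x))
      b <- b * scale
    }
    return(structure_set(x, y, b, image_size_px = spec$image_size_px))
  }
  # concentric rings
  rsp <- spec$ring_spacing_nm / spec$pixel_size_nm
  r_max <- min(H, W) / 2 - 1
  if (rsp > r_max)
    stop("ring spacing exceeds the field; structure would be empty")
  radii <- seq(rsp, r_max, by = rsp)
  cx <- W / 2; cy <- H / 2
  pts <- lapply(radii, function(r) {
    n <- max(8L, ceiling(2 * pi * r / sp))
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(cx + r * cos(th), cy + r * sin(th))
  })
  pts <- do.call(rbind, pts)
  structure_set(pts[, 1], pts[, 2], spec$brightness,
                image_size_px = spec$image_size_px)
}

#' Simulate state trajectories of blinking/bleaching fluorophores
#'
#' Each fluorophore follows an independent three-state Markov chain
#' (emitting / not emitting / bleached) with transitions given by
#' [transition_matrix()]. In frame 1, exactly `ceiling(n / 2)` randomly
#' chosen fluorophores are emitting and the rest are not emitting; nobody
#' starts bleached. Bleached is absorbing.
#'
#' @param n Number of fluorophores.
#' @param K Number of frames (>= 1).
#' @param params A [photophysics_params()].
#' @param seed Optional integer seed.
#' @return Integer matrix `[n, K]` of state codes ([STATE_EMITTING] etc.).
#' @export
simulate_states <- function(n, K, params = photophysics_params(),
                            seed = NULL) {
  stopifnot(inherits(params, "photophysics_params"), n >= 1, K >= 1)
  if (!is.null(seed)) set.seed(seed)
  states <- matrix(STATE_DARK, nrow = n, ncol = K)
  states[sample.int(n, ceiling(n / 2)), 1] <- STATE_EMITTING
  a <- params$alpha; b <- params$beta; pb <- params$p_bleach
  for (k in seq_len(K - 1L) + 1L) {
    prev <- states[, k - 1L]
    u <- stats::runif(n)
    s <- prev
    e <- prev == STATE_EMITTING
    s[e] <- ifelse(u[e] < a, STATE_EMITTING, STATE_DARK)
    d <- prev == STATE_DARK
    s[d] <- ifelse(u[d] < b, STATE_EMITTING,
                   ifelse(u[d] < b + pb, STATE_BLEACHED, STATE_DARK))
    states[, k] <- s  # bleached rows keep STATE_BLEACHED (absorbing)
  }
  states
}

# Pixel-integrated Gaussian splats: adds, for each spot, amplitude times the
# 2D Gaussian of width sigma_px integrated over each pixel square (exact
# difference-of-normal-CDF integral, so total added mass equals the summed
# amplitudes up to boundary truncation). Shared by the frame renderer and the
# reconstruction renderer.
add_gaussian_spots <- function(img, x, y, amplitude, sigma_px,
                               window_sigmas = 6) {
  H <- nrow(img); W <- ncol(img)
  hw <- max(1, ceiling(window_sigmas * sigma_px))
  for (i in seq_along(x)) {
    c0 <- max(0L, floor(x[i] - hw)); c1 <- min(W - 1L, ceiling(x[i] + hw) - 1L)
    r0 <- max(0L, floor(y[i] - hw)); r1 <- min(H - 1L, ceiling(y[i] + hw) - 1L)
    if (c0 > c1 || r0 > r1) next
    gx <- diff(stats::pnorm((c0:(c1 + 1L) - x[i]) / sigma_px))
    gy <- diff(stats::pnorm((r0:(r1 + 1L) - y[i]) / sigma_px))
    img[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <-
      img[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] +
      amplitude[i] * (gy %o% gx)
  }
  img
}

#' Render one noiseless frame of a structure
#'
#' Each emitting molecule contributes its brightness times an isotropic 2D
#' Gaussian PSF integrated exactly over each pixel square; molecules that are
#' not emitting (or bleached) contribute nothing.
#'
#' @param structure A [structure_set()].
#' @param emitting Logical vector, one entry per molecule; `TRUE` entries are
#'   rendered. Default all.
#' @param sigma_px PSF width in pixel units.
#' @param image_size_px `(H, W)` field size.
#' @return Numeric `H x W` matrix of expected counts.
#' @export
render_frame <- function(structure, sigma_px, image_size_px,
                         emitting = NULL) {
  stopifnot(inherits(structure, "fid_structure"), sigma_px > 0)
  if (is.null(emitting)) emitting <- rep(TRUE, nrow(structure))
  img <- matrix(0, image_size_px[1], image_size_px[2])
  if (!any(emitting)) return(img)
  add_gaussian_spots(img, structure$x_px[emitting], structure$y_px[emitting],
                     structure$brightness[emitting], sigma_px)
}

#' Degrade an image with shot and readout noise
#'
#' Applies, independently per pixel, Poisson shot noise around
#' `image + background` followed by additive Gaussian readout noise of
#' standard deviation `read_sigma`.
#'
#' @param image Non-negative numeric matrix of expected counts.
#' @param noise A [noise_params()].
#' @param seed Optional integer seed.
#' @return Numeric matrix (may contain negative values from readout noise;
#'   the dataset simulator clips at zero when emulating camera counts).
#' @export
add_noise <- function(image, noise = noise_params(), seed = NULL) {
  stopifnot(inherits(noise, "noise_params"))
  if (min(image) < 0) stop("expected image must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- stats::rpois(length(image), lambda = image + noise$background) +
    stats::rnorm(length(image), 0, noise$read_sigma)
  matrix(out, nrow(image), ncol(image))
}

#' Simulate a full blinking/bleaching dataset
#'
#' Composes [build_structure()], [simulate_states()], [render_frame()] and
#' [add_noise()]: one fluorophore per ground-truth molecule, emitting
#' according to its simulated trajectory. Camera counts are rounded to
#' integers and clipped at zero. Fully reproducible from `seed`.
#'
#' @param spec A [structure_spec()].
#' @param params A [photophysics_params()].
#' @param noise A [noise_params()].
#' @param psf A [psf_model()].
#' @param n_frames Number of frames K.
#' @param seed Optional integer seed.
#' @param dir Optional output directory; when given, writes `stack.tif`,
#'   `truth.csv`, `states.csv` and `config.json` there.
#' @return List with `stack` ([frame_stack()]), `structure`
#'   ([structure_set()]), `states` (trajectory matrix) and `config`.
#' @export
simulate_dataset <- function(spec = structure_spec(),
                             params = photophysics_params(),
                             noise = noise_params(),
                             psf = psf_model(),
                             n_frames = 200,
                             seed = NULL,
                             dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure <- build_structure(spec)
  n <- nrow(structure)
  states <- simulate_states(n, n_frames, params)
  sigma_px <- psf$sigma_nm / spec$pixel_size_nm
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  frames <- array(0, dim = c(H, W, n_frames))
  for (k in seq_len(n_frames)) {
    img <- render_frame(structure, sigma_px, c(H, W),
                        emitting = states[, k] == STATE_EMITTING)
    frames[, , k] <- pmax(0, round(add_noise(img, noise)))
  }
  stack <- frame_stack(frames, pixel_size_nm = spec$pixel_size_nm)
  config <- list(
    structure = unclass(spec), photophysics = unclass(params),
    noise = unclass(noise), psf = unclass(psf),
    n_frames = n_frames, n_fluorophores = n, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(stack, file.path(dir, "stack.tif"))
    write_structure_csv(structure, file.path(dir, "truth.csv"))
    write_states_csv(states, file.path(dir, "states.csv"))
    write_run_config(config, file.path(dir, "config.json"))
  }
  list(stack = stack, structure = structure, states = states, config = config)
}
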