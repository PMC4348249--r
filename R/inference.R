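# Bayesian reconstruction engine: a self-contained 3B-style model-selection
# sampler over sets of blinking/bleaching fluorophores.
#
# Each model fluorophore has a continuous position, a brightness and a hidden
# three-state trajectory that is never sampled explicitly: its marginal
# likelihood over all state paths is computed with the HMM forward algorithm
# (compiled recursion in src/), with per-frame Gaussian emission densities of
# the residual image restricted to a window around the fluorophore. The
# coupling between fluorophores of the underlying factorial HMM is
# approximated by residual conditioning: every other fluorophore contributes
# brightness x PSF x its posterior emitting probability (forward-backward)
# to the explained image, and candidates are scored against what is left.
#
# One engine iteration = one model-selection decision: a birth at a uniform
# position (Op_a), a birth drawn from the intensity prior (Op_b) or a removal
# of a uniformly chosen fluorophore (Op_c). Births are locally optimized and
# retained only if the penalized log-evidence gain clears the acceptance
# threshold. Every `sweep_interval` decisions the whole model is re-optimized
# fluorophore by fluorophore.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Engine configuration
#'
#' @param mode `"fid3b"` (births from the intensity prior with probability
#'   `op_probs[2]`) or `"3b"` (uniform births only; the prior-birth
#'   probability is folded into the uniform-birth probability so both modes
#'   propose births at the same rate).
#' @param op_probs Probabilities of the three model-selection operations
#'   (uniform birth, prior birth, removal); must sum to 1.
#' @param n_iterations Number of model-selection decisions.
#' @param snapshot_interval Decisions between recorded intermediate
#'   reconstructions.
#' @param accept_threshold Penalized log-evidence gain required to retain a
#'   birth (a gain exactly at threshold retains).
#' @param noise_sigma Gaussian likelihood noise scale in counts; `NULL`
#'   estimates it from low-intensity pixels of the stack.
#' @param initial_spot_count Size of the initial model.
#' @param penalty Per-fluorophore complexity penalty on the log-evidence;
#'   `NULL` uses a BIC-style `(3/2) log(K * window pixels)` per candidate
#'   (three free parameters: x, y, brightness).
#' @param sweep_interval Decisions between full-model re-optimization sweeps.
#' @param optim_maxit Nelder-Mead iteration cap per local optimization.
#' @param window_halfwidth_sigma Half-width of the likelihood window around a
#'   fluorophore, in PSF sigmas (plus one pixel of slack).
#' @param render render_config used for snapshots and the final
#'   reconstruction.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(mode = c("fid3b", "3b"),
                          op_probs = c(0.2, 0.5, 0.3),
                          n_iterations = 320,
                          snapshot_interval = 40,
                          accept_threshold = 0,
                          noise_sigma = NULL,
                          initial_spot_count = 20,
                          penalty = NULL,
                          sweep_interval = 10,
                          optim_maxit = 60,
                          window_halfwidth_sigma = 4,
                          render = render_config()) {
  mode <- match.arg(mode)
  if (length(op_probs) != 3L || any(op_probs < 0) ||
      abs(sum(op_probs) - 1) > 1e-8)
    stop("'op_probs' must be three non-negative probabilities summing to 1")
  if (mode == "3b") {
    # uniform-position births only, at the combined birth rate
    op_probs <- c(op_probs[1] + op_probs[2], 0, op_probs[3])
  }
  structure(list(mode = mode, op_probs = op_probs,
                 n_iterations = as.integer(n_iterations),
                 snapshot_interval = as.integer(snapshot_interval),
                 accept_threshold = accept_threshold,
                 noise_sigma = noise_sigma,
                 initial_spot_count = as.integer(initial_spot_count),
                 penalty = penalty,
                 sweep_interval = as.integer(sweep_interval),
                 optim_maxit = as.integer(optim_maxit),
                 window_halfwidth_sigma = window_halfwidth_sigma,
                 render = render),
            class = "engine_config")
}

#' Draw model-selection operations
#'
#' Samples operation labels (`"a"` uniform birth, `"b"` prior birth, `"c"`
#' removal) with the configured probabilities; the engine draws one per
#' decision from this same path.
#'
#' @param config An [engine_config()].
#' @param n Number of draws.
#' @return Character vector of operation labels.
#' @export
draw_operation <- function(config, n = 1) {
  sample(c("a", "b", "c"), n, replace = TRUE, prob = config$op_probs)
}

#' Estimate the likelihood noise scale from a stack
#'
#' Takes the quarter of pixels with the lowest temporal mean (background)
#' and returns the root-mean temporal variance there, floored at `1e-3`.
#'
#' @param stack A [frame_stack()].
#' @return Positive scalar, counts.
#' @export
estimate_noise_sigma <- function(stack) {
  d <- dim(stack$frames)
  if (d[3] < 2) return(1)
  m <- matrix(stack$frames, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (d[3] - 1)
  bg <- mu <= stats::quantile(mu, 0.25)
  max(sqrt(mean(v[bg])), 1e-3)
}

# ---- internal engine -------------------------------------------------------

# 1-based row/col index window around a continuous position.
window_for <- function(x, y, H, W, hw) {
  c0 <- max(0L, as.integer(floor(x - hw)))
  c1 <- min(W - 1L, as.integer(ceiling(x + hw)) - 1L)
  r0 <- max(0L, as.integer(floor(y - hw)))
  r1 <- min(H - 1L, as.integer(ceiling(y + hw)) - 1L)
  list(rows = (r0:r1) + 1L, cols = (c0:c1) + 1L)
}

# Unit-mass pixel-integrated PSF over a window, flattened column-major to
# match `win_matrix` (rows fastest).
psf_window_gauss <- function(x, y, sigma, rows, cols) {
  gx <- diff(stats::pnorm((c(cols - 1L, cols[length(cols)]) - x) / sigma))
  gy <- diff(stats::pnorm((c(rows - 1L, rows[length(rows)]) - y) / sigma))
  as.vector(gy %o% gx)
}

# K x P matrix of an [H, W, K] array restricted to a window.
win_matrix <- function(arr, rows, cols) {
  sub <- arr[rows, cols, , drop = FALSE]
  t(matrix(sub, length(rows) * length(cols), dim(arr)[3]))
}

eng_new <- function(stack, config, params, psf, prior) {
  env <- new.env(parent = emptyenv())
  env$stack <- stack$frames
  env$H <- dim(stack$frames)[1]
  env$W <- dim(stack$frames)[2]
  env$K <- dim(stack$frames)[3]
  env$sigma_px <- psf$sigma_nm / stack$pixel_size_nm
  env$hw <- ceiling(config$window_halfwidth_sigma * env$sigma_px) + 1L
  env$noise_sigma <- config$noise_sigma %||% estimate_noise_sigma(stack)
  env$config <- config
  env$params <- params
  env$prior <- prior
  env$M <- array(0, dim = dim(stack$frames))
  env$fl <- list()
  env$iteration <- 0L
  env$initial_positions <- list()
  env$births <- list()     # retained + discarded proposals
  env$removals <- list()
  env$snapshots <- list()
  env
}

eng_penalty <- function(env, n_window_px) {
  env$config$penalty %||% (1.5 * log(env$K * n_window_px))
}

# contribution array [pr, pc, K] of one fluorophore record
fl_contrib <- function(fl, K) {
  array(as.vector(fl$g2d) %o% fl$q, dim = c(length(fl$rows), length(fl$cols), K))
}

eng_add_fluor <- function(env, fl) {
  env$M[fl$rows, fl$cols, ] <- env$M[fl$rows, fl$cols, ] +
    fl_contrib(fl, env$K)
  env$fl[[length(env$fl) + 1L]] <- fl
}

eng_remove_fluor <- function(env, j) {
  fl <- env$fl[[j]]
  env$M[fl$rows, fl$cols, ] <- env$M[fl$rows, fl$cols, ] -
    fl_contrib(fl, env$K)
  env$fl[[j]] <- NULL
}

# Residual (observed minus model) over a window, optionally putting back the
# contribution of one fluorophore (so it can be scored/re-optimized).
eng_residual <- function(env, rows, cols, exclude = NULL) {
  R <- win_matrix(env$stack, rows, cols) - win_matrix(env$M, rows, cols)
  if (!is.null(exclude)) {
    fl <- env$fl[[exclude]]
    # overlap of the excluded fluorophore's window with this window
    g2d <- matrix(0, length(rows), length(cols))
    ri <- match(fl$rows, rows); ci <- match(fl$cols, cols)
    ok_r <- !is.na(ri); ok_c <- !is.na(ci)
    if (any(ok_r) && any(ok_c)) {
      g2d[ri[ok_r], ci[ok_c]] <- fl$g2d[ok_r, ok_c]
      R <- R + fl$q %o% as.vector(g2d)
    }
  }
  R
}

# Emission log-densities and forward log-marginal for a candidate with unit
# PSF g over the window and brightness b, against residual Rmat (K x P).
candidate_logmarg <- function(Rmat, d0, g, b, env) {
  s2 <- env$noise_sigma^2
  P <- length(g)
  const <- -0.5 * P * log(2 * pi * s2)
  ld <- -d0 / (2 * s2) + const
  cross <- as.vector(Rmat %*% g)
  le <- -(d0 - 2 * b * cross + b^2 * sum(g^2)) / (2 * s2) + const
  p <- env$params
  list(logmarg = forward_logmarg_cpp(le, ld, p$alpha, p$beta, p$p_bleach),
       le = le, ld = ld, null_logdens = sum(ld))
}

# Initial brightness guess: local mean residual mass per frame near the
# position, assuming roughly half the frames are emitting.
eng_init_brightness <- function(env, x, y) {
  w <- window_for(x, y, env$H, env$W, 2)
  R <- eng_residual(env, w$rows, w$cols)
  max(2 * mean(pmax(rowSums(R), 0)), 1)
}

# Local derivative-free optimization of (x, y, log brightness) over a fixed
# window anchored at the starting position. Never returns a lower
# log-marginal than the start.
eng_optimize <- function(env, x, y, b, exclude = NULL) {
  w <- window_for(x, y, env$H, env$W, env$hw)
  Rmat <- eng_residual(env, w$rows, w$cols, exclude = exclude)
  d0 <- rowSums(Rmat^2)
  xlim <- c(w$cols[1] - 1L, w$cols[length(w$cols)])
  ylim <- c(w$rows[1] - 1L, w$rows[length(w$rows)])
  # Parameterized as displacements from the start so the search is genuinely
  # local: the initial simplex has sub-pixel size and only grows while the
  # likelihood keeps improving. Proposals sitting on a flat likelihood
  # plateau therefore stay put instead of being teleported onto structure.
  obj <- function(d) {
    px <- x + d[1]; py <- y + d[2]; lb <- log(b) + d[3]
    if (px < xlim[1] || px > xlim[2] || py < ylim[1] || py > ylim[2] ||
        lb < log(1e-3) || lb > log(1e7)) return(1e12)
    g <- psf_window_gauss(px, py, env$sigma_px, w$rows, w$cols)
    -candidate_logmarg(Rmat, d0, g, exp(lb), env)$logmarg
  }
  v0 <- obj(c(0, 0, 0))
  res <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = env$config$optim_maxit))
  if (!is.finite(res$value) || res$value > v0) {
    res$par <- c(0, 0, 0); res$value <- v0
  }
  px <- x + res$par[1]; py <- y + res$par[2]; pb <- b * exp(res$par[3])
  g <- psf_window_gauss(px, py, env$sigma_px, w$rows, w$cols)
  sc <- candidate_logmarg(Rmat, d0, g, pb, env)
  list(x = px, y = py, b = pb,
       logmarg = -res$value, null_logdens = sc$null_logdens,
       le = sc$le, ld = sc$ld, rows = w$rows, cols = w$cols,
       n_window_px = length(g))
}

# Build a full fluorophore record (with posterior emitting probabilities)
# at given values, scored against the current residual.
eng_make_record <- function(env, x, y, b, exclude = NULL) {
  w <- window_for(x, y, env$H, env$W, env$hw)
  Rmat <- eng_residual(env, w$rows, w$cols, exclude = exclude)
  d0 <- rowSums(Rmat^2)
  g <- psf_window_gauss(x, y, env$sigma_px, w$rows, w$cols)
  sc <- candidate_logmarg(Rmat, d0, g, b, env)
  p <- env$params
  fb <- forward_backward_cpp(sc$le, sc$ld, p$alpha, p$beta, p$p_bleach)
  g2d <- matrix(b * g, length(w$rows), length(w$cols))
  list(x = x, y = y, b = b, q = fb$q_emitting, rows = w$rows, cols = w$cols,
       g2d = g2d, logmarg = fb$log_marginal)
}

eng_birth <- function(env, op) {
  if (op == "b" && !is.null(env$prior)) {
    pos <- sample_birth_position(env$prior, 1)
    x <- pos$x_px; y <- pos$y_px
  } else {
    x <- stats::runif(1, 0, env$W); y <- stats::runif(1, 0, env$H)
  }
  env$initial_positions[[length(env$initial_positions) + 1L]] <-
    list(iteration = env$iteration, op = op, x_px = x, y_px = y)
  b0 <- eng_init_brightness(env, x, y)
  opt <- eng_optimize(env, x, y, b0)
  # positions clamped to the field on both axes are hopeless starts
  clamped <- (opt$x <= 0 || opt$x >= env$W) && (opt$y <= 0 || opt$y >= env$H)
  gain <- opt$logmarg - opt$null_logdens - eng_penalty(env, opt$n_window_px)
  retained <- !clamped && gain >= env$config$accept_threshold
  env$births[[length(env$births) + 1L]] <- list(
    iteration = env$iteration, op = op, x_px = x, y_px = y,
    opt_x = opt$x, opt_y = opt$y, opt_b = opt$b, gain = gain,
    outcome = if (retained) "retained" else "discarded")
  if (retained)
    eng_add_fluor(env, eng_make_record(env, opt$x, opt$y, opt$b))
  invisible(retained)
}

# Gaussian log-density of the current unexplained residual over a window:
# the deterministic (posterior-weighted) model-fit score used to compare
# model variants whose fluorophores sit at their optimized values.
eng_window_fit <- function(env, rows, cols) {
  R <- win_matrix(env$stack, rows, cols) - win_matrix(env$M, rows, cols)
  -sum(R^2) / (2 * env$noise_sigma^2) -
    0.5 * length(R) * log(2 * pi * env$noise_sigma^2)
}

# Removal decision: tentatively drop a uniformly chosen fluorophore,
# re-optimize the fluorophores whose windows overlap it (they absorb any
# signal the removed one was explaining), and keep the removal iff the
# penalized window fit does not decrease; otherwise roll the model back.
# A change of exactly zero removes (prefers the sparser model).
eng_removal <- function(env) {
  n <- length(env$fl)
  if (n == 0L) {
    env$removals[[length(env$removals) + 1L]] <- list(
      iteration = env$iteration, op = "c", x_px = NA_real_, y_px = NA_real_,
      gain = NA_real_, outcome = "noop")
    return(invisible(FALSE))
  }
  j <- sample.int(n, 1)
  fl <- env$fl[[j]]
  neighbors <- which(vapply(seq_along(env$fl), function(i) {
    i != j && length(intersect(env$fl[[i]]$rows, fl$rows)) > 0 &&
      length(intersect(env$fl[[i]]$cols, fl$cols)) > 0
  }, TRUE))
  fl_before <- env$fl
  M_before <- env$M
  fit_before <- eng_window_fit(env, fl$rows, fl$cols)
  eng_remove_fluor(env, j)
  # re-optimize overlapping neighbors in the reduced model (indices shift)
  for (i in neighbors - (neighbors > j)) {
    nb <- env$fl[[i]]
    opt <- eng_optimize(env, nb$x, nb$y, nb$b, exclude = i)
    eng_remove_fluor(env, i)
    rec <- eng_make_record(env, opt$x, opt$y, opt$b)
    env$M[rec$rows, rec$cols, ] <- env$M[rec$rows, rec$cols, ] +
      fl_contrib(rec, env$K)
    env$fl <- append(env$fl, list(rec), after = i - 1L)
  }
  fit_after <- eng_window_fit(env, fl$rows, fl$cols)
  gain <- fit_after - fit_before + eng_penalty(env, length(fl$g2d))
  removed <- gain >= 0
  if (!removed) {
    env$fl <- fl_before
    env$M <- M_before
  }
  env$removals[[length(env$removals) + 1L]] <- list(
    iteration = env$iteration, op = "c", x_px = fl$x, y_px = fl$y,
    gain = gain, outcome = if (removed) "removed" else "kept")
  invisible(removed)
}

eng_sweep <- function(env) {
  for (j in seq_along(env$fl)) {
    fl <- env$fl[[j]]
    opt <- eng_optimize(env, fl$x, fl$y, fl$b, exclude = j)
    eng_remove_fluor(env, j)
    rec <- eng_make_record(env, opt$x, opt$y, opt$b)
    # reinsert at the same slot to keep indexing stable
    env$M[rec$rows, rec$cols, ] <- env$M[rec$rows, rec$cols, ] +
      fl_contrib(rec, env$K)
    env$fl <- append(env$fl, list(rec), after = j - 1L)
  }
  invisible(NULL)
}

eng_snapshot <- function(env) {
  st <- eng_pack_state(env)
  img <- render_reconstruction(st, c(env$H, env$W), env$config$render,
                               quiet = TRUE)
  env$snapshots[[length(env$snapshots) + 1L]] <-
    list(iteration = env$iteration, image = img)
}

bind_log <- function(lst, cols) {
  if (length(lst) == 0L) {
    proto <- lapply(cols, function(cn)
      if (cn %in% c("op", "outcome")) character(0) else numeric(0))
    names(proto) <- cols
    return(as.data.frame(proto, stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(lst, function(e)
    as.data.frame(e[cols], stringsAsFactors = FALSE)))
}

eng_pack_state <- function(env) {
  fl_df <- if (length(env$fl))
    data.frame(x_px = vapply(env$fl, `[[`, 0, "x"),
               y_px = vapply(env$fl, `[[`, 0, "y"),
               brightness = vapply(env$fl, `[[`, 0, "b"))
  else data.frame(x_px = numeric(0), y_px = numeric(0),
                  brightness = numeric(0))
  births <- bind_log(env$births, c("iteration", "op", "x_px", "y_px",
                                   "opt_x", "opt_y", "opt_b", "gain",
                                   "outcome"))
  structure(list(
    fluorophores = fl_df,
    model = env$fl,
    initial_positions_log = bind_log(env$initial_positions,
                                     c("iteration", "op", "x_px", "y_px")),
    retained_log = births[births$outcome == "retained", , drop = FALSE],
    discarded_log = births[births$outcome == "discarded", , drop = FALSE],
    removal_log = bind_log(env$removals, c("iteration", "op", "x_px", "y_px",
                                           "gain", "outcome")),
    snapshots = env$snapshots,
    iteration = env$iteration,
    noise_sigma = env$noise_sigma,
    image_size_px = c(env$H, env$W),
    sigma_px = env$sigma_px,
    config = env$config), class = "reconstruction_state")
}

#' @export
print.reconstruction_state <- function(x, ...) {
  cat(sprintf(paste0("reconstruction_state: %d iterations, %d fluorophores",
                     " in model\n  births: %d retained / %d discarded;",
                     " %d removal decisions; %d snapshots\n"),
              x$iteration, nrow(x$fluorophores), nrow(x$retained_log),
              nrow(x$discarded_log), nrow(x$removal_log),
              length(x$snapshots)))
  invisible(x)
}

# ---- exported operations ---------------------------------------------------

#' Marginal likelihood of one candidate fluorophore
#'
#' Scores a candidate against the residual stack (observed minus the
#' posterior-weighted contributions of the other fluorophores) by the HMM
#' forward algorithm over its three-state chain, with per-frame Gaussian
#' emission densities over a window of about 4 PSF sigmas around the
#' candidate. The initial state distribution is (1/2, 1/2, 0) over
#' (emitting, not emitting, bleached).
#'
#' @param stack A [frame_stack()].
#' @param others Data frame (`x_px`, `y_px`, `brightness`) of the other model
#'   fluorophores; their emitting posteriors are computed sequentially
#'   against the stack in row order. May be empty.
#' @param candidate List or one-row data frame with `x_px`, `y_px`,
#'   `brightness`.
#' @param params A [photophysics_params()].
#' @param noise_sigma Gaussian likelihood noise scale (counts).
#' @param psf A [psf_model()].
#' @param config An [engine_config()] (window width, penalties).
#' @return Scalar log marginal likelihood.
#' @export
fluorophore_log_marginal <- function(stack, others, candidate, params,
                                     noise_sigma, psf = psf_model(),
                                     config = engine_config()) {
  config$noise_sigma <- noise_sigma
  env <- eng_new(stack, config, params, psf, prior = NULL)
  if (!is.null(others) && nrow(others) > 0)
    for (i in seq_len(nrow(others)))
      eng_add_fluor(env, eng_make_record(env, others$x_px[i], others$y_px[i],
                                         others$brightness[i]))
  w <- window_for(candidate$x_px, candidate$y_px, env$H, env$W, env$hw)
  Rmat <- eng_residual(env, w$rows, w$cols)
  g <- psf_window_gauss(candidate$x_px, candidate$y_px, env$sigma_px,
                        w$rows, w$cols)
  candidate_logmarg(Rmat, rowSums(Rmat^2), g, candidate$brightness,
                    env)$logmarg
}

#' Initialize a reconstruction model
#'
#' Step 1 of the procedure: places `initial_spot_count` fluorophores, drawn
#' from the intensity prior in FID3B mode (uniformly in 3B mode, or when the
#' prior is degenerate, with a warning), brightness initialized from the
#' local mean residual intensity.
#'
#' @inheritParams run_engine
#' @return A `reconstruction_state` at iteration 0.
#' @export
initialize_model <- function(stack, config = engine_config(),
                             params = photophysics_params(),
                             psf = psf_model(), prior = NULL, seed = NULL) {
  config$n_iterations <- 0L
  run_engine(stack, config, params, psf, prior, seed)
}

#' Re-optimize one model fluorophore
#'
#' Step 2 for a single fluorophore: derivative-free local maximization of
#' its marginal likelihood over (x, y, log brightness), started at the
#' current values; the result never has a lower log-marginal than the input.
#'
#' @param stack A [frame_stack()].
#' @param state A `reconstruction_state`.
#' @param index Index of the fluorophore in `state$fluorophores`.
#' @param params A [photophysics_params()].
#' @param psf A [psf_model()].
#' @param config An [engine_config()].
#' @return List with the updated `x`, `y`, `b` and the achieved `logmarg`.
#' @export
optimize_fluorophore <- function(stack, state, index,
                                 params = photophysics_params(),
                                 psf = psf_model(),
                                 config = NULL) {
  config <- config %||% state$config
  config$noise_sigma <- config$noise_sigma %||% state$noise_sigma
  env <- eng_new(stack, config, params, psf, prior = NULL)
  for (fl in state$model) eng_add_fluor(env, fl)
  if (index < 1 || index > length(env$fl)) stop("fluorophore index out of range")
  fl <- env$fl[[index]]
  eng_optimize(env, fl$x, fl$y, fl$b, exclude = index)
}

#' Run the reconstruction engine
#'
#' Alternates full-model re-optimization sweeps with model-selection
#' decisions (one decision per iteration), recording every birth proposal
#' and its outcome, and rendering an intermediate reconstruction every
#' `snapshot_interval` decisions. Fully reproducible from `seed`.
#'
#' @param stack A [frame_stack()].
#' @param config An [engine_config()].
#' @param params A [photophysics_params()].
#' @param psf A [psf_model()].
#' @param prior An [intensity_prior()] or `NULL`; in FID3B mode a `NULL`
#'   prior is computed from the stack with the configured alpha/beta (if
#'   degenerate, the engine falls back to uniform proposals with a warning).
#' @param seed Optional integer seed.
#' @return A `reconstruction_state`.
#' @export
run_engine <- function(stack, config = engine_config(),
                       params = photophysics_params(),
                       psf = psf_model(), prior = NULL, seed = NULL) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(config, "engine_config"))
  if (!is.null(seed)) set.seed(seed)
  if (config$mode == "fid3b" && is.null(prior)) {
    prior <- tryCatch(
      intensity_prior(stack, params$alpha, params$beta),
      error = function(e) {
        warning("degenerate intensity prior (", conditionMessage(e),
                "); falling back to uniform birth proposals")
        NULL
      })
  }
  if (config$mode == "3b") prior <- NULL
  env <- eng_new(stack, config, params, psf, prior)
  # Step 1: initial model
  if (config$initial_spot_count > 0) {
    if (!is.null(prior)) {
      pos <- sample_birth_position(prior, config$initial_spot_count)
    } else {
      pos <- data.frame(x_px = stats::runif(config$initial_spot_count, 0, env$W),
                        y_px = stats::runif(config$initial_spot_count, 0, env$H))
    }
    for (i in seq_len(nrow(pos)))
      eng_add_fluor(env, eng_make_record(
        env, pos$x_px[i], pos$y_px[i],
        eng_init_brightness(env, pos$x_px[i], pos$y_px[i])))
  }
  for (it in seq_len(config$n_iterations)) {
    env$iteration <- it
    op <- draw_operation(config, 1)
    if (op == "c") eng_removal(env) else eng_birth(env, op)
    if (config$sweep_interval > 0 && it %% config$sweep_interval == 0L)
      eng_sweep(env)
    if (config$snapshot_interval > 0 && it %% config$snapshot_interval == 0L)
      eng_snapshot(env)
  }
  eng_pack_state(env)
}

#' One model-selection decision
#'
#' Applies a single Step-3 decision (drawn from the configured operation
#' probabilities) to an existing state and returns the updated state.
#'
#' @inheritParams optimize_fluorophore
#' @param prior An [intensity_prior()] or `NULL` (uniform births).
#' @param seed Optional integer seed.
#' @return The updated `reconstruction_state`.
#' @export
model_selection_step <- function(stack, state,
                                 params = photophysics_params(),
                                 psf = psf_model(), prior = NULL,
                                 config = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- config %||% state$config
  config$noise_sigma <- config$noise_sigma %||% state$noise_sigma
  env <- eng_new(stack, config, params, psf, prior)
  for (fl in state$model) eng_add_fluor(env, fl)
  env$iteration <- state$iteration + 1L
  # restore logs
  env$initial_positions <- lapply(seq_len(nrow(state$initial_positions_log)),
    function(i) as.list(state$initial_positions_log[i, ]))
  births <- rbind(state$retained_log, state$discarded_log)
  env$births <- lapply(seq_len(nrow(births)), function(i) as.list(births[i, ]))
  env$removals <- lapply(seq_len(nrow(state$removal_log)),
    function(i) as.list(state$removal_log[i, ]))
  env$snapshots <- state$snapshots
  op <- draw_operation(config, 1)
  if (op == "c") eng_removal(env) else eng_birth(env, op)
  eng_pack_state(env)
}

#' Combined model-selection ledger
#'
#' Birth proposals (initial positions, outcome retained/discarded) and
#' removal decisions in iteration order, as written to `ledger.csv`.
#'
#' @param state A `reconstruction_state`.
#' @return Data frame with columns `iteration, op, x_px, y_px, outcome`.
#' @export
ledger <- function(state) {
  cols <- c("iteration", "op", "x_px", "y_px", "outcome")
  births <- rbind(state$retained_log[, cols, drop = FALSE],
                  state$discarded_log[, cols, drop = FALSE])
  out <- rbind(births, state$removal_log[, cols, drop = FALSE])
  out[order(out$iteration), , drop = FALSE]
}
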