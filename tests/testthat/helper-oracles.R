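# Independent reference implementations used as oracles. These deliberately
# use the slowest, most literal formulation of each definition (triple loops,
# exhaustive path enumeration, quadrature) and share no code with the package
# internals they check.

logsumexp <- function(v) {
  v <- v[is.finite(v) | v > -Inf]
  if (length(v) == 0L) return(-Inf)
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# Total intensity map by the literal O(K^2 * pixels) double sum.
gamma_brute_force <- function(frames, alpha, beta) {
  K <- dim(frames)[3]
  out <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (k in seq_len(K)) {
    tau <- sum(alpha ^ abs(k - seq_len(K)))
    gk <- matrix(0, dim(frames)[1], dim(frames)[2])
    for (t in seq_len(K))
      gk <- gk + (alpha ^ abs(k - t) / tau + beta / K) * frames[, , t]
    out <- out + gk
  }
  out
}

# Per-frame estimate gamma_k by the same literal sum.
gamma_k_brute_force <- function(frames, k, alpha, beta) {
  K <- dim(frames)[3]
  tau <- sum(alpha ^ abs(k - seq_len(K)))
  gk <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (t in seq_len(K))
    gk <- gk + (alpha ^ abs(k - t) / tau + beta / K) * frames[, , t]
  gk
}

# Exhaustive 3^K path enumeration of the three-state chain marginal with
# per-frame log emission densities le (emitting) / ld (dark or bleached).
# States: 1 emitting, 2 dark, 3 bleached; initial (1/2, 1/2, 0).
enum_log_marginal <- function(le, ld, params) {
  K <- length(le)
  Tm <- transition_matrix(params)
  init <- c(0.5, 0.5, 0)
  paths <- as.matrix(expand.grid(rep(list(1:3), K)))
  lp <- apply(paths, 1, function(s) {
    p <- log(init[s[1]]) + if (s[1] == 1) le[1] else ld[1]
    for (k in seq_len(K - 1) + 1) {
      p <- p + log(Tm[s[k - 1], s[k]]) + if (s[k] == 1) le[k] else ld[k]
      if (!is.finite(p)) return(-Inf)
    }
    p
  })
  logsumexp(lp)
}

# Pixel-integrated Gaussian image by midpoint quadrature (independent of the
# closed-form CDF-difference integral used by the package).
quad_gauss_image <- function(x0, y0, amp, sigma, H, W, nsub = 31) {
  img <- matrix(0, H, W)
  offs <- (seq_len(nsub) - 0.5) / nsub
  for (r in seq_len(H)) for (c in seq_len(W)) {
    xs <- (c - 1) + offs
    ys <- (r - 1) + offs
    gx <- mean(stats::dnorm(xs, x0, sigma)) # midpoint rule over the pixel
    gy <- mean(stats::dnorm(ys, y0, sigma))
    img[r, c] <- amp * gx * gy
  }
  img
}

# Full-image per-fluorophore log marginal computed from first principles:
# emission densities over every pixel (use stacks small enough that the
# package's likelihood window covers the whole field).
oracle_log_marginal <- function(frames, x, y, b, sigma, noise_sigma, params) {
  H <- dim(frames)[1]; W <- dim(frames)[2]; K <- dim(frames)[3]
  gx <- diff(stats::pnorm((0:W - x) / sigma))
  gy <- diff(stats::pnorm((0:H - y) / sigma))
  g <- gy %o% gx
  le <- ld <- numeric(K)
  for (k in seq_len(K)) {
    le[k] <- sum(stats::dnorm(frames[, , k], b * g, noise_sigma, log = TRUE))
    ld[k] <- sum(stats::dnorm(frames[, , k], 0, noise_sigma, log = TRUE))
  }
  enum_log_marginal(le, ld, params)
}

# Small blinking-emitter stack; noiseless unless noise is given.
make_emitter_stack <- function(x, y, brightness, K, sigma_px = 1.02,
                               size = c(20, 20), params = photophysics_params(),
                               noise = NULL, seed = 1) {
  set.seed(seed)
  truth <- structure_set(x, y, brightness)
  states <- simulate_states(length(x), K, params)
  frames <- array(0, c(size[1], size[2], K))
  for (k in seq_len(K)) {
    img <- render_frame(truth, sigma_px, size,
                        emitting = states[, k] == STATE_EMITTING)
    if (!is.null(noise)) img <- pmax(0, round(add_noise(img, noise)))
    frames[, , k] <- img
  }
  list(stack = frame_stack(frames), truth = truth, states = states)
}
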