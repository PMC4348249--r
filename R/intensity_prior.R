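# Fluorophore intensity distribution: a transition-probability-weighted
# temporal average of the pixel intensities, max-normalized into a
# probability map and used as the birth-proposal prior.
#
# For frame k and pixel x,
#   gamma_k(x) = sum_t ( alpha^|k-t| / tau_k + beta / K ) i_t(x),
#   tau_k = sum_t alpha^|k-t|,
# with the convention 0^0 = 1 so alpha = 0 collapses the first term to the
# current frame. The total gamma(x) = sum_k gamma_k(x) and the map
# P(x) = gamma(x) / max_x gamma(x).

# K x K weight matrix A[k, t] = alpha^|k - t| and its row sums tau.
prior_weights <- function(K, alpha) {
  A <- alpha ^ abs(outer(seq_len(K), seq_len(K), "-"))
  list(A = A, tau = rowSums(A))
}

#' Estimated fluorescence intensity of one frame
#'
#' Weighted average of the intensity trace at every pixel: frames close to
#' frame `k` get exponentially larger weight (blinking persistence,
#' weight `alpha^|k-t|`, normalized by `tau_k`), and every frame contributes
#' a flat `beta / K` term for dark-to-emitting recoveries at any time.
#'
#' @param stack A [frame_stack()].
#' @param k Frame index, 1-based, `1 <= k <= K`.
#' @param alpha,beta Transition probabilities (emitting->emitting,
#'   dark->emitting), each in `[0, 1]`.
#' @return Numeric `H x W` matrix `gamma_k`.
#' @export
frame_intensity_estimate <- function(stack, k, alpha, beta) {
  stopifnot(inherits(stack, "frame_stack"))
  K <- n_frames(stack)
  if (k < 1 || k > K || k != floor(k)) stop("frame index out of range")
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  w <- prior_weights(K, alpha)
  wk <- w$A[k, ] / w$tau[k] + beta / K
  d <- dim(stack$frames)
  matrix(matrix(stack$frames, d[1] * d[2], d[3]) %*% wk, d[1], d[2])
}

#' Total estimated intensity map
#'
#' Sum of the per-frame estimates over all `K` frames. Computed in one pass
#' by collapsing the double sum into per-frame coefficients
#' `c_t = beta + sum_k alpha^|k-t| / tau_k`; equals the brute-force double
#' sum to numerical precision.
#'
#' @inheritParams frame_intensity_estimate
#' @return Numeric `H x W` matrix `gamma`.
#' @export
total_intensity <- function(stack, alpha, beta) {
  stopifnot(inherits(stack, "frame_stack"))
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  K <- n_frames(stack)
  w <- prior_weights(K, alpha)
  ct <- colSums(w$A / w$tau) + beta  # sum_k (A[k,t]/tau_k + beta/K)
  d <- dim(stack$frames)
  matrix(matrix(stack$frames, d[1] * d[2], d[3]) %*% ct, d[1], d[2])
}

#' Max-normalized probability map
#'
#' `P(x) = gamma(x) / max_x gamma(x)`; ranges over `[0, 1]` with maximum
#' exactly 1. Note this is a confidence map, not a probability mass
#' function; the birth-position sampler renormalizes by the sum.
#'
#' @param gamma Non-negative intensity map with at least one positive entry.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
probability_map <- function(gamma) {
  if (min(gamma) < 0) stop("gamma must be non-negative")
  m <- max(gamma)
  if (m <= 0)
    stop("degenerate intensity map (all zero); fall back to uniform proposals")
  gamma / m
}

#' Compute the intensity-distribution birth prior
#'
#' Builds the full prior object from a frame stack: the total intensity map,
#' its max-normalized probability map, and the transition probabilities used.
#' An optional constant background can be subtracted from the raw counts
#' first (clipped at zero).
#'
#' @inheritParams frame_intensity_estimate
#' @param background_subtract Constant background level to subtract from
#'   every pixel before weighting (default 0: raw counts).
#' @return An object of class `intensity_prior` with elements `gamma`,
#'   `p_map`, `alpha`, `beta`, `K`.
#' @export
intensity_prior <- function(stack, alpha = 0.84, beta = 0.1,
                            background_subtract = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  s <- stack
  if (background_subtract > 0)
    s <- frame_stack(pmax(0, stack$frames - background_subtract),
                     pixel_size_nm = stack$pixel_size_nm)
  gamma <- total_intensity(s, alpha, beta)
  structure(list(gamma = gamma, p_map = probability_map(gamma),
                 alpha = alpha, beta = beta, K = n_frames(stack)),
            class = "intensity_prior")
}

#' Sample birth positions from the intensity prior
#'
#' Pixels are drawn with probability proportional to the map value
#' (`P(x) / sum_x P(x)`), then a uniform sub-pixel offset is added inside
#' the chosen pixel square, giving continuous positions.
#'
#' @param prior An [intensity_prior()], or any non-negative matrix with a
#'   positive maximum (taken as the map).
#' @param n Number of positions to draw.
#' @param seed Optional integer seed.
#' @return Data frame with columns `x_px`, `y_px`.
#' @export
sample_birth_position <- function(prior, n = 1, seed = NULL) {
  p <- if (inherits(prior, "intensity_prior")) prior$p_map else prior
  if (min(p) < 0 || max(p) <= 0)
    stop("degenerate prior: map must be non-negative with a positive maximum")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(p), n, replace = TRUE, prob = as.vector(p))
  # column-major: pixel (r, c) 1-based; positions use 0-based pixel corners
  r <- (idx - 1L) %% nrow(p)
  c <- (idx - 1L) %/% nrow(p)
  data.frame(x_px = c + stats::runif(n), y_px = r + stats::runif(n))
}
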