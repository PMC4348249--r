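test_that("grid structures put every molecule on one of 6 evenly spaced lines", {
  spec <- structure_spec("grid", image_size_px = c(40, 40),
                         molecule_spacing_nm = 50)
  s <- build_structure(spec)
  lines_y <- 40 * (1:3) / 4
  lines_x <- 40 * (1:3) / 4
  on_line <- vapply(seq_len(nrow(s)), function(i) {
    min(abs(s$y_px[i] - lines_y), abs(s$x_px[i] - lines_x)) < 1e-9
  }, TRUE)
  expect_true(all(on_line))
  # molecules cover both orientations and the field span
  expect_gt(nrow(s), 400)
  expect_lt(min(s$x_px), 1)
  expect_gt(max(s$x_px), 39)
  expect_true(all(s$brightness == 500))
  expect_error(build_structure(structure_spec("grid",
                                              molecule_spacing_nm = 5e5)),
               "empty")
})

test_that("gradient grids decay linearly with the stated edge ratio", {
  spec <- structure_spec("gradient_grid", gradient_min_fraction = 0.2)
  s <- build_structure(spec)
  left <- s$brightness[which.min(s$x_px)]
  right <- s$brightness[which.max(s$x_px)]
  expect_equal(left / right, 1 / 0.2, tolerance = 1e-12)
  # linear in x: brightness of a molecule halfway across is halfway between
  fit <- stats::lm(brightness ~ x_px, data = s)
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
})

test_that("concentric rings are spaced 200 nm (2 px at 100 nm pixels) apart", {
  spec <- structure_spec("concentric_rings", ring_spacing_nm = 200,
                         pixel_size_nm = 100)
  s <- build_structure(spec)
  r <- sqrt((s$x_px - 20)^2 + (s$y_px - 20)^2)
  radii <- sort(unique(round(r, 6)))
  expect_equal(diff(radii), rep(2, length(radii) - 1), tolerance = 1e-9)
  expect_equal(radii[1], 2, tolerance = 1e-9)
})

test_that("exactly half the fluorophores emit in frame 1 and bleaching is absorbing", {
  states <- simulate_states(1000, 50, photophysics_params(), seed = 4)
  expect_identical(sum(states[, 1] == STATE_EMITTING), 500L)
  expect_true(all(states[, 1] != STATE_BLEACHED))
  # odd n rounds up
  expect_identical(sum(simulate_states(7, 3, seed = 1)[, 1] == STATE_EMITTING),
                   4L)
  # bleached frames form a suffix of every trajectory
  suffix_ok <- apply(states, 1, function(tr) {
    w <- which(tr == STATE_BLEACHED)
    length(w) == 0L || all(tr[w[1]:length(tr)] == STATE_BLEACHED)
  })
  expect_true(all(suffix_ok))
  # fraction bleached by frame k is non-decreasing in k
  frac_bleached <- colMeans(states == STATE_BLEACHED)
  expect_true(all(diff(frac_bleached) >= 0))
})

test_that("state transitions follow the configured probabilities", {
  p <- photophysics_params(alpha = 0.84, beta = 0.1, p_bleach = 0.05)
  states <- simulate_states(2000, 2, p, seed = 9)
  em1 <- states[, 1] == STATE_EMITTING
  frac <- mean(states[em1, 2] == STATE_EMITTING)
  se <- sqrt(0.84 * 0.16 / sum(em1))
  expect_lt(abs(frac - 0.84), 3 * se)
  dark1 <- states[, 1] == STATE_DARK
  frac_b <- mean(states[dark1, 2] == STATE_BLEACHED)
  expect_lt(abs(frac_b - 0.05), 3 * sqrt(0.05 * 0.95 / sum(dark1)))
  # alpha = 1 keeps an emitting fluorophore emitting forever
  st <- simulate_states(50, 30, photophysics_params(1, 0, 0.5), seed = 2)
  expect_true(all(st[st[, 1] == STATE_EMITTING, ] == STATE_EMITTING))
})

test_that("rendered frames conserve flux and match quadrature of the Gaussian", {
  s <- structure_set(20.5, 20.5, 1000)
  img <- render_frame(s, 1, c(40, 40))
  expect_gte(sum(img), 999)
  expect_lte(sum(img), 1000)
  # dark emitter contributes nothing
  expect_equal(render_frame(s, 1, c(40, 40), emitting = FALSE),
               matrix(0, 40, 40))
  # independent midpoint-quadrature oracle on a small field
  s2 <- structure_set(4.3, 6.1, 100)
  img2 <- render_frame(s2, 1.3, c(12, 12))
  expect_equal(img2, quad_gauss_image(4.3, 6.1, 100, 1.3, 12, 12),
               tolerance = 1e-4)
})

test_that("two close emitters render as the sum of two Gaussians without a deep dip", {
  sigma <- 1.02
  s <- structure_set(c(8.5 - 1.2, 8.5 + 1.2), c(8.5, 8.5), 1000)
  img <- render_frame(s, sigma, c(17, 17))
  oracle <- quad_gauss_image(8.5 - 1.2, 8.5, 1000, sigma, 17, 17) +
    quad_gauss_image(8.5 + 1.2, 8.5, 1000, sigma, 17, 17)
  expect_equal(img, oracle, tolerance = 1e-4)
  profile <- img[9, ]  # row through both peaks
  peaks <- max(profile)
  midpoint <- profile[9]
  expect_gt(midpoint / peaks, 0.735)  # Sparrow-type overlap, unresolved dip
})

test_that("render is linear in the emitter set", {
  set.seed(3)
  a <- structure_set(runif(5, 2, 18), runif(5, 2, 18), runif(5, 100, 900))
  b <- structure_set(runif(4, 2, 18), runif(4, 2, 18), runif(4, 100, 900))
  ab <- structure_set(c(a$x_px, b$x_px), c(a$y_px, b$y_px),
                      c(a$brightness, b$brightness))
  expect_equal(render_frame(ab, 1.1, c(20, 20)),
               render_frame(a, 1.1, c(20, 20)) +
                 render_frame(b, 1.1, c(20, 20)),
               tolerance = 1e-10)
})

test_that("noise has Poisson + Gaussian moments", {
  img <- matrix(100, 100, 100)
  out <- add_noise(img, noise_params(background = 10, read_sigma = 3),
                   seed = 11)
  n <- length(out)
  expect_lt(abs(mean(out) - 110), 3 * sqrt((110 + 9) / n))
  expect_lt(abs(stats::var(as.vector(out)) - 119), 5 * 119 / sqrt(n))
  # no noise sources -> identity
  expect_equal(add_noise(matrix(0, 5, 5), noise_params(0, 0)),
               matrix(0, 5, 5))
  expect_error(add_noise(matrix(-1, 2, 2), noise_params()), "non-negative")
})

test_that("simulate_dataset composes reproducibly with the stated shape", {
  spec <- structure_spec("grid", image_size_px = c(40, 40))
  sim <- simulate_dataset(spec, n_frames = 12, seed = 21)
  expect_equal(dim(sim$stack$frames), c(40, 40, 12))
  expect_equal(nrow(sim$states), nrow(sim$structure))
  sim2 <- simulate_dataset(spec, n_frames = 12, seed = 21)
  expect_identical(sim$stack$frames, sim2$stack$frames)
  sim3 <- simulate_dataset(spec, n_frames = 12, seed = 22)
  expect_true(any(sim$stack$frames != sim3$stack$frames))
  # written outputs round trip
  dir <- withr::local_tempdir()
  sim4 <- simulate_dataset(spec, n_frames = 5, seed = 1, dir = dir)
  expect_identical(read_stack(file.path(dir, "stack.tif"))$frames,
                   sim4$stack$frames)
  expect_equal(nrow(read_structure_csv(file.path(dir, "truth.csv"))),
               nrow(sim4$structure))
})
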