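test_that("forward algorithm matches exhaustive path enumeration", {
  set.seed(31)
  for (K in 2:6) {
    for (rep in 1:3) {
      le <- rnorm(K, -5, 3)
      ld <- rnorm(K, -5, 3)
      p <- photophysics_params(runif(1), runif(1, 0, 0.6), runif(1, 0, 0.3))
      expect_equal(
        fid3b:::forward_logmarg_cpp(le, ld, p$alpha, p$beta, p$p_bleach),
        enum_log_marginal(le, ld, p),
        tolerance = 1e-10)
    }
  }
  # forward-backward marginal agrees with the plain forward pass
  le <- rnorm(5, -2, 1); ld <- rnorm(5, -2, 1)
  p <- photophysics_params(0.84, 0.1, 0.01)
  fb <- fid3b:::forward_backward_cpp(le, ld, p$alpha, p$beta, p$p_bleach)
  expect_equal(fb$log_marginal,
               fid3b:::forward_logmarg_cpp(le, ld, p$alpha, p$beta,
                                           p$p_bleach),
               tolerance = 1e-12)
  expect_true(all(fb$q_emitting >= 0 & fb$q_emitting <= 1))
})

test_that("candidate log-marginal matches a first-principles pixel-level oracle", {
  p <- photophysics_params(0.7, 0.2, 0.05)
  fix <- make_emitter_stack(3.4, 3.8, 40, K = 3, sigma_px = 1,
                            size = c(7, 7), params = p,
                            noise = noise_params(2, 1), seed = 13)
  cand <- list(x_px = 3.6, y_px = 3.5, brightness = 35)
  got <- fluorophore_log_marginal(fix$stack, NULL, cand, p,
                                  noise_sigma = 2, psf = psf_model(100))
  want <- oracle_log_marginal(fix$stack$frames, 3.6, 3.5, 35, 1, 2, p)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("a zero-brightness candidate scores as the pure-residual density", {
  p <- photophysics_params()
  fix <- make_emitter_stack(3.2, 3.2, 30, K = 4, sigma_px = 1,
                            size = c(7, 7), params = p,
                            noise = noise_params(1, 1), seed = 5)
  cand <- list(x_px = 3.5, y_px = 3.5, brightness = 0)
  got <- fluorophore_log_marginal(fix$stack, NULL, cand, p, noise_sigma = 1.5)
  null_dens <- sum(stats::dnorm(fix$stack$frames, 0, 1.5, log = TRUE))
  expect_equal(got, null_dens, tolerance = 1e-8)
})

test_that("local optimization improves the log-marginal and recovers an emitter", {
  fix <- make_emitter_stack(10.3, 9.6, 500, K = 60, sigma_px = 1.02,
                            size = c(20, 20), seed = 7)
  cfg <- engine_config(mode = "3b", initial_spot_count = 0,
                       noise_sigma = 2)
  env <- fid3b:::eng_new(fix$stack, cfg, photophysics_params(),
                         psf_model(102), NULL)
  # started 0.8 px off the true position, the optimum lands within 0.05 px
  opt <- fid3b:::eng_optimize(env, 10.3 + 0.8 / sqrt(2), 9.6 - 0.8 / sqrt(2),
                              300)
  expect_lt(sqrt((opt$x - 10.3)^2 + (opt$y - 9.6)^2), 0.05)
  # starting at the truth barely moves
  opt0 <- fid3b:::eng_optimize(env, 10.3, 9.6, 500)
  expect_lt(sqrt((opt0$x - 10.3)^2 + (opt0$y - 9.6)^2), 0.05)
  # monotonicity contract on random starts
  set.seed(42)
  for (i in 1:5) {
    x0 <- runif(1, 3, 17); y0 <- runif(1, 3, 17); b0 <- runif(1, 10, 800)
    w <- fid3b:::window_for(x0, y0, 20, 20, env$hw)
    R <- fid3b:::eng_residual(env, w$rows, w$cols)
    g <- fid3b:::psf_window_gauss(x0, y0, env$sigma_px, w$rows, w$cols)
    before <- fid3b:::candidate_logmarg(R, rowSums(R^2), g, b0, env)$logmarg
    opt <- fid3b:::eng_optimize(env, x0, y0, b0)
    expect_gte(opt$logmarg, before)
  }
})

test_that("model initialization respects the prior, count and seed", {
  fix <- make_emitter_stack(5, 5, 300, K = 10, size = c(12, 12),
                            noise = noise_params(), seed = 3)
  cfg <- engine_config(initial_spot_count = 0, n_iterations = 0,
                       noise_sigma = 3)
  st <- initialize_model(fix$stack, cfg, seed = 1)
  expect_equal(nrow(st$fluorophores), 0)
  expect_s3_class(st, "reconstruction_state")
  # delta prior concentrates every initial spot in one pixel
  delta <- matrix(0, 12, 12); delta[6, 8] <- 1
  pr <- structure(list(p_map = delta), class = "intensity_prior")
  cfg$initial_spot_count <- 6L
  st <- initialize_model(fix$stack, cfg, prior = pr, seed = 2)
  expect_true(all(floor(st$fluorophores$x_px) == 7))
  expect_true(all(floor(st$fluorophores$y_px) == 5))
  st2 <- initialize_model(fix$stack, cfg, prior = pr, seed = 2)
  expect_identical(st$fluorophores, st2$fluorophores)
})

test_that("birth decisions retain supported spots and discard background ones", {
  fix <- make_emitter_stack(6.5, 6.5, 600, K = 40, size = c(24, 24),
                            noise = noise_params(), seed = 11)
  base <- initialize_model(fix$stack,
                           engine_config(initial_spot_count = 0,
                                         noise_sigma = 3), seed = 1)
  # prior birth proposed right on a clean bright spot: retained
  on_spot <- matrix(0, 24, 24); on_spot[7, 7] <- 1
  cfg_b <- engine_config(op_probs = c(0, 1, 0), noise_sigma = 3,
                         initial_spot_count = 0)
  st <- model_selection_step(fix$stack, base,
                             prior = structure(list(p_map = on_spot),
                                               class = "intensity_prior"),
                             config = cfg_b, seed = 4)
  expect_equal(nrow(st$retained_log), 1)
  expect_equal(st$retained_log$op, "b")
  expect_lt(sqrt((st$fluorophores$x_px - 6.5)^2 +
                   (st$fluorophores$y_px - 6.5)^2), 0.2)
  # birth proposed in pure background > 5 sigma away: discarded
  off_spot <- matrix(0, 24, 24); off_spot[20, 20] <- 1
  st2 <- model_selection_step(fix$stack, base,
                              prior = structure(list(p_map = off_spot),
                                                class = "intensity_prior"),
                              config = cfg_b, seed = 5)
  expect_equal(nrow(st2$discarded_log), 1)
  expect_equal(nrow(st2$fluorophores), 0)
  # removal drawn on an empty model is a logged no-op
  cfg_c <- engine_config(op_probs = c(0, 0, 1), noise_sigma = 3,
                         initial_spot_count = 0)
  st3 <- model_selection_step(fix$stack, base, config = cfg_c, seed = 6)
  expect_equal(nrow(st3$fluorophores), 0)
  expect_equal(st3$removal_log$outcome, "noop")
})

test_that("runs are reproducible and 3B equals FID3B with the prior move disabled", {
  fix <- make_emitter_stack(c(8.2, 14.6), c(9.1, 13.5), 500, K = 30,
                            size = c(22, 22), noise = noise_params(),
                            seed = 17)
  cfg <- engine_config(mode = "fid3b", n_iterations = 15,
                       snapshot_interval = 5, initial_spot_count = 3,
                       noise_sigma = 3)
  a <- run_engine(fix$stack, cfg, seed = 9)
  b <- run_engine(fix$stack, cfg, seed = 9)
  expect_identical(ledger(a), ledger(b))
  expect_identical(a$fluorophores, b$fluorophores)
  expect_equal(length(a$snapshots), 3)
  # n_iterations = 0 leaves only the initial model
  st0 <- run_engine(fix$stack, engine_config(n_iterations = 0,
                                             initial_spot_count = 2,
                                             noise_sigma = 3), seed = 1)
  expect_equal(nrow(st0$fluorophores), 2)
  expect_equal(nrow(st0$initial_positions_log), 0)
  # FID3B with the prior-birth probability zeroed reproduces 3B's proposal
  # stream exactly (empty initial model: Step 1 placement is mode-specific)
  cfg_fid0 <- engine_config(mode = "fid3b", op_probs = c(0.7, 0, 0.3),
                            n_iterations = 15, initial_spot_count = 0,
                            noise_sigma = 3)
  cfg_3b <- engine_config(mode = "3b", op_probs = c(0.2, 0.5, 0.3),
                          n_iterations = 15, initial_spot_count = 0,
                          noise_sigma = 3)
  expect_identical(ledger(run_engine(fix$stack, cfg_fid0, seed = 21)),
                   ledger(run_engine(fix$stack, cfg_3b, seed = 21)))
})

test_that("the ledger partitions proposals and tags operations correctly", {
  fix <- make_emitter_stack(c(6, 12), c(6, 12), 500, K = 25, size = c(18, 18),
                            noise = noise_params(), seed = 23)
  st <- run_engine(fix$stack, engine_config(n_iterations = 30,
                                            snapshot_interval = 0,
                                            initial_spot_count = 2,
                                            noise_sigma = 3), seed = 2)
  expect_equal(nrow(st$initial_positions_log),
               nrow(st$retained_log) + nrow(st$discarded_log))
  expect_true(all(st$initial_positions_log$op %in% c("a", "b")))
  expect_true(all(st$removal_log$op == "c"))
  # proposals match birth decisions iteration by iteration
  led <- ledger(st)
  births <- led[led$op %in% c("a", "b"), ]
  expect_equal(sort(births$iteration),
               sort(st$initial_positions_log$iteration))
})
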