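# Grid-scan fitting: scaling, RMSE, decay/affinity/delay recovery,
# half-life prediction and model comparison.

grid_step_alpha <- (1.4 - 0.02) / 199

test_that("min-max scaling handles ordinary, degenerate and fixed ranges", {
  expect_equal(minmax_scale(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(2, 2, 2)), c(0, 0, 0))
  expect_equal(minmax_scale(c(0, 0.3, 1)), c(0, 0.3, 1))
})

test_that("profile RMSE matches the closed-form hat-function value", {
  prof <- expression_profile("sustained", c(0, 1, 1, 1, 1))
  grid <- seq(0, 8, by = 0.1)
  expect_equal(profile_rmse(grid, rep(1, 81) * 0 + approx(c(0, 2, 4, 6, 8),
                                                          c(0, 1, 1, 1, 1),
                                                          xout = grid)$y,
                            prof), 0)
  # model identically zero: RMSE is the RMS of the interpolated ramp,
  # sqrt((sum((i/20)^2, i=0..20) + 60) / 81)
  closed_form <- sqrt((sum((0:20 / 20)^2) + 60) / 81)
  expect_equal(profile_rmse(grid, rep(0, 81), prof), closed_form)
  # Riemann-sum convergence under successive grid halving (the observed
  # 0.1 -> 0.05 change for this fixture is ~1.1e-3 and shrinks further)
  r05 <- profile_rmse(seq(0, 8, 0.05), rep(0, 161), prof,
                      grid = seq(0, 8, 0.05))
  r025 <- profile_rmse(seq(0, 8, 0.025), rep(0, 321), prof,
                       grid = seq(0, 8, 0.025))
  expect_lt(abs(r05 - closed_form), 2e-3)
  expect_lt(abs(r025 - r05), abs(r05 - closed_form))
  expect_error(profile_rmse(seq(0, 8, 0.1), rep(0, 81), prof,
                            grid = seq(0, 4, 0.1)), "cover")
})

test_that("decay/half-life conversion reproduces first-order kinetics", {
  expect_equal(decay_halflife_convert(0.693, "rate_to_halflife"), 1,
               tolerance = 1e-3)
  rate <- decay_halflife_convert(1 / 3, "halflife_to_rate")
  expect_equal(rate, 2.0794, tolerance = 1e-4)
  expect_equal(round(rate, 1), 2.1)
  x <- 0.37
  expect_equal(decay_halflife_convert(decay_halflife_convert(x), # round trip
                                      "halflife_to_rate"), x, tolerance = 1e-12)
  expect_error(decay_halflife_convert(0), "positive")
  expect_error(decay_halflife_convert(-1), "positive")
})

test_that("decay scan uses the documented grid and recovers known rates", {
  sp <- gen_expression_profiles("sustained", 0.2)
  fs <- scan_decay(synthetic_profile(sp, 1))
  expect_length(fs$alpha_grid, 200)
  expect_equal(fs$alpha_grid[1], 0.02)
  expect_equal(fs$alpha_grid[200], 1.4)
  expect_lt(abs(fs$argmin$alpha_m - 0.2), grid_step_alpha)
  expect_lt(fs$rmse_min, 0.02)
  expect_equal(fs$half_life_h, log(2) / fs$argmin$alpha_m)
})

test_that("noiseless decay-scan RMSE is unimodal along the grid", {
  for (cond in c("sustained", "pulsed")) {
    sp <- gen_expression_profiles(cond, 0.45)
    r <- scan_decay(synthetic_profile(sp, 1))$rmse
    interior_minima <- which(diff(sign(diff(r))) == 2) + 1
    expect_true(all(r[interior_minima] <= min(r) + 1e-6))
  }
})

test_that("parameter recovery holds across conditions and decay rates", {
  set.seed(21)
  alphas <- runif(20, 0.05, 1.2)
  conds <- rep(c("sustained", "transient", "pulsed"), length.out = 20)
  for (i in seq_along(alphas)) {
    sp <- gen_expression_profiles(conds[i], alphas[i])
    fs <- scan_decay(synthetic_profile(sp, 1))
    expect_lt(abs(fs$argmin$alpha_m - alphas[i]), grid_step_alpha)
  }
})

test_that("joint decay-affinity scan recovers grid-aligned truth exactly", {
  alpha_true <- 0.02 + 40 * grid_step_alpha       # on the 200-point grid
  K_true <- 0.01 + 33 * (3 - 0.01) / 199
  sp <- gen_expression_profiles("transient", alpha_true, variant = "hill",
                                K = K_true, n_target = 1.8)
  fs <- scan_decay_affinity(synthetic_profile(sp, 1), n_target = 1.8)
  expect_equal(fs$argmin$alpha_m, alpha_true, tolerance = 1e-9)
  expect_equal(fs$argmin$K, K_true, tolerance = 1e-9)
  expect_lt(fs$rmse_min, 1e-6)
  # minimum dominates the surface boundary by construction
  r <- fs$rmse
  expect_true(fs$rmse_min <= min(r[1, ], r[nrow(r), ], r[, 1], r[, ncol(r)]))
})

test_that("off-grid affinity truth recovers the decay axis tightly and the
           affinity axis within its shallow ridge", {
  sp <- gen_expression_profiles("transient", 0.3, variant = "hill",
                                K = 0.5, n_target = 1.8)
  fs <- scan_decay_affinity(synthetic_profile(sp, 1), n_target = 1.8)
  expect_lt(abs(fs$argmin$alpha_m - 0.3), grid_step_alpha)
  expect_lt(abs(fs$argmin$K - 0.5), 0.15)
})

test_that("delay scan spans 0.01-1 h in 25 steps and recovers the delay", {
  p <- jnk_params(tau = 0.8)
  traj <- simulate_jnk(p, make_stimulus("transient"),
                       variant = "mass_action_delay")
  prof <- expression_profile("transient",
                             minmax_scale(sample_target(traj, c(0, 2, 4, 6, 8))))
  fs <- scan_delay(prof, "mass_action_delay")
  expect_length(fs$delay_grid, 25)
  expect_equal(fs$delay_grid[1], 0.01)
  expect_equal(fs$delay_grid[25], 1.0)
  delay_step <- (1 - 0.01) / 24
  expect_lt(abs(fs$argmin$delay - 0.8), delay_step)
  # nested models: allowing a delay can only improve the fit
  no_delay <- scan_decay(prof)
  expect_gte(no_delay$rmse_min, fs$rmse_min - 1e-12)
})

test_that("cluster half-life prediction averages per-gene estimates", {
  sp <- gen_expression_profiles("sustained", rep(0.693, 5), noise_sd = 0.02,
                                seed = 31)
  profs <- lapply(1:5, function(i) synthetic_profile(sp, i))
  est <- predict_cluster_halflife(profs)
  expect_identical(est$n_genes, 5L)
  expect_lt(abs(est$mean_half_life_h - 1) / 1, 0.2)
  expect_false(est$single_gene)
  expect_gt(est$sem_h, 0)

  one <- predict_cluster_halflife(profs[1])
  expect_true(one$single_gene)
  expect_identical(one$sem_h, 0)

  mixed <- gen_expression_profiles("sustained", c(rep(0.1, 3), rep(1.2, 3)))
  mix_est <- predict_cluster_halflife(lapply(1:6, function(i)
    synthetic_profile(mixed, i)))
  hl <- mix_est$per_gene$half_life_h
  expect_gt(mix_est$mean_half_life_h, min(hl))
  expect_lt(mix_est$mean_half_life_h, max(hl))
  expect_error(predict_cluster_halflife(list()), "at least one")
})

test_that("short-lived synthetic clusters get shorter predicted half-lives", {
  short <- gen_expression_profiles("pulsed", rep(log(2) / 0.5, 4),
                                   noise_sd = 0.03, seed = 41)
  long <- gen_expression_profiles("pulsed", rep(log(2) / 5, 4),
                                  noise_sd = 0.03, seed = 42)
  hs <- predict_cluster_halflife(lapply(1:4, function(i) synthetic_profile(short, i)))
  hl <- predict_cluster_halflife(lapply(1:4, function(i) synthetic_profile(long, i)))
  expect_lt(hs$mean_half_life_h, hl$mean_half_life_h)
})

test_that("model comparison is deterministic and identifies the generator", {
  spm <- gen_expression_profiles("sustained", 0.3)
  pm <- synthetic_profile(spm, 1)
  tab1 <- compare_models(pm)
  tab2 <- compare_models(pm)
  expect_identical(tab1, tab2)
  # Hill promoters nest the saturated regime: on a mass-action profile
  # their best fit cannot be meaningfully worse
  best_hill <- min(tab1$rmse_min[tab1$model != "mass_action"])
  expect_lte(best_hill, tab1$rmse_min[tab1$model == "mass_action"] + 0.02)

  # strongly cooperative generator, truth on the default comparison grids
  alpha_true <- 0.02 + 27 * (1.4 - 0.02) / 99
  K_true <- 0.01 + 49 * (3 - 0.01) / 99
  sph <- gen_expression_profiles("transient", alpha_true, variant = "hill",
                                 K = K_true, n_target = 4)
  tab <- compare_models(synthetic_profile(sph, 1))
  expect_identical(tab$model[1], "hill_4")
})

test_that("fast scan path matches full joint simulation", {
  sp <- gen_expression_profiles("pulsed", 0.3)
  prof <- synthetic_profile(sp, 1)
  alpha10 <- seq(0.02, 1.4, length.out = 200)[seq(10, 200, by = 20)]
  g <- jnkdyn:::scan_grids(prof, jnk_params(), 8, 0.001, 0.1, 0)
  f <- jnkdyn:::scan_forcing(g$pjun, jnk_params())
  out <- jnkdyn:::target_scan_batch(f, 0.001, alpha10, 1 / alpha10, g$outidx)
  M <- matrix(out, nrow = length(prof$timepoints))
  for (i in seq_along(alpha10)) {
    traj <- simulate_jnk(jnk_params(alpha_m = alpha10[i]),
                         make_stimulus("pulsed"), dt_out = 0.05)
    joint <- sample_target(traj, prof$timepoints)
    expect_lt(sqrt(mean((minmax_scale(M[, i]) - minmax_scale(joint))^2)),
              1e-6)
  }
})
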