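# Core model: rate equations, steady state, stimulus programs,
# simulation and trajectory sampling.

zero_state <- setNames(rep(0, 7),
                       c("inactive_cJun", "pJun", "cJun_mRNA", "target_gene",
                         "active_JNK", "DUSP1_mRNA", "DUSP1"))

test_that("rate equations reduce correctly at limiting states", {
  p <- jnk_params()
  d0 <- jnk_rhs(zero_state, 0, p, c_value = 0)
  # only the two basal production terms are active at the zero state
  expect_equal(d0[["cJun_mRNA"]], p$beta_jmi)
  expect_equal(d0[["cJun_mRNA"]], 1.0)
  expect_equal(d0[["target_gene"]], p$beta_t)
  expect_equal(unname(d0[setdiff(names(d0), c("cJun_mRNA", "target_gene"))]),
               rep(0, 5))

  d1 <- jnk_rhs(zero_state, 0, p, c_value = 1)
  expect_equal(d1[["active_JNK"]], p$beta_jnkp)     # stimulus-driven input
  expect_equal(d1[["active_JNK"]], 10.0)

  # no kinase, no substrate flux into pJun
  s <- zero_state
  s["inactive_cJun"] <- 3
  expect_equal(jnk_rhs(s, 0, p, c_value = 1)[["pJun"]], 0)

  expect_error(jnk_rhs(replace(zero_state, 1, -1), 0, p), "negative")
})

test_that("Hill promoter term saturates as K -> 0", {
  p <- jnk_params(K = 1e-6)
  s <- zero_state
  s["pJun"] <- 0.5
  d <- jnk_rhs(s, 0, p, c_value = 0, variant = "hill")
  expect_equal(d[["target_gene"]], p$beta_t + p$beta_tj, tolerance = 1e-4)
})

test_that("stimulus programs encode the treatment schedules", {
  expect_equal(make_stimulus("sustained")$on_intervals[1, ],
               c(start = 0, end = Inf))
  expect_equal(unname(make_stimulus("transient")$on_intervals), matrix(c(0, 1), 1))
  expect_equal(unname(make_stimulus("pulsed")$on_intervals),
               matrix(c(0, 4, 1, 5), 2))
  expect_equal(nrow(make_stimulus("none")$on_intervals), 0)
  expect_equal(stimulus_value(make_stimulus("pulsed"), c(0.5, 2, 4.5, 7)),
               c(1, 0, 1, 0))
  expect_error(make_stimulus("ramp"), "sustained")
  expect_error(stimulus_program(matrix(c(0, 1, 2, 3), 2)), "overlap")
})

test_that("resting steady state has the closed-form composition", {
  p <- jnk_params()
  s <- steady_state(p)
  expect_equal(s[["cJun_mRNA"]], 1 / 2.1, tolerance = 1e-12)
  expect_equal(s[["pJun"]], 0)
  expect_equal(s[["inactive_cJun"]], 3 * (1 / 2.1) / 0.5)
  s2 <- steady_state(jnk_params(alpha_m = 0.693))
  expect_equal(s2[["target_gene"]], 1 / 0.693, tolerance = 1e-12)
  # fixed point: residual of the rate equations below 1e-8
  expect_lt(max(abs(jnk_rhs(s, 0, p, c_value = 0))), 1e-8)
})

test_that("unstimulated simulation stays at the fixed point", {
  traj <- simulate_jnk(jnk_params(), make_stimulus("none"), t_end = 8)
  s <- steady_state(jnk_params())
  for (sp in colnames(traj$states)) {
    drift <- abs(traj$states[, sp] - s[[sp]]) / max(abs(s[[sp]]), 1e-12)
    expect_lt(max(drift), 1e-6)
  }
})

test_that("pulsed stimulus yields two pJun activation pulses", {
  traj <- simulate_jnk(jnk_params(), make_stimulus("pulsed"))
  pk <- count_peaks(traj$states[, "pJun"], traj$times, min_height = 0.1)
  expect_identical(pk$n_peaks, 2L)
  # pulses track the two treatment windows
  expect_true(abs(pk$peak_times[1] - 1) < 0.5)
  expect_true(abs(pk$peak_times[2] - 5) < 0.5)
})

test_that("transient pJun pulse decays back to rest after washout", {
  traj <- simulate_jnk(jnk_params(), make_stimulus("transient"))
  pj <- traj$states[, "pJun"]
  peak <- max(pj)
  after <- traj$times >= 4   # 3 h past the 1-h washout
  expect_lt(max(pj[after]), 0.05 * peak)
})

test_that("short-lived target under sustained input rises then declines", {
  p <- jnk_params(alpha_m = log(2) / 0.5)
  traj <- simulate_jnk(p, make_stimulus("sustained"))
  tg <- minmax_scale(traj$states[, "target_gene"])
  expect_lt(which.max(tg), length(tg))      # peak strictly before t_end
  expect_lt(tg[length(tg)], 0.9)            # declined from its maximum
})

test_that("sample_target interpolates linearly and refuses extrapolation", {
  traj <- simulate_jnk(jnk_params(), make_stimulus("transient"), dt_out = 0.05)
  expect_equal(sample_target(traj, traj$times[c(3, 40)]),
               unname(traj$states[c(3, 40), "target_gene"]))
  mid <- mean(traj$times[5:6])
  expect_equal(sample_target(traj, mid),
               mean(traj$states[5:6, "target_gene"]))
  expect_length(sample_target(traj, c(0, 2, 4, 6, 8)), 5)
  expect_error(sample_target(traj, 9), "extrapolation")
})

test_that("species stay non-negative across stimuli and parameter draws", {
  base <- unlist(jnk_params())[1:20]
  set.seed(11)
  for (i in 1:5) {
    fac <- exp(runif(20, log(0.8), log(1.25)))
    p <- do.call(jnk_params, as.list(base * fac))
    for (lab in c("sustained", "transient", "pulsed")) {
      traj <- simulate_jnk(p, make_stimulus(lab), t_end = 9)
      expect_gte(min(traj$states), -1e-9)
    }
  }
})

test_that("delay variant converges to the undelayed model as tau -> 0", {
  hill <- simulate_jnk(jnk_params(), make_stimulus("pulsed"), variant = "hill")
  del <- simulate_jnk(jnk_params(tau = 1e-4), make_stimulus("pulsed"),
                      variant = "hill_delay")
  rms <- sqrt(mean((hill$states[, "target_gene"] -
                      del$states[, "target_gene"])^2))
  expect_lt(rms, 1e-3)
})

test_that("a finite transcription delay shifts the target response", {
  und <- simulate_jnk(jnk_params(), make_stimulus("transient"))
  del <- simulate_jnk(jnk_params(tau = 0.8), make_stimulus("transient"),
                      variant = "mass_action_delay")
  t_half_rise <- function(traj) {
    tg <- traj$states[, "target_gene"]
    traj$times[min(which(tg > min(tg) + 0.5 * diff(range(tg))))]
  }
  expect_gt(t_half_rise(del), t_half_rise(und) + 0.4)
  expect_error(simulate_jnk(jnk_params(tau = 0.5), make_stimulus("none")),
               "delay variant")
})

test_that("pulse counting collapses plateaus and ignores endpoints", {
  x <- c(0, 1, 1, 1, 0, 2, 0, 3)        # plateau, interior peak, rising end
  pk <- count_peaks(x)
  expect_identical(pk$n_peaks, 2L)
  expect_identical(pk$peak_index, c(2L, 6L))
  expect_identical(count_peaks(rep(1, 10))$n_peaks, 0L)
  # prominence filter drops the shoulder but keeps the major peak
  y <- c(0, 0.5, 0.45, 1, 0)
  expect_identical(count_peaks(y, min_prominence = 0.2)$n_peaks, 1L)
  expect_identical(count_peaks(y)$n_peaks, 2L)
})
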