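# KTR trace quantification: baseline, pulse detection, durations and
# population summaries.

test_that("baseline averages the pre-treatment frames", {
  times <- seq(-4 / 6, 2, by = 1 / 6)
  tr <- cell_trace("c1", times, rep(1, length(times)))
  expect_equal(compute_baseline(tr), 1.0)
  v <- rep(1, length(times))
  v[times < 0] <- c(0.8, 1.0, 1.2, 1.0)
  tr2 <- cell_trace("c2", times, v)
  expect_equal(compute_baseline(tr2), 1.0)
  # three pre-treatment frames are not enough
  expect_error(cell_trace("c3", seq(-3 / 6, 2, by = 1 / 6),
                          rep(1, 16)), "4 pre-treatment")
})

test_that("trace validation rejects malformed inputs", {
  expect_error(cell_trace("c", c(-0.5, -0.3, -0.2, -0.1, 0, 0.5),
                          rep(1, 6)), "uniform")
  expect_error(cell_trace("c", seq(-4 / 6, 1, 1 / 6),
                          c(rep(1, 9), -0.2, 1)), "> 0")
})

test_that("pulse detection applies the 50%-above-baseline rule", {
  flat <- cell_trace("f", seq(-4 / 6, 8, 1 / 6),
                     rep(1, length(seq(-4 / 6, 8, 1 / 6))))
  expect_identical(detect_pulses(flat)$n_pulses, 0L)

  tb <- two_bump_trace(peak1 = 2, peak2 = 2)
  ps <- detect_pulses(tb)
  expect_identical(ps$n_pulses, 2L)
  expect_lt(abs(ps$peak_times[1] - 0.5), 0.2)
  expect_lt(abs(ps$peak_times[2] - 4.5), 0.2)
  expect_equal(ps$threshold, 1.5 * ps$baseline)

  # a 1.4x-baseline bump stays below the 1.5x threshold
  low <- two_bump_trace(peak1 = 1.4, peak2 = 1.4)
  expect_identical(detect_pulses(low)$n_pulses, 0L)

  # plateau at the maximum counts once, at its leftmost frame
  times <- seq(-4 / 6, 3, 1 / 6)
  v <- rep(1, length(times))
  v[times > 1 - 1e-9 & times < 1.5 + 1e-9] <- 2
  plat <- cell_trace("p", times, v)
  expect_identical(detect_pulses(plat)$n_pulses, 1L)
  expect_equal(detect_pulses(plat)$peak_times, 1)
})

test_that("activity durations count threshold-exceeding frames", {
  times <- seq(-4 / 6, 8, 1 / 6)
  v <- rep(1, length(times))
  v[times > 1 - 1e-9 & times < 2 - 1e-9] <- 2    # exactly 6 frames above
  tr <- cell_trace("d", times, v)
  expect_equal(activity_duration(tr), 1.0)
  expect_equal(activity_duration(tr, window = c(0, 3)), 1.0)

  below <- cell_trace("b", times, rep(1.2, length(times)))
  expect_equal(activity_duration(below), 0)

  # activity confined to 3-5 h is invisible to a (0, 3) window
  v2 <- rep(1, length(times))
  v2[times > 3 - 1e-9 & times < 5 - 1e-9] <- 2
  late <- cell_trace("l", times, v2)
  expect_equal(activity_duration(late, window = c(0, 3)), 0)
  expect_gt(activity_duration(late), 0)
  expect_error(activity_duration(late, window = c(10, 12)), "outside")
})

test_that("raising the threshold never increases pulse or duration metrics", {
  syn <- gen_cell_traces("pulsed", 20, noise_sd = 0.05, seed = 8)
  for (tr in syn$traces[1:10]) {
    b <- compute_baseline(tr)
    expect_lte(detect_pulses(tr, b, threshold_frac = 0.8)$n_pulses,
               detect_pulses(tr, b, threshold_frac = 0.5)$n_pulses)
    expect_lte(activity_duration(tr, b, threshold_frac = 0.8),
               activity_duration(tr, b, threshold_frac = 0.5))
    expect_lte(activity_duration(tr, b, window = c(0, 3)),
               activity_duration(tr, b))
  }
})

test_that("population summary aligns frames and tabulates per-cell metrics", {
  times <- seq(-4 / 6, 8, 1 / 6)
  one <- two_bump_trace()
  s1 <- summarize_population(list(one))
  expect_equal(s1$frame_summary$mean, one$cn_ratio)
  expect_equal(s1$frame_summary$sd, rep(0, length(one$cn_ratio)))

  # mirror-image pair averages to the constant midline
  base <- rep(1.6, length(times))
  dev <- 0.4 * sin(seq_along(times) / 3)
  up <- cell_trace("u", times, base + dev)
  dn <- cell_trace("v", times, base - dev)
  s2 <- summarize_population(list(up, dn))
  expect_equal(s2$frame_summary$mean, base)

  short <- cell_trace("s", times[1:20], rep(1, 20))
  expect_error(summarize_population(list(one, short)), "frame grid")
})

test_that("programmed pulsed cells are dominated by two-pulse calls", {
  syn <- gen_cell_traces("pulsed", 100, noise_sd = 0, seed = 12)
  s <- summarize_population(syn$traces)
  counts <- s$cell_summary$n_pulses
  expect_identical(as.integer(names(which.max(table(counts)))), 2L)
  expect_true(all(counts == 2))
})

test_that("pulse counts survive 10% frame noise with the spacing rule", {
  syn <- gen_cell_traces("pulsed", 100, noise_sd = 0.1, seed = 5)
  counts <- vapply(syn$traces, function(tr) {
    detect_pulses(tr, min_peak_distance = 1)$n_pulses
  }, integer(1))
  expect_gte(mean(counts == syn$truth$programmed_pulses), 0.95)
})
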