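test_that("lowess reproduces constants and straight lines exactly", {
  expect_equal(lowess_smooth(rep(3.5, 50)), rep(3.5, 50))
  y <- 0.5 + 0.01 * (1:200)
  expect_equal(lowess_smooth(y, 0.1, 3, 20), y, tolerance = 1e-9)
})

test_that("lowess is translation- and scale-equivariant", {
  set.seed(51)
  y <- exp(-(1:300) / 400) + rnorm(300, 0, 0.02)
  f <- lowess_smooth(y, 0.1, 3, 20)
  expect_equal(lowess_smooth(2.5 * y, 0.1, 3, 20), 2.5 * f,
               tolerance = 1e-9)
  # translation changes the relative robustness cutoff only through the
  # numeric guard, not the fit
  expect_equal(lowess_smooth(y + 4, 0.1, 3, 20), f + 4, tolerance = 1e-9)
})

test_that("delta = 0 equals the naive no-delta oracle to machine precision", {
  set.seed(52)
  y <- bleach_spike_fixture(n = 300, noise_sd = 0.01)
  expect_equal(lowess_smooth(y, 0.1, 3, 0), lowess_oracle(y, 0.1, 3),
               tolerance = 1e-12)
  # the spike survives in the residual
  fit <- lowess_smooth(y, 0.1, 3, 20)
  expect_gt((y - fit)[150], 0.4)
})

test_that("delta acceleration is exact at anchors and interpolates between", {
  y <- bleach_spike_fixture(n = 300, noise_sd = 0)
  f0 <- lowess_smooth(y, 0.1, 0, 0)
  f20 <- lowess_smooth(y, 0.1, 0, 20)
  anchors <- c(seq(1, 281, by = 20), 300)
  expect_equal(f20[anchors], f0[anchors], tolerance = 1e-12)
  # between anchors the fit is the chord of the anchor fits
  expect_equal(f20[1:21], approx(c(1, 21), f0[c(1, 21)], xout = 1:21)$y,
               tolerance = 1e-12)
})

test_that("lowess rejects windows below two points", {
  expect_error(lowess_smooth(1:1), "two points")
})

test_that("preprocessing z-scores the subtracted residual", {
  set.seed(53)
  s <- simulate_task_session(task_config(session_duration = 120))
  tr <- simulate_photometry(s)
  pp <- preprocess_photometry(tr)
  n <- nrow(pp)
  expect_equal(mean(pp$z), 0, tolerance = 1e-9)
  expect_equal(sqrt(sum((pp$z - mean(pp$z))^2) / n), 1, tolerance = 1e-9)
  expect_equal(pp$dff, pp$resid470 - pp$resid415)

  # identical channels: delta fluorescence is constant zero -> error
  flat <- tibble::tibble(time_s = (0:499) / 50, ch470 = rnorm(500))
  flat$ch415 <- flat$ch470
  expect_error(preprocess_photometry(flat), "constant")
})

test_that("detrending removes nearly all bleaching variance", {
  set.seed(54)
  s <- simulate_task_session(task_config(session_duration = 300))
  cfg <- photo_sim_config(noise_sd = 0.02, transient_amp = 0, dip_amp = 0,
                          artifact_amp = 0)
  tr <- simulate_photometry(s, cfg)
  pp <- preprocess_photometry(tr)
  bleach <- 2 * exp(-tr$time_s / 60) + exp(-tr$time_s / 600)
  expect_lt(var(pp$resid470), 0.01 * var(bleach))
  # residual noise level close to the injected noise
  expect_equal(sd(pp$resid470), cfg$noise_sd, tolerance = 0.1)
  expect_equal(sd(pp$dff), sqrt(2) * cfg$noise_sd, tolerance = 0.1)
})

test_that("the common-mode artifact cancels in the subtracted trace", {
  set.seed(55)
  s <- simulate_task_session(task_config(session_duration = 300))
  base <- photo_sim_config(noise_sd = 0, transient_amp = 0, dip_amp = 0,
                           artifact_amp = 0)
  with_art <- photo_sim_config(noise_sd = 0, transient_amp = 0, dip_amp = 0,
                               artifact_amp = 0.5)
  tr0 <- simulate_photometry(s, base)
  tr1 <- simulate_photometry(s, with_art)
  pp0 <- preprocess_photometry(tr0)
  pp1 <- preprocess_photometry(tr1)
  # artifact power surviving the detrend in a single channel...
  leak_single <- sd(pp1$resid470 - pp0$resid470)
  # ...must be suppressed by the isosbestic subtraction
  leak_dff <- sd(pp1$dff - pp0$dff)
  expect_gt(leak_single, 0.01)
  expect_lt(leak_dff, leak_single / 10)
})

test_that("PETH extraction aligns windows at the nearest sample", {
  z <- tibble::tibble(time_s = (0:999) / 50, z = 0)
  cfg <- peth_config(window_pre = 1, window_post = 2)
  p <- compute_peth(z, c(5, 10), cfg)
  expect_equal(dim(p$trials), c(2L, 151L))
  expect_true(all(p$trials == 0))
  expect_true(all(p$mean == 0) && all(p$sem == 0))
  # single event: the trial row is the window verbatim
  z$z <- rnorm(1000)
  p1 <- compute_peth(z, 10, cfg)
  expect_equal(drop(p1$trials), z$z[(501 - 50):(501 + 100)])
  expect_equal(p1$mean, drop(p1$trials))
  # default window at 50 Hz has 226 timepoints
  p2 <- compute_peth(z, 10, peth_config())
  expect_length(p2$rel_time, 226L)
  # events too close to the edges are dropped and counted
  p3 <- compute_peth(z, c(0.2, 10, 19.9), cfg)
  expect_equal(p3$dropped, 2L)
  expect_error(compute_peth(z, 0.1, cfg), "window")
})

test_that("PETH recovers a known transient amplitude within the CLT bound", {
  set.seed(56)
  rate <- 50
  n <- 60000
  sigma <- 0.1
  amp <- 1
  z <- rnorm(n, 0, sigma)
  events <- seq(60, by = 22, length.out = 50)
  kern <- amp * exp(-(0:100) / (0.2 * rate))
  for (t0 in events) {
    i0 <- round(t0 * rate) + 1
    z[i0:(i0 + 100)] <- z[i0:(i0 + 100)] + kern
  }
  d <- tibble::tibble(time_s = (0:(n - 1)) / rate, z = z)
  p <- compute_peth(d, events, peth_config())
  at0 <- which(p$rel_time == 0)
  expect_equal(p$mean[at0], amp, tolerance = 3 * sigma / sqrt(50) / amp)
  expect_equal(p$n_trials, 50L)
})

test_that("per-trial baseline subtraction recentres each trial window", {
  z <- tibble::tibble(time_s = (0:999) / 50, z = 5)
  cfg <- peth_config(window_pre = 1, window_post = 1,
                     baseline = c(-1, -0.5))
  p <- compute_peth(z, 10, cfg)
  expect_true(all(abs(p$trials) < 1e-12))
})

test_that("the repeated-measures comparison reproduces design dfs and aov", {
  set.seed(57)
  yr <- matrix(rnorm(4 * 5, 1), 4, 5)
  yu <- matrix(rnorm(4 * 5), 4, 5)
  res <- compare_peths(yr, yu, posthoc = "none")
  ref <- rm_anova_oracle(yr, yu)
  expect_equal(res$anova$statistic, unname(ref), tolerance = 1e-8)
  expect_equal(res$anova$df1, c(4L, 1L, 4L))
  expect_equal(res$anova$df2, c(12L, 3L, 12L))
})

test_that("identical groups give a null trial-type effect and empty mask", {
  set.seed(58)
  y <- matrix(rnorm(6 * 30), 6, 30)
  res <- compare_peths(y, y)
  expect_lt(res$anova$statistic[res$anova$term == "trial_type"], 1e-20)
  expect_equal(sum(res$mask), 0L)
})

test_that("a confined group difference is localised by the post hoc mask", {
  set.seed(59)
  n <- 22; tp <- 226
  rel <- seq(-1.5, 3.0, length.out = tp)
  effect_window <- rel >= 0 & rel <= 1
  # effect sized at 7x the group-difference standard error
  effect <- 7 * sqrt(2) / sqrt(n)
  reps <- 10
  hits <- 0; false_alarm <- 0
  for (r in seq_len(reps)) {
    yr <- matrix(rnorm(n * tp), n, tp)
    yu <- matrix(rnorm(n * tp), n, tp)
    yr[, effect_window] <- yr[, effect_window] + effect
    res <- compare_peths(
      structure(list(trials = yr, rel_time = rel), class = "peth"),
      structure(list(trials = yu, rel_time = rel), class = "peth")
    )
    hits <- hits + mean(res$mask[effect_window])
    false_alarm <- false_alarm + mean(res$mask[!effect_window])
  }
  expect_gt(hits / reps, 0.8)
  expect_lt(false_alarm / reps, 0.05)
})

test_that("mismatched group shapes are rejected", {
  expect_error(compare_peths(matrix(0, 3, 5), matrix(0, 4, 5)), "same")
  expect_error(compare_peths(matrix(0, 1, 5), matrix(0, 1, 5)), "at least")
})
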