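test_that("ITI draws respect the truncation bounds and conditional law", {
  set.seed(101)
  cfg <- task_config()
  x <- sample_iti(5000, cfg)
  expect_true(all(x >= cfg$iti_min & x <= cfg$iti_max))
  # conditional-exponential mean, not the clamp mean (which would exceed it)
  expect_equal(mean(x),
               trunc_exp_mean_oracle(cfg$iti_mean, cfg$iti_min, cfg$iti_max),
               tolerance = 0.05)
})

test_that("the generator is bit-for-bit reproducible under a fixed seed", {
  run <- function() {
    set.seed(77)
    s <- simulate_task_session(task_config(session_duration = 200))
    sn <- corrupt_events(s)
    tr <- simulate_photometry(s, photo_sim_config())
    list(s$licks, s$reward_times, sn$events, tr)
  }
  expect_identical(run(), run())
})

test_that("lick trains have ordered, non-overlapping licks inside the session", {
  set.seed(5)
  for (rep in 1:5) {
    s <- simulate_lick_train(lick_train_params(), duration = 600)
    expect_true(all(diff(s$licks$onset) > 0))
    expect_true(all(s$licks$offset > s$licks$onset))
    expect_true(all(s$licks$offset[-nrow(s$licks)] < s$licks$onset[-1]))
    expect_true(all(s$licks$offset <= 600))
    expect_true(all(s$licks$onset >= 0))
  }
})

test_that("zero duration yields an empty session", {
  set.seed(1)
  s <- simulate_lick_train(lick_train_params(), duration = 0)
  expect_equal(nrow(s$licks), 0L)
  expect_equal(nrow(s$bouts), 0L)
})

test_that("forcing 5 bouts of 10 licks gives 50 licks and 45 within-bout ILIs", {
  set.seed(9)
  params <- lick_train_params(licks_per_bout = list(name = "fixed", size = 10))
  s <- simulate_lick_train(params, n_bouts = 5)
  expect_equal(nrow(s$licks), 50L)
  expect_equal(s$bouts$n_licks, rep(10L, 5))
  within <- unlist(lapply(split(s$licks$onset, s$licks$bout), diff))
  expect_length(within, 45L)
  expect_true(all(within >= params$ili_floor & within <= params$ili_ceiling))
})

test_that("within-bout ILIs concentrate at the configured licking rhythm", {
  set.seed(11)
  s <- simulate_lick_train(lick_train_params(), duration = 1800)
  within <- unlist(lapply(split(s$licks$onset, s$licks$bout), diff))
  expect_gt(length(within), 500)
  expect_equal(mean(within), 0.146, tolerance = 0.005 / 0.146)
})

test_that("a noiseless error model reproduces the truth bijectively", {
  set.seed(2)
  s <- simulate_lick_train(lick_train_params(), duration = 300)
  clean <- error_model(p_fn_short = 0, p_fn_sipper = 0, p_double = 0,
                       p_snout = 0)
  sn <- corrupt_events(s, clean)
  expect_equal(nrow(sn$events), nrow(s$licks))
  expect_true(all(sn$events$source == "true"))
  expect_equal(sn$events$truth_lick, seq_len(nrow(s$licks)))
  # each event sits inside its lick interval
  expect_true(all(sn$events$onset >= s$licks$onset &
                    sn$events$offset <= s$licks$offset))
})

test_that("double detections appear at the configured rate with sub-50ms gaps", {
  set.seed(3)
  s <- simulate_lick_train(
    lick_train_params(licks_per_bout = list(name = "fixed", size = 10)),
    n_bouts = 100
  )
  sn <- corrupt_events(s, error_model(p_fn_short = 0, p_fn_sipper = 0,
                                      p_double = 0.1, p_snout = 0))
  doubles <- sn$events[sn$events$source == "double_fp", ]
  expect_equal(nrow(doubles), 100, tolerance = 0.3)
  true_on <- sn$events$onset[sn$events$source == "true"]
  gaps <- doubles$onset -
    sn$events$onset[match(doubles$truth_lick, sn$events$truth_lick)]
  expect_true(all(gaps > 0 & gaps < 0.05))
})

test_that("snout artifacts stay clear of lick intervals", {
  set.seed(4)
  s <- simulate_lick_train(lick_train_params(), duration = 600)
  model <- error_model(p_snout = 0.1)
  sn <- corrupt_events(s, model)
  snout <- sn$events[sn$events$source == "snout_fp", ]
  expect_gt(nrow(snout), 10)
  for (i in seq_len(nrow(snout))) {
    expect_false(any(s$licks$onset < snout$offset[i] &
                       s$licks$offset > snout$onset[i]))
  }
})

test_that("false-negative rates per lick kind follow the error model", {
  set.seed(6)
  s <- simulate_lick_train(lick_train_params(), duration = 20000)
  sn <- corrupt_events(s, error_model())
  st <- sn$lick_status
  for (kd in c("short", "sipper")) {
    sub <- st[st$kind == kd, ]
    p <- if (kd == "short") 10 / 27 else 4 / 203
    bt <- stats::binom.test(sum(!sub$detected), nrow(sub), p = p)
    expect_gt(bt$p.value, 0.01)
  }
})

test_that("rewards land exactly on first licks of bouts, spaced by the ITI floor", {
  set.seed(8)
  for (rep in 1:20) {
    s <- simulate_task_session(task_config(session_duration = 400))
    first_licks <- s$bouts$start
    expect_true(all(s$reward_times %in% first_licks))
    expect_equal(s$reward_times, first_licks[s$bouts$rewarded])
    if (length(s$reward_times) > 1) {
      expect_true(all(diff(s$reward_times) >= s$task$iti_min))
    }
  }
})

test_that("a session without licks yields no rewards", {
  set.seed(10)
  s <- simulate_task_session(
    task_config(session_duration = 5),
    lick_train_params(bout_rate = 1e-6)
  )
  expect_equal(nrow(s$licks), 0L)
  expect_length(s$reward_times, 0L)
})

test_that("photometry channels reduce to their deterministic parts", {
  set.seed(12)
  s <- simulate_task_session(task_config(session_duration = 60))
  flat <- photo_sim_config(bleach_amp = 0, bleach_tau = 1, noise_sd = 0,
                           transient_amp = 0, dip_amp = 0, artifact_amp = 0)
  tr <- simulate_photometry(s, flat)
  expect_equal(tr$ch470, rep(flat$baseline_470, nrow(tr)))
  expect_equal(tr$ch415, rep(flat$baseline_415, nrow(tr)))

  bl <- photo_sim_config(bleach_amp = c(2, 1), bleach_tau = c(60, 600),
                         noise_sd = 0, transient_amp = 0, dip_amp = 0,
                         artifact_amp = 0)
  tr2 <- simulate_photometry(s, bl)
  expected <- bl$baseline_470 + 2 * exp(-tr2$time_s / 60) +
    exp(-tr2$time_s / 600)
  expect_equal(tr2$ch470, expected, tolerance = 1e-12)
  expect_equal(tr2$ch415,
               bl$baseline_415 + bl$iso_scale * (expected - bl$baseline_470),
               tolerance = 1e-12)
})

test_that("pose tracks expose every lick above the poke line at the right kind", {
  set.seed(13)
  s <- simulate_lick_train(lick_train_params(), duration = 200)
  pose <- simulate_pose_track(s)
  vl <- segment_video_licks(pose, segmentation_config())
  expect_equal(nrow(vl), nrow(s$licks))
  expect_equal(vl$kind, s$licks$kind)
})
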