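test_that("video segmentation finds excursions with frame-accurate bounds", {
  cfg <- segmentation_config(pad_frames = 0)
  # never beyond the poke line -> nothing
  expect_equal(nrow(segment_video_licks(make_tongue_track(rep(5, 20)), cfg)),
               0L)
  # one excursion past the sipper line -> one sipper lick
  y <- c(rep(0, 5), 30, 60, 55, 30, rep(0, 5))
  vl <- segment_video_licks(make_tongue_track(y), cfg)
  expect_equal(nrow(vl), 1L)
  expect_equal(vl$kind, "sipper")
  expect_equal(vl$peak_displacement, 60)
  expect_equal(vl$start, 5 / 60)
  expect_equal(vl$end, 8 / 60)
  # two excursions separated by more than max_gap_frames -> two licks
  y2 <- c(0, 30, 35, 0, 0, 0, 0, 0, 40, 42, 0)
  vl2 <- segment_video_licks(make_tongue_track(y2), cfg)
  expect_equal(nrow(vl2), 2L)
  expect_equal(vl2$kind, c("short", "short"))
  expect_equal(vl2$start, c(1, 8) / 60)
  expect_equal(vl2$end, c(2, 9) / 60)
  # a single-frame dropout within max_gap_frames is bridged
  y3 <- c(0, 30, 0, 35, 0)
  vl3 <- segment_video_licks(make_tongue_track(y3), cfg)
  expect_equal(nrow(vl3), 1L)
})

test_that("segmentation respects the likelihood threshold and tongue requirement", {
  track <- make_tongue_track(c(0, 40, 0), likelihood = c(0.99, 0.2, 0.99))
  expect_equal(nrow(segment_video_licks(track)), 0L)
  nose_only <- tibble::tibble(frame = 0L, time_s = 0, bodypart = "nose",
                              x = 0, y = 0, likelihood = 1)
  expect_error(segment_video_licks(nose_only), "tongue_tip")
})

test_that("event matching implements the TP/FP/FN classification rules", {
  licks <- tibble::tibble(start = c(1.0, 2.0), end = c(1.1, 2.1),
                          kind = c("sipper", "sipper"))
  # lick with no event -> FN; two events in one lick -> TP then FP;
  # event outside every lick -> FP
  ev <- make_events(c(1.02, 1.05, 5.0), duration = 0.02)
  m <- match_events(licks, ev)
  expect_equal(m$events$label, c("TP", "FP", "FP"))
  expect_equal(m$events$video_lick, c(1L, 1L, NA_integer_))
  expect_equal(m$licks$matched, c(TRUE, FALSE))
  # label partition invariants
  expect_equal(sum(m$events$label %in% c("TP", "FP")), nrow(ev))
  expect_equal(sum(m$licks$matched) + sum(!m$licks$matched), nrow(licks))
})

test_that("overlapping video licks are rejected as ambiguous", {
  licks <- tibble::tibble(start = c(1.0, 1.05), end = c(1.1, 1.2))
  expect_error(match_events(licks, make_events(1.02)), "ambiguous")
})

test_that("detection metrics use explicit NA sentinels and both summaries", {
  m <- detection_metrics(data.frame(tp = 9, fp = 1, fn = 0))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 1.0)
  m0 <- detection_metrics(data.frame(tp = 0, fp = 0, fn = 2))
  expect_true(is.na(m0$precision))
  expect_equal(m0$recall, 0)

  two <- data.frame(tp = c(9, 1), fp = c(1, 9), fn = c(0, 0))
  s <- detection_summary(two)
  expect_equal(s$precision[s$summary == "pooled"], 0.5)
  expect_equal(s$precision[s$summary == "mean_of_sessions"], 0.5)
  # unbalanced sessions: pooled and mean-of-ratios diverge
  unb <- data.frame(tp = c(90, 1), fp = c(10, 9), fn = c(0, 0))
  s2 <- detection_summary(unb)
  expect_equal(s2$precision[s2$summary == "pooled"], 91 / 110)
  expect_equal(s2$precision[s2$summary == "mean_of_sessions"], 0.5)
})

test_that("Fisher's exact test matches hand-enumerable cases", {
  # empty first column: only one table possible
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 0, 7), 2, byrow = TRUE)), 1)
  # diagonal 2x2 with margins 2/2/2: p = 1/6 + 1/6
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 3, tolerance = 1e-12)
})

test_that("Fisher's exact test agrees with stats::fisher.test", {
  set.seed(31)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("the post hoc filter applies duration and ILI keep-criteria", {
  cfg <- filter_config()
  # duration outside [0.003, 0.2] s -> removed for duration
  long_ev <- tibble::tibble(channel = "lick", onset = 1, offset = 1.25)
  f <- apply_posthoc_filter(long_ev, cfg)
  expect_equal(nrow(f$events), 0L)
  expect_equal(f$removed$reason, "duration")
  # two valid-duration events 30 ms apart -> second removed for ILI
  f2 <- apply_posthoc_filter(make_events(c(1.0, 1.03), 0.02), cfg)
  expect_equal(f2$events$onset, 1.0)
  expect_equal(f2$removed$reason, "ili")
  # isolated valid event is kept
  f3 <- apply_posthoc_filter(make_events(2.0, 0.05), cfg)
  expect_equal(nrow(f3$events), 1L)
  expect_equal(nrow(f3$removed), 0L)
})

test_that("the filter ILI is measured against the previous kept event", {
  # a removed double must not shield the next double: with onsets 0.03 apart
  # the second event is removed, and the third (0.06 from the first kept)
  # passes the ILI guard
  f <- apply_posthoc_filter(make_events(c(1.0, 1.03, 1.06), 0.02))
  expect_equal(f$events$onset, c(1.0, 1.06))
  # under the disjunctive reading both criteria must fail to remove
  fe <- apply_posthoc_filter(make_events(c(1.0, 1.03), 0.02),
                             rule = "either")
  expect_equal(nrow(fe$events), 2L)
  bad <- tibble::tibble(channel = "lick", onset = c(1.0, 1.03),
                        offset = c(1.02, 1.33))
  fe2 <- apply_posthoc_filter(bad, rule = "either")
  expect_equal(fe2$removed$reason, "duration+ili")
})

test_that("on synthetic sessions, scoring recovers the generative error rates", {
  set.seed(32)
  s <- simulate_lick_train(lick_train_params(), duration = 4000)
  model <- error_model()
  sn <- corrupt_events(s, model)
  pose <- simulate_pose_track(s)
  m <- match_events(segment_video_licks(pose), sn$events)
  # matching agrees with generator provenance
  expect_equal(sum(m$events$label == "TP"), sum(sn$lick_status$detected))
  expect_equal(sum(!m$licks$matched), sum(!sn$lick_status$detected))
  met <- detection_metrics(m)
  # recall is governed by the kind-mixture of miss rates
  p_fn <- model$p_fn_short * (27 / 230) + model$p_fn_sipper * (203 / 230)
  expect_equal(met$recall, 1 - p_fn, tolerance = 0.05)
})

test_that("filtering removes false positives only, mirroring the validation claim", {
  set.seed(33)
  s <- simulate_lick_train(lick_train_params(), duration = 1800)
  sn <- corrupt_events(s, error_model())
  f <- apply_posthoc_filter(sn$events, filter_config())
  expect_true(all(f$removed$source != "true"))
  expect_lt(sum(f$events$source != "true"), sum(sn$events$source != "true"))
  expect_equal(sum(f$events$source == "true"),
               sum(sn$events$source == "true"))
})
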