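# Synthetic-data generators. These emulate the statistical structure the
# downstream analyses assume: bout-structured lick trains with within-bout
# ILIs near 0.146 s, a bout-triggered reward schedule gated by a truncated
# exponential ITI, a beam-break sensor with kind-dependent misses and two
# false-positive processes, a 60 Hz pose track, and a two-channel
# photometry trace. All randomness goes through R's global RNG, so
# `set.seed()` fixes every output bit-for-bit.

# Guard (seconds) kept between a lick offset and the next lick onset.
LICK_GAP_GUARD <- 0.04

new_lick_session <- function(licks, bouts, reward_times, duration, params) {
  structure(list(
    licks = licks, bouts = bouts, reward_times = reward_times,
    duration = duration, params = params
  ), class = "lick_session")
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf(
    "<lick_session> %d licks in %d bouts over %.1f s; %s rewards\n",
    nrow(x$licks), nrow(x$bouts), x$duration,
    if (is.null(x$reward_times)) "no" else length(x$reward_times)
  ))
  invisible(x)
}

#' Sample truncated-exponential intertrial intervals
#'
#' Draws from an exponential distribution with mean `config$iti_mean`,
#' conditioned on the interval `[iti_min, iti_max]` (the conditional law,
#' not a clamp, so no mass piles up at the bounds). Sampling uses inversion
#' of the truncated CDF, which is draw-count deterministic and equivalent
#' in law to rejection sampling. With the default mean 18 s on [2, 30] s
#' the resulting mean is about 12.51 s.
#'
#' @param n Number of draws.
#' @param config A [task_config()].
#' @return Numeric vector of `n` ITIs in seconds.
#' @examples
#' set.seed(1)
#' mean(sample_iti(1000, task_config()))
#' @export
sample_iti <- function(n, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  a <- config$iti_min
  b <- config$iti_max
  if (b <= a) return(rep.int(a, n))
  lambda <- 1 / config$iti_mean
  z <- 1 - exp(-lambda * (b - a))
  a - log(1 - runif(n) * z) / lambda
}

# Mean of the exponential(mean = 1/lambda) conditioned on [a, b].
truncated_exp_mean <- function(iti_mean, iti_min, iti_max) {
  lambda <- 1 / iti_mean
  d <- iti_max - iti_min
  if (d <= 0) return(iti_min)
  iti_min + 1 / lambda - d * exp(-lambda * d) / (1 - exp(-lambda * d))
}

# CDF of the truncated exponential, used by distributional tests.
truncated_exp_cdf <- function(q, iti_mean, iti_min, iti_max) {
  lambda <- 1 / iti_mean
  p <- (1 - exp(-lambda * (pmax(pmin(q, iti_max), iti_min) - iti_min))) /
    (1 - exp(-lambda * (iti_max - iti_min)))
  ifelse(q < iti_min, 0, ifelse(q > iti_max, 1, p))
}

draw_snout_durations <- function(n, spec) {
  pmin(rlnorm(n, spec$meanlog, spec$sdlog), spec$max)
}

# Build one bout of n licks starting at `start`; returns tibble rows.
build_bout <- function(start, n_licks, params) {
  ilis <- if (n_licks > 1) {
    rnorm_trunc(n_licks - 1, params$ili_mean, params$ili_sd,
                params$ili_floor, params$ili_ceiling)
  } else {
    numeric(0)
  }
  onsets <- start + cumsum(c(0, ilis))
  durs <- rnorm_trunc(n_licks, params$lick_duration_mean,
                      params$lick_duration_sd,
                      params$lick_duration_min, params$lick_duration_max)
  if (n_licks > 1) {
    # keep a guard gap before the next lick so lick intervals never overlap
    cap <- pmax(ilis - LICK_GAP_GUARD, 0.5 * ilis)
    durs[-n_licks] <- pmin(durs[-n_licks], cap)
  }
  list(onset = onsets, offset = onsets + durs)
}

#' Simulate a ground-truth lick train
#'
#' Bout onsets follow exponential gaps at `params$bout_rate`, with a hard
#' refractory gap of `params$bout_refractory` seconds after the previous
#' bout's last lick offset, so that onset-to-onset gaps across bouts always
#' exceed the 0.5 s bout-break threshold and bout segmentation recovers the
#' generated labels exactly. Within-bout ILIs are truncated-normal; each
#' lick is independently marked `"short"` with probability `params$p_short`.
#'
#' @param params A [lick_train_params()].
#' @param duration Session length in seconds; licks extending past it are
#'   dropped. Ignored when `n_bouts` is given.
#' @param n_bouts Optional: generate exactly this many bouts instead of
#'   filling a fixed duration.
#' @return A `lick_session` with `$licks` (tibble: onset, offset, kind,
#'   bout), `$bouts`, `$duration`, and no rewards.
#' @examples
#' set.seed(1)
#' simulate_lick_train(lick_train_params(), duration = 120)
#' @export
simulate_lick_train <- function(params = lick_train_params(),
                                duration = 1800, n_bouts = NULL) {
  stopifnot(inherits(params, "lick_train_params"))
  if (is.null(n_bouts)) {
    check_number(duration, "duration", lower = 0)
  }
  onset <- list(); offset <- list(); bout_id <- list()
  b <- 0L
  t_next <- rexp(1, params$bout_rate)
  repeat {
    if (is.null(n_bouts)) {
      if (t_next > duration) break
    } else {
      if (b >= n_bouts) break
    }
    b <- b + 1L
    n_licks <- draw_counts(1L, params$licks_per_bout)
    bout <- build_bout(t_next, n_licks, params)
    if (is.null(n_bouts)) {
      keep <- bout$offset <= duration
      bout$onset <- bout$onset[keep]
      bout$offset <- bout$offset[keep]
      if (length(bout$onset) == 0L) {
        b <- b - 1L
        break
      }
    }
    onset[[b]] <- bout$onset
    offset[[b]] <- bout$offset
    bout_id[[b]] <- rep.int(b, length(bout$onset))
    t_next <- max(bout$offset) + params$bout_refractory +
      rexp(1, params$bout_rate)
  }
  onset <- unlist(onset) %||% numeric(0)
  offset <- unlist(offset) %||% numeric(0)
  bout_id <- unlist(bout_id) %||% integer(0)
  kind <- ifelse(runif(length(onset)) < params$p_short, "short", "sipper")
  licks <- tibble::tibble(
    onset = onset, offset = offset,
    kind = as.character(kind), bout = bout_id
  )
  if (is.null(n_bouts)) {
    dur_out <- duration
  } else {
    dur_out <- if (nrow(licks)) max(licks$offset) + params$bout_refractory else 0
  }
  new_lick_session(licks, bout_table(licks), NULL, dur_out, params)
}

bout_table <- function(licks) {
  if (nrow(licks) == 0L) {
    return(tibble::tibble(
      bout = integer(0), first = integer(0), last = integer(0),
      start = numeric(0), end = numeric(0), n_licks = integer(0)
    ))
  }
  idx <- seq_len(nrow(licks))
  split_idx <- split(idx, licks$bout)
  tibble::tibble(
    bout = as.integer(names(split_idx)),
    first = unname(vapply(split_idx, min, integer(1))),
    last = unname(vapply(split_idx, max, integer(1))),
    start = licks$onset[unname(vapply(split_idx, min, integer(1)))],
    end = licks$offset[unname(vapply(split_idx, max, integer(1)))],
    n_licks = unname(lengths(split_idx))
  )
}

#' Simulate a full reward-task session
#'
#' Runs the reward state machine over a simulated lick train: after each
#' reward an ITI is drawn; the next bout-initiating lick at or after the
#' availability time triggers a reward, and bouts starting earlier go
#' unrewarded. The first availability time is an ITI drawn from session
#' start.
#'
#' @param task A [task_config()].
#' @param params A [lick_train_params()].
#' @return A `lick_session` whose `$reward_times` are exactly the onsets of
#'   the rewarded bouts' first licks, and whose `$bouts` carry a `rewarded`
#'   flag.
#' @examples
#' set.seed(1)
#' simulate_task_session(task_config(session_duration = 300))
#' @export
simulate_task_session <- function(task = task_config(),
                                  params = lick_train_params()) {
  stopifnot(inherits(task, "task_config"))
  session <- simulate_lick_train(params, duration = task$session_duration)
  bouts <- session$bouts
  rewarded <- logical(nrow(bouts))
  reward_times <- numeric(0)
  avail <- sample_iti(1, task)
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      t1 <- bouts$start[i]
      if (t1 >= avail) {
        rewarded[i] <- TRUE
        reward_times <- c(reward_times, t1)
        avail <- t1 + sample_iti(1, task)
      }
    }
  }
  bouts$rewarded <- rewarded
  session$bouts <- bouts
  session$reward_times <- reward_times
  session$task <- task
  session
}

#' Corrupt a ground-truth session into a sensor event stream
#'
#' Applies the sensor error model: short licks are dropped with
#' `p_fn_short`, sipper licks with `p_fn_sipper`; each surviving lick emits
#' one beam-break event inside the central half of the lick interval (the
#' beam sits at sipper depth, so the crossing happens mid-protrusion);
#' detected licks spawn a double-detection false positive with `p_double`
#' (onset gap < 50 ms); snout artifacts arrive at `p_snout` events per
#' second, placed in lick-free time with a buffer so their provenance is
#' unambiguous.
#'
#' @param session A `lick_session`.
#' @param model An [error_model()].
#' @return A `sensor_sim` list: `$events`, a sorted tibble with columns
#'   `channel`, `onset`, `offset`, `source` (`true`, `double_fp`,
#'   `snout_fp`) and `truth_lick`; and `$lick_status`, one row per
#'   ground-truth lick with its `detected` flag.
#' @examples
#' set.seed(1)
#' sim <- simulate_task_session(task_config(session_duration = 120))
#' corrupt_events(sim, error_model())
#' @export
corrupt_events <- function(session, model = error_model()) {
  stopifnot(inherits(session, "lick_session"), inherits(model, "error_model"))
  licks <- session$licks
  n <- nrow(licks)
  p_fn <- ifelse(licks$kind == "short", model$p_fn_short, model$p_fn_sipper)
  detected <- if (n) runif(n) >= p_fn else logical(0)

  dur <- licks$offset - licks$onset
  ev_on <- licks$onset + 0.25 * dur
  ev_off <- licks$onset + 0.75 * dur
  true_ev <- tibble::tibble(
    onset = ev_on[detected], offset = ev_off[detected],
    source = "true", truth_lick = which(detected)
  )

  is_double <- runif(nrow(true_ev)) < model$p_double
  dbl_on <- true_ev$onset[is_double] +
    runif(sum(is_double), model$double_gap[1], model$double_gap[2])
  dbl_off <- dbl_on +
    runif(sum(is_double), model$double_duration[1], model$double_duration[2])
  dbl_ev <- tibble::tibble(
    onset = dbl_on, offset = dbl_off,
    source = "double_fp", truth_lick = true_ev$truth_lick[is_double]
  )

  n_snout <- rpois(1, model$p_snout * session$duration)
  snout_ev <- place_snout_events(n_snout, session, model)

  events <- dplyr::bind_rows(true_ev, dbl_ev, snout_ev)
  events <- events[order(events$onset), , drop = FALSE]
  if (nrow(events) > 1L) {
    # clip any event that would run into its successor (doubles can)
    cap <- c(events$onset[-1] - 1e-3, Inf)
    events$offset <- pmin(events$offset, cap)
  }
  events <- dplyr::mutate(events, channel = "lick", .before = 1)
  structure(list(
    events = events,
    lick_status = tibble::tibble(
      lick = seq_len(n), kind = licks$kind, bout = licks$bout,
      detected = detected
    ),
    model = model
  ), class = "sensor_sim")
}

place_snout_events <- function(n_snout, session, model) {
  if (n_snout == 0L) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0),
                          source = character(0), truth_lick = integer(0)))
  }
  durs <- draw_snout_durations(n_snout, model$snout_duration)
  buf <- model$snout_buffer
  lick_on <- session$licks$onset
  lick_off <- session$licks$offset
  placed_on <- numeric(0); placed_off <- numeric(0)
  for (d in durs) {
    for (try in seq_len(100L)) {
      s <- runif(1, 0, max(session$duration - d, 0))
      e <- s + d
      clash_lick <- any(lick_on < e + buf & lick_off > s - buf)
      clash_snout <- length(placed_on) &&
        any(placed_on < e + buf & placed_off > s - buf)
      if (!clash_lick && !clash_snout) {
        placed_on <- c(placed_on, s); placed_off <- c(placed_off, e)
        break
      }
    }
  }
  tibble::tibble(
    onset = placed_on, offset = placed_off,
    source = rep("snout_fp", length(placed_on)),
    truth_lick = rep(NA_integer_, length(placed_on))
  )
}

# Event kernel: (1 - exp(-t/rise)) * exp(-t/decay) on the sample grid,
# rescaled so its grid maximum equals `amp` exactly.
event_kernel <- function(amp, rise, decay, rate) {
  t_max <- rise + 10 * decay
  tt <- seq(0, t_max, by = 1 / rate)
  k <- (1 - exp(-tt / rise)) * exp(-tt / decay)
  k * (amp / max(k))
}

#' Simulate a two-channel photometry trace
#'
#' @param session A `lick_session` with reward annotations (from
#'   [simulate_task_session()]).
#' @param cfg A [photo_sim_config()].
#' @return A tibble with columns `time_s`, `ch470`, `ch415`, uniformly
#'   sampled at `cfg$rate`.
#' @examples
#' set.seed(1)
#' sim <- simulate_task_session(task_config(session_duration = 120))
#' simulate_photometry(sim, photo_sim_config())
#' @export
simulate_photometry <- function(session, cfg = photo_sim_config()) {
  stopifnot(inherits(session, "lick_session"), inherits(cfg, "photo_sim_config"))
  if (is.null(session$reward_times)) {
    abort("`session` must carry reward annotations; use simulate_task_session().")
  }
  n <- floor(session$duration * cfg$rate) + 1L
  tt <- (seq_len(n) - 1L) / cfg$rate
  bleach <- rowSums(vapply(
    seq_along(cfg$bleach_amp),
    function(i) cfg$bleach_amp[i] * exp(-tt / cfg$bleach_tau[i]),
    numeric(n)
  ))
  artifact <- if (cfg$artifact_amp > 0) {
    cfg$artifact_amp * sin(2 * pi * tt / cfg$artifact_period)
  } else {
    numeric(n)
  }
  sig <- numeric(n)
  add_kernels <- function(sig, times, kern) {
    for (t0 in times) {
      i0 <- round(t0 * cfg$rate) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, n)
      if (i0 <= n) sig[idx] <- sig[idx] + kern[seq_along(idx)]
    }
    sig
  }
  rewarded_first <- session$reward_times
  unrewarded_first <- session$bouts$start[!session$bouts$rewarded]
  if (cfg$transient_amp > 0 && length(rewarded_first)) {
    sig <- add_kernels(sig, rewarded_first,
                       event_kernel(cfg$transient_amp, cfg$transient_rise,
                                    cfg$transient_decay, cfg$rate))
  }
  if (cfg$dip_amp < 0 && length(unrewarded_first)) {
    sig <- add_kernels(sig, unrewarded_first,
                       event_kernel(1, cfg$dip_rise, cfg$dip_decay,
                                    cfg$rate) * cfg$dip_amp)
  }
  ch470 <- cfg$baseline_470 + bleach + artifact + sig +
    rnorm(n, 0, cfg$noise_sd)
  ch415 <- cfg$baseline_415 + cfg$iso_scale * bleach + artifact +
    rnorm(n, 0, cfg$noise_sd)
  tibble::tibble(time_s = tt, ch470 = ch470, ch415 = ch415)
}

#' Simulate a pose-tracking table for a session
#'
#' Synthesises a 60 Hz tongue-tip/nose pose track consistent with a
#' ground-truth lick train: during each lick the tongue-tip displacement
#' follows a trapezoidal excursion (10% rise and fall ramps) whose peak
#' falls between the poke line and the sipper line for short licks and
#' beyond the sipper line for sipper licks; outside licks the tongue is
#' invisible (low likelihood, noisy coordinates).
#'
#' @param session A `lick_session`.
#' @param frame_rate Frames per second, default 60.
#' @param short_peak,sipper_peak Uniform ranges (px) for peak displacement
#'   by lick kind; defaults bracket the [segmentation_config()] defaults.
#' @return A tibble with columns `frame`, `time_s`, `bodypart`, `x`, `y`,
#'   `likelihood`.
#' @export
simulate_pose_track <- function(session, frame_rate = 60,
                                short_peak = c(32, 45),
                                sipper_peak = c(55, 70)) {
  stopifnot(inherits(session, "lick_session"))
  n_frames <- floor(session$duration * frame_rate) + 1L
  frame <- seq_len(n_frames) - 1L
  tt <- frame / frame_rate
  licks <- session$licks
  y <- abs(rnorm(n_frames, 0, 1))
  lik <- runif(n_frames, 0.01, 0.2)
  if (nrow(licks)) {
    peaks <- ifelse(licks$kind == "short",
                    runif(nrow(licks), short_peak[1], short_peak[2]),
                    runif(nrow(licks), sipper_peak[1], sipper_peak[2]))
    hit <- findInterval(tt, licks$onset)
    inside <- hit > 0 & tt <= licks$offset[pmax(hit, 1L)]
    idx <- which(inside)
    li <- hit[idx]
    u <- (tt[idx] - licks$onset[li]) / (licks$offset[li] - licks$onset[li])
    g <- pmin(1, pmin(u, 1 - u) / 0.1)
    y[idx] <- peaks[li] * g
    lik[idx] <- runif(length(idx), 0.95, 1)
  }
  tongue <- tibble::tibble(
    frame = frame, time_s = tt, bodypart = "tongue_tip",
    x = rnorm(n_frames, 0, 1), y = y, likelihood = lik
  )
  nose <- tibble::tibble(
    frame = frame, time_s = tt, bodypart = "nose",
    x = rnorm(n_frames, 0, 1), y = rnorm(n_frames, 5, 0.5),
    likelihood = runif(n_frames, 0.95, 1)
  )
  dplyr::bind_rows(tongue, nose)
}
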