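# Configuration constructors. Each constructor validates its invariants so
# that every downstream stage can assume a well-formed configuration.

#' Behavioural task configuration
#'
#' Parameters of the bout-triggered reward task: a reward becomes available
#' after an intertrial interval (ITI) drawn from an exponential distribution
#' with mean `iti_mean`, conditioned on lying inside `[iti_min, iti_max]`.
#' The reward is delivered at the first lick of the first bout that starts
#' at or after the availability time.
#'
#' @param iti_mean Mean (seconds) of the untruncated exponential ITI.
#' @param iti_min,iti_max Truncation bounds (seconds) for the ITI.
#' @param reward_volume Reward volume in microliters (metadata only).
#' @param session_duration Session length in seconds.
#' @return A `task_config` object.
#' @examples
#' task_config()
#' @export
task_config <- function(iti_mean = 18, iti_min = 2, iti_max = 30,
                        reward_volume = 5, session_duration = 1800) {
  check_number(iti_mean, "iti_mean", lower = 0, strict_lower = TRUE)
  check_number(iti_min, "iti_min", lower = 0, strict_lower = TRUE)
  check_number(iti_max, "iti_max", lower = iti_min)
  check_number(reward_volume, "reward_volume", lower = 0)
  check_number(session_duration, "session_duration", lower = 0,
               strict_lower = TRUE)
  new_config(list(
    iti_mean = iti_mean, iti_min = iti_min, iti_max = iti_max,
    reward_volume = reward_volume, session_duration = session_duration
  ), "task_config")
}

#' Lick-train generator parameters
#'
#' Controls the simulated ground-truth lick trains. Licks are organised in
#' bouts; bout onsets follow a homogeneous Poisson process with a hard
#' refractory gap (`bout_refractory`) appended after the previous bout ends,
#' so that analysis-side bout segmentation at the same threshold recovers
#' the generated bout labels exactly. Within-bout interlick intervals (ILIs)
#' are truncated-normal around the rodent licking rhythm (~0.146 s).
#'
#' Lick durations are truncated-normal inside
#' `[lick_duration_min, lick_duration_max]`. The default lower bound (20 ms)
#' keeps every simulated protrusion longer than one 60 Hz video frame, so a
#' video-based segmentation of the simulated pose track sees every lick; it
#' also keeps clean licks strictly inside the post hoc filter's keep-window.
#'
#' @param bout_rate Rate (bouts/second) of the exponential inter-bout gaps.
#' @param licks_per_bout Count-distribution spec, e.g.
#'   `list(name = "geometric", mean = 15)` or `list(name = "fixed", size = 10)`.
#' @param ili_mean,ili_sd Mean and sd (seconds) of the within-bout ILI.
#' @param ili_floor Lower truncation (seconds) of the ILI distribution.
#' @param ili_ceiling Upper truncation (seconds) of the ILI distribution;
#'   must stay below the bout-break threshold used for segmentation.
#' @param lick_duration_mean,lick_duration_sd Duration distribution (seconds).
#' @param lick_duration_min,lick_duration_max Duration truncation (seconds).
#' @param p_short Probability a lick is a "short" lick (fails to reach the
#'   sipper); defaults to the observed fraction 27/230.
#' @param bout_refractory Minimum gap (seconds) from one bout's last lick
#'   offset to the next bout's onset, beyond the exponential draw.
#' @return A `lick_train_params` object.
#' @export
lick_train_params <- function(bout_rate = 0.05,
                              licks_per_bout = list(name = "geometric",
                                                    mean = 15),
                              ili_mean = 0.146, ili_sd = 0.015,
                              ili_floor = 0.05, ili_ceiling = 0.45,
                              lick_duration_mean = 0.06,
                              lick_duration_sd = 0.02,
                              lick_duration_min = 0.02,
                              lick_duration_max = 0.2,
                              p_short = 27 / 230,
                              bout_refractory = 0.55) {
  check_number(bout_rate, "bout_rate", lower = 0, strict_lower = TRUE)
  validate_count_spec(licks_per_bout, "licks_per_bout")
  check_number(ili_floor, "ili_floor", lower = 0, strict_lower = TRUE)
  check_number(ili_mean, "ili_mean", lower = ili_floor, strict_lower = TRUE)
  check_number(ili_sd, "ili_sd", lower = 0, strict_lower = TRUE)
  check_number(ili_ceiling, "ili_ceiling", lower = ili_mean,
               strict_lower = TRUE)
  check_number(lick_duration_min, "lick_duration_min", lower = 0,
               strict_lower = TRUE)
  check_number(lick_duration_max, "lick_duration_max",
               lower = lick_duration_min, strict_lower = TRUE)
  check_number(lick_duration_mean, "lick_duration_mean", lower = 0,
               strict_lower = TRUE)
  check_number(lick_duration_sd, "lick_duration_sd", lower = 0,
               strict_lower = TRUE)
  check_probability(p_short, "p_short")
  check_number(bout_refractory, "bout_refractory", lower = 0,
               strict_lower = TRUE)
  new_config(list(
    bout_rate = bout_rate, licks_per_bout = licks_per_bout,
    ili_mean = ili_mean, ili_sd = ili_sd, ili_floor = ili_floor,
    ili_ceiling = ili_ceiling,
    lick_duration_mean = lick_duration_mean,
    lick_duration_sd = lick_duration_sd,
    lick_duration_min = lick_duration_min,
    lick_duration_max = lick_duration_max,
    p_short = p_short, bout_refractory = bout_refractory
  ), "lick_train_params")
}

#' Sensor error model
#'
#' Describes how the simulated beam-break sensor corrupts a ground-truth
#' lick train: short licks are missed with probability `p_fn_short` (10/27
#' observed), sipper licks with `p_fn_sipper` (4/203 observed); surviving
#' licks may trigger a double detection (an extra event starting less than
#' 50 ms after the true event); snout artifacts are long beam breaks placed
#' in lick-free time.
#'
#' @param p_fn_short,p_fn_sipper Miss probabilities per lick kind.
#' @param p_double Probability of a double-detection false positive per
#'   detected lick.
#' @param double_gap Length-2 numeric: uniform range (seconds) of the
#'   onset-to-onset gap of a double detection; support must lie in (0, 0.05).
#' @param double_duration Length-2 numeric: uniform range (seconds) of the
#'   double event duration.
#' @param p_snout Rate (events/second of session time) of snout artifacts.
#' @param snout_duration Spec for snout artifact durations:
#'   `list(name = "lognormal", meanlog, sdlog, max)`; most mass lies above
#'   the 0.2 s duration cutoff of true licks.
#' @param snout_buffer Minimum gap (seconds) between a snout artifact and any
#'   true lick interval or other snout artifact, so artifact provenance stays
#'   unambiguous when scoring.
#' @return An `error_model` object.
#' @export
error_model <- function(p_fn_short = 10 / 27, p_fn_sipper = 4 / 203,
                        p_double = 0.05,
                        double_gap = c(0.005, 0.045),
                        double_duration = c(0.005, 0.03),
                        p_snout = 0.048,
                        snout_duration = list(name = "lognormal",
                                              meanlog = log(0.3),
                                              sdlog = 0.6, max = 2),
                        snout_buffer = 0.25) {
  check_probability(p_fn_short, "p_fn_short")
  check_probability(p_fn_sipper, "p_fn_sipper")
  check_probability(p_double, "p_double")
  if (!is.numeric(double_gap) || length(double_gap) != 2L ||
      double_gap[1] <= 0 || double_gap[2] >= 0.05 ||
      double_gap[1] > double_gap[2]) {
    abort("`double_gap` must be an increasing pair inside (0, 0.05).")
  }
  if (!is.numeric(double_duration) || length(double_duration) != 2L ||
      double_duration[1] <= 0 || double_duration[1] > double_duration[2]) {
    abort("`double_duration` must be an increasing positive pair.")
  }
  check_number(p_snout, "p_snout", lower = 0)
  if (!is.list(snout_duration) || !identical(snout_duration$name, "lognormal")) {
    abort("`snout_duration` must be list(name = \"lognormal\", meanlog, sdlog, max).")
  }
  check_number(snout_duration$meanlog, "snout_duration$meanlog")
  check_number(snout_duration$sdlog, "snout_duration$sdlog", lower = 0)
  check_number(snout_duration$max, "snout_duration$max", lower = 0,
               strict_lower = TRUE)
  check_number(snout_buffer, "snout_buffer", lower = 0, strict_lower = TRUE)
  new_config(list(
    p_fn_short = p_fn_short, p_fn_sipper = p_fn_sipper,
    p_double = p_double, double_gap = double_gap,
    double_duration = double_duration,
    p_snout = p_snout, snout_duration = snout_duration,
    snout_buffer = snout_buffer
  ), "error_model")
}

#' Post hoc artifact filter configuration
#'
#' Keep-criteria for sensor events: duration inside `[dur_min, dur_max]`
#' and onset-to-onset interlick interval (measured against the previous
#' *kept* event) strictly greater than `ili_min`.
#'
#' @param dur_min,dur_max Duration keep-window (seconds), default 3-200 ms.
#' @param ili_min ILI guard (seconds), default 50 ms.
#' @return A `filter_config` object.
#' @export
filter_config <- function(dur_min = 0.003, dur_max = 0.2, ili_min = 0.05) {
  check_number(dur_min, "dur_min", lower = 0, strict_lower = TRUE)
  check_number(dur_max, "dur_max", lower = dur_min, strict_lower = TRUE)
  check_number(ili_min, "ili_min", lower = 0, strict_lower = TRUE)
  new_config(list(dur_min = dur_min, dur_max = dur_max, ili_min = ili_min),
             "filter_config")
}

#' Video lick segmentation configuration
#'
#' Thresholds for turning a tongue-tip pose track into video-defined licks.
#' A lick is a maximal run of frames whose tracking likelihood is at least
#' `likelihood_min` and whose protrusion displacement exceeds `poke_line`,
#' tolerating up to `max_gap_frames` sub-threshold frames inside the run.
#' A lick reaches the sipper (kind `"sipper"`) when its peak displacement
#' is at least `sipper_line`. `pad_frames` widens each lick by that many
#' frame periods on each side to compensate for frame-sampling quantisation
#' of the true protrusion interval.
#'
#' @param likelihood_min Minimum tracking likelihood, default 0.9.
#' @param poke_line Displacement (px) beyond which the tongue counts as
#'   protruded.
#' @param sipper_line Displacement (px) at which the tongue reaches the
#'   sipper; must exceed `poke_line`.
#' @param max_gap_frames Frames of tolerated dropout inside a lick.
#' @param pad_frames Frame periods of padding on each side of a lick.
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(likelihood_min = 0.9, poke_line = 20,
                                sipper_line = 50, max_gap_frames = 1,
                                pad_frames = 1) {
  check_probability(likelihood_min, "likelihood_min")
  check_number(poke_line, "poke_line")
  check_number(sipper_line, "sipper_line", lower = poke_line,
               strict_lower = TRUE)
  check_number(max_gap_frames, "max_gap_frames", lower = 0)
  check_number(pad_frames, "pad_frames", lower = 0)
  new_config(list(
    likelihood_min = likelihood_min, poke_line = poke_line,
    sipper_line = sipper_line, max_gap_frames = as.integer(max_gap_frames),
    pad_frames = pad_frames
  ), "segmentation_config")
}

#' Lick-microstructure analysis configuration
#'
#' @param ili_max Analysis ceiling (seconds) for ILI histograms and the modal
#'   ILI; within-bout analysis focuses on ILIs below 0.5 s.
#' @param primary_lo,primary_hi Window (seconds) of the "primary ILI", the
#'   mean ILI inside 0.05-0.25 s.
#' @param hist_bin Histogram bin width (seconds).
#' @return A `microstructure_config` object.
#' @export
microstructure_config <- function(ili_max = 0.5, primary_lo = 0.05,
                                  primary_hi = 0.25, hist_bin = 0.01) {
  check_number(primary_lo, "primary_lo", lower = 0, strict_lower = TRUE)
  check_number(primary_hi, "primary_hi", lower = primary_lo,
               strict_lower = TRUE)
  check_number(ili_max, "ili_max", lower = primary_hi)
  check_number(hist_bin, "hist_bin", lower = 0, strict_lower = TRUE)
  new_config(list(
    ili_max = ili_max, primary_lo = primary_lo, primary_hi = primary_hi,
    hist_bin = hist_bin
  ), "microstructure_config")
}

#' Photometry detrending configuration
#'
#' Parameters of the robust locally weighted regression (LOWESS) used to
#' estimate and remove slow photobleaching from each fluorescence channel.
#'
#' @param lowess_frac Fraction of samples in each local fit (default 0.1).
#' @param lowess_it Robustifying iterations with bisquare weights (default 3).
#' @param lowess_delta Interpolation distance in sample-index units
#'   (default 20, i.e. 0.4 s at 50 Hz).
#' @return A `photometry_config` object.
#' @export
photometry_config <- function(lowess_frac = 0.1, lowess_it = 3,
                              lowess_delta = 20) {
  check_number(lowess_frac, "lowess_frac", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(lowess_it, "lowess_it", lower = 0)
  check_number(lowess_delta, "lowess_delta", lower = 0)
  new_config(list(
    lowess_frac = lowess_frac, lowess_it = as.integer(lowess_it),
    lowess_delta = lowess_delta
  ), "photometry_config")
}

#' Peri-event time histogram configuration
#'
#' The window spans `window_pre` seconds before to `window_post` seconds
#' after each event; at a 50 Hz acquisition rate the default -1.5 s to
#' +3.0 s window gives 226 timepoints.
#'
#' @param window_pre,window_post Window extent (seconds) around each event.
#' @param baseline Optional length-2 numeric: a relative-time interval whose
#'   per-trial mean is subtracted from that trial, or `NULL` for none.
#' @return A `peth_config` object.
#' @export
peth_config <- function(window_pre = 1.5, window_post = 3.0,
                        baseline = NULL) {
  check_number(window_pre, "window_pre", lower = 0)
  check_number(window_post, "window_post", lower = 0)
  if (window_pre + window_post <= 0) {
    abort("PETH window must have positive extent.")
  }
  if (!is.null(baseline)) {
    if (!is.numeric(baseline) || length(baseline) != 2L ||
        baseline[1] >= baseline[2]) {
      abort("`baseline` must be an increasing pair of relative times.")
    }
    if (baseline[1] < -window_pre || baseline[2] > window_post) {
      abort("`baseline` must lie inside the PETH window.")
    }
  }
  new_config(list(
    window_pre = window_pre, window_post = window_post, baseline = baseline
  ), "peth_config")
}

#' Photometry simulation configuration
#'
#' Generates a two-channel fluorescence recording: the signal channel
#' (470 nm) carries a two-exponential photobleaching decay, positive
#' transients at rewarded first licks, negative deflections at unrewarded
#' first licks, a slow common-mode artifact, and white noise. The isosbestic
#' channel (415 nm) shares the bleaching (scaled by `iso_scale`) and the
#' artifact but carries no lick-locked kernel.
#'
#' Transient/dip kernels are `(1 - exp(-t/rise)) * exp(-t/decay)` shapes
#' rescaled so their maximum on the sample grid equals the configured
#' amplitude exactly, which makes amplitude-recovery checks sharp.
#'
#' @param rate Sampling rate (Hz) per channel.
#' @param baseline_470,baseline_415 Constant offsets (a.u.).
#' @param bleach_amp,bleach_tau Two-exponential bleach amplitudes (a.u.) and
#'   time constants (seconds).
#' @param iso_scale Coupling of the bleach into the isosbestic channel.
#' @param noise_sd White-noise sd (a.u.) per channel.
#' @param transient_amp,transient_rise,transient_decay Rewarded-lick kernel:
#'   peak amplitude (a.u., > 0) and rise/decay constants (seconds).
#' @param dip_amp,dip_rise,dip_decay Unrewarded-lick kernel; `dip_amp` < 0.
#' @param artifact_amp,artifact_period Amplitude (a.u.) and period (seconds)
#'   of the sinusoidal common-mode artifact shared by both channels.
#' @return A `photo_sim_config` object.
#' @export
photo_sim_config <- function(rate = 50,
                             baseline_470 = 10, baseline_415 = 8,
                             bleach_amp = c(2, 1),
                             bleach_tau = c(60, 600),
                             iso_scale = 0.8, noise_sd = 0.05,
                             transient_amp = 1, transient_rise = 0.05,
                             transient_decay = 0.2,
                             dip_amp = -0.5, dip_rise = 0.05,
                             dip_decay = 0.2,
                             artifact_amp = 0.3, artifact_period = 120) {
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(baseline_470, "baseline_470")
  check_number(baseline_415, "baseline_415")
  if (!is.numeric(bleach_amp) || !is.numeric(bleach_tau) ||
      length(bleach_amp) != length(bleach_tau)) {
    abort("`bleach_amp` and `bleach_tau` must be numeric vectors of equal length.")
  }
  if (any(bleach_tau <= 0)) abort("`bleach_tau` values must be positive.")
  check_number(iso_scale, "iso_scale")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(transient_amp, "transient_amp", lower = 0)
  check_number(transient_rise, "transient_rise", lower = 0,
               strict_lower = TRUE)
  check_number(transient_decay, "transient_decay", lower = 0,
               strict_lower = TRUE)
  check_number(dip_amp, "dip_amp", upper = 0)
  check_number(dip_rise, "dip_rise", lower = 0, strict_lower = TRUE)
  check_number(dip_decay, "dip_decay", lower = 0, strict_lower = TRUE)
  check_number(artifact_amp, "artifact_amp", lower = 0)
  check_number(artifact_period, "artifact_period", lower = 0,
               strict_lower = TRUE)
  new_config(list(
    rate = rate, baseline_470 = baseline_470, baseline_415 = baseline_415,
    bleach_amp = bleach_amp, bleach_tau = bleach_tau,
    iso_scale = iso_scale, noise_sd = noise_sd,
    transient_amp = transient_amp, transient_rise = transient_rise,
    transient_decay = transient_decay,
    dip_amp = dip_amp, dip_rise = dip_rise, dip_decay = dip_decay,
    artifact_amp = artifact_amp, artifact_period = artifact_period
  ), "photo_sim_config")
}
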