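# Small builders shared across test files.

# Event stream from onsets and a common (or per-event) duration.
make_events <- function(onsets, duration = 0.05, channel = "lick") {
  tibble::tibble(channel = channel, onset = onsets,
                 offset = onsets + duration)
}

# Pose track tracing an explicit tongue-tip y trajectory at 60 Hz.
make_tongue_track <- function(y, likelihood = 0.99, frame_rate = 60) {
  n <- length(y)
  tibble::tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / frame_rate,
    bodypart = "tongue_tip",
    x = 0, y = y,
    likelihood = rep_len(likelihood, n)
  )
}

# The clean 300-point detrending fixture: a slow photobleaching-like
# exponential decay carrying one sharp transient.
bleach_spike_fixture <- function(n = 300, tau = 15000, noise_sd = 0,
                                 spike_at = 150) {
  y <- exp(-seq_len(n) / tau)
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  y[spike_at + (-1:1)] <- y[spike_at + (-1:1)] + c(0.3, 0.5, 0.3)
  y
}
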