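# Lick microstructure: interlick intervals, bout segmentation, modal and
# primary ILI, histograms, session summaries, and cross-session
# correlation.

#' Interlick intervals of an event stream
#'
#' Successive onset-to-onset differences of the lick-channel events
#' (offset-to-onset pauses are available behind `from = "offset"`).
#'
#' @param events An event stream tibble.
#' @param from `"onset"` (default, the standard ILI) or `"offset"`.
#' @return A numeric vector of length `n_licks - 1` (empty below 2 licks).
#' @examples
#' ev <- tibble::tibble(channel = "lick", onset = c(0, 0.15, 0.30),
#'                      offset = c(0, 0.15, 0.30) + 0.05)
#' interlick_intervals(ev)
#' @export
interlick_intervals <- function(events, from = c("onset", "offset")) {
  from <- match.arg(from)
  if ("channel" %in% names(events)) {
    events <- events[events$channel == "lick", , drop = FALSE]
  }
  if (nrow(events) < 2L) return(numeric(0))
  onsets <- sort(events$onset)
  if (from == "onset") {
    diff(onsets)
  } else {
    ord <- order(events$onset)
    events$onset[ord][-1] - events$offset[ord][-nrow(events)]
  }
}

#' Segment an event stream into lick bouts
#'
#' Greedy left-to-right partition: an onset-to-onset ILI of at least
#' `bout_break` seconds starts a new bout. The threshold defaults to
#' 0.5 s, consistent with treating ILIs below 0.5 s as within-bout.
#'
#' @param events An event stream tibble.
#' @param bout_break Bout-break threshold in seconds.
#' @return A tibble of bouts: `bout`, `first`, `last` (lick indices into
#'   the onset-sorted stream), `start`, `end`, `n_licks`.
#' @examples
#' ev <- tibble::tibble(channel = "lick",
#'                      onset = c(0, 0.15, 0.30, 2.0, 2.15),
#'                      offset = c(0, 0.15, 0.30, 2.0, 2.15) + 0.05)
#' segment_bouts(ev)
#' @export
segment_bouts <- function(events, bout_break = 0.5) {
  check_number(bout_break, "bout_break", lower = 0, strict_lower = TRUE)
  if ("channel" %in% names(events)) {
    events <- events[events$channel == "lick", , drop = FALSE]
  }
  events <- events[order(events$onset), , drop = FALSE]
  n <- nrow(events)
  if (n == 0L) {
    return(tibble::tibble(bout = integer(0), first = integer(0),
                          last = integer(0), start = numeric(0),
                          end = numeric(0), n_licks = integer(0)))
  }
  ilis <- diff(events$onset)
  bout_id <- cumsum(c(TRUE, ilis >= bout_break))
  idx <- split(seq_len(n), bout_id)
  tibble::tibble(
    bout = seq_along(idx),
    first = unname(vapply(idx, min, integer(1))),
    last = unname(vapply(idx, max, integer(1))),
    start = events$onset[unname(vapply(idx, min, integer(1)))],
    end = events$offset[unname(vapply(idx, max, integer(1)))],
    n_licks = unname(lengths(idx))
  )
}

#' ILI histogram below the analysis ceiling
#'
#' Fixed-width bins on `(0, ili_max]`.
#'
#' @param ilis Numeric vector of interlick intervals (seconds).
#' @param cfg A [microstructure_config()].
#' @return A tibble with columns `bin_lo`, `bin_hi`, `count`.
#' @export
ili_histogram <- function(ilis, cfg = microstructure_config()) {
  stopifnot(inherits(cfg, "microstructure_config"))
  breaks <- seq(0, cfg$ili_max, by = cfg$hist_bin)
  if (tail(breaks, 1) < cfg$ili_max) breaks <- c(breaks, cfg$ili_max)
  inside <- ilis > 0 & ilis <= cfg$ili_max
  counts <- tabulate(findInterval(ilis[inside], breaks, left.open = TRUE,
                                  rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = counts
  )
}

#' Modal ILI (peak of the ILI distribution)
#'
#' The centre of the maximal histogram bin below the analysis ceiling,
#' with ties broken toward the smaller ILI. Returns `NA` when no ILI lies
#' below the ceiling.
#'
#' @inheritParams ili_histogram
#' @return The modal ILI in seconds, or `NA`.
#' @examples
#' modal_ili(c(rep(0.105, 10), rep(0.205, 5)))
#' @export
modal_ili <- function(ilis, cfg = microstructure_config()) {
  h <- ili_histogram(ilis, cfg)
  if (sum(h$count) == 0L) return(NA_real_)
  i <- which.max(h$count)  # which.max takes the first, i.e. smaller, tie
  (h$bin_lo[i] + h$bin_hi[i]) / 2
}

#' Primary ILI (mean ILI in the 0.05-0.25 s window)
#'
#' Arithmetic mean of the ILIs inside the closed
#' `[primary_lo, primary_hi]` window; `NA` when none fall inside.
#'
#' @inheritParams ili_histogram
#' @return The primary ILI in seconds, or `NA`.
#' @examples
#' primary_ili(c(0.10, 0.15, 0.20, 0.40))
#' @export
primary_ili <- function(ilis, cfg = microstructure_config()) {
  stopifnot(inherits(cfg, "microstructure_config"))
  inside <- ilis >= cfg$primary_lo & ilis <= cfg$primary_hi
  if (!any(inside)) return(NA_real_)
  mean(ilis[inside])
}

#' Summarise one session's licking
#'
#' @param events An event stream tibble (lick channel).
#' @param reward_times Optional numeric vector of reward times.
#' @param cfg A [microstructure_config()].
#' @param bout_break Bout-break threshold (seconds) for bout counting.
#' @return A one-row tibble: `n_licks`, `n_bouts`, `n_rewards`,
#'   `modal_ili`, `primary_ili`.
#' @export
session_summary <- function(events, reward_times = NULL,
                            cfg = microstructure_config(),
                            bout_break = 0.5) {
  if ("channel" %in% names(events)) {
    events <- events[events$channel == "lick", , drop = FALSE]
  }
  ilis <- interlick_intervals(events)
  tibble::tibble(
    n_licks = nrow(events),
    n_bouts = nrow(segment_bouts(events, bout_break)),
    n_rewards = length(reward_times %||% numeric(0)),
    modal_ili = modal_ili(ilis, cfg),
    primary_ili = primary_ili(ilis, cfg)
  )
}

#' Pearson correlation with a two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the usual
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Constant input yields the `NA` sentinel with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return A one-row tibble: `estimate`, `p.value`, `n`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 3, 2))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input: correlation is undefined.")
    return(tibble::tibble(estimate = NA_real_, p.value = NA_real_,
                          n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n = length(x))
}
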