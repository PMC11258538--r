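# Sensor-vs-video validation: segment video licks from the tongue-tip pose
# track, match sensor events to them, classify TP/FP/FN, summarise
# precision/recall, test false-negative enrichment by lick kind, and apply
# the post hoc artifact filter.

#' Segment video-defined licks from a pose track
#'
#' A video lick is a maximal run of frames where the tongue tip is tracked
#' confidently (likelihood >= `likelihood_min`) and displaced beyond the
#' poke line, tolerating up to `max_gap_frames` sub-threshold frames inside
#' the run. Lick bounds are the first/last qualifying frame times, padded
#' by `pad_frames` frame periods on each side to cover the protrusion
#' portion lost to frame sampling. The lick reaches the sipper (kind
#' `"sipper"`) when its peak displacement is at least `sipper_line`.
#'
#' @param track A pose tibble (from [read_pose()] or
#'   [simulate_pose_track()]) containing the `tongue_tip` bodypart.
#' @param cfg A [segmentation_config()].
#' @return A tibble of video licks: `start`, `end`, `kind`,
#'   `peak_displacement`.
#' @export
segment_video_licks <- function(track, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  tongue <- track[track$bodypart == "tongue_tip", , drop = FALSE]
  if (nrow(tongue) == 0L) abort("Pose track has no `tongue_tip` bodypart.")
  tongue <- tongue[order(tongue$frame), , drop = FALSE]
  ok <- is.finite(tongue$likelihood) &
    tongue$likelihood >= cfg$likelihood_min &
    tongue$y >= cfg$poke_line
  if (!any(ok)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          kind = character(0),
                          peak_displacement = numeric(0)))
  }
  frame_period <- if (nrow(tongue) > 1L) median(diff(tongue$time_s)) else 0
  idx <- which(ok)
  gaps <- diff(idx)
  new_run <- c(TRUE, gaps > cfg$max_gap_frames + 1L)
  run_id <- cumsum(new_run)
  pad <- cfg$pad_frames * frame_period
  runs <- lapply(split(idx, run_id), function(ii) {
    span <- seq(min(ii), max(ii))
    tibble::tibble(
      start = tongue$time_s[min(ii)] - pad,
      end = tongue$time_s[max(ii)] + pad,
      peak_displacement = max(tongue$y[span])
    )
  })
  out <- dplyr::bind_rows(runs)
  out$kind <- ifelse(out$peak_displacement >= cfg$sipper_line,
                     "sipper", "short")
  out[c("start", "end", "kind", "peak_displacement")]
}

#' Match sensor events against video-defined licks
#'
#' Each sensor event is assigned to the video lick whose `[start, end]`
#' interval contains its onset. The first event assigned to a lick is a
#' true positive; later events in the same lick, and events inside no
#' lick, are false positives. Licks that receive no event are false
#' negatives.
#'
#' @param licks A tibble of video licks (from [segment_video_licks()]),
#'   sorted and non-overlapping.
#' @param events An event stream tibble; only the `lick` channel is scored
#'   if a `channel` column is present.
#' @return A `match_result`: `$events` with a `label` (`TP`/`FP`) and
#'   `video_lick` assignment, and `$licks` with a `matched` flag.
#' @export
match_events <- function(licks, events) {
  if ("channel" %in% names(events)) {
    events <- events[events$channel == "lick", , drop = FALSE]
  }
  licks <- licks[order(licks$start), , drop = FALSE]
  if (nrow(licks) > 1L &&
      any(licks$start[-1] < licks$end[-nrow(licks)])) {
    abort("Video licks overlap; event assignment would be ambiguous.")
  }
  events <- events[order(events$onset), , drop = FALSE]
  hit <- findInterval(events$onset, licks$start)
  inside <- hit > 0 & events$onset <= licks$end[pmax(hit, 1L)]
  assigned <- ifelse(inside, hit, NA_integer_)
  first_in_lick <- !is.na(assigned) & !duplicated(assigned, incomparables = NA)
  label <- ifelse(first_in_lick, "TP", "FP")
  ev <- dplyr::mutate(events, video_lick = assigned, label = label)
  lk <- dplyr::mutate(licks,
                      matched = seq_len(nrow(licks)) %in% assigned[first_in_lick])
  structure(list(events = ev, licks = lk), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d events (%d TP, %d FP), %d video licks (%d FN)\n",
              nrow(x$events), sum(x$events$label == "TP"),
              sum(x$events$label == "FP"), nrow(x$licks),
              sum(!x$licks$matched)))
  invisible(x)
}

#' Detection metrics from a match result or per-session counts
#'
#' `precision = tp / (tp + fp)` and `recall = tp / (tp + fn)`. Undefined
#' ratios (zero denominator) are reported as `NA`, an explicit sentinel,
#' never as 0.
#'
#' @param x A `match_result`, or a data frame with columns `tp`, `fp`,
#'   `fn` (one row per session).
#' @return A tibble with columns `tp`, `fp`, `fn`, `precision`, `recall`
#'   (one row per input row for the data-frame method).
#' @examples
#' detection_metrics(data.frame(tp = 9, fp = 1, fn = 0))
#' @export
detection_metrics <- function(x) {
  UseMethod("detection_metrics")
}

#' @export
detection_metrics.match_result <- function(x) {
  detection_metrics(data.frame(
    tp = sum(x$events$label == "TP"),
    fp = sum(x$events$label == "FP"),
    fn = sum(!x$licks$matched)
  ))
}

#' @export
detection_metrics.data.frame <- function(x) {
  stopifnot(all(c("tp", "fp", "fn") %in% names(x)))
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::as_tibble(x) |>
    dplyr::mutate(
      precision = ratio(.data$tp, .data$tp + .data$fp),
      recall = ratio(.data$tp, .data$tp + .data$fn)
    )
}

#' Pooled and per-session summaries of detection metrics
#'
#' Reports both the pooled-count metrics (summing tp/fp/fn over sessions
#' before taking ratios) and the mean with its standard error of the
#' per-session ratios; the two differ whenever sessions are unbalanced,
#' and per-animal means are what validation studies usually report.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`, one row per
#'   session.
#' @return A tibble with rows `pooled` and `mean_of_sessions`.
#' @export
detection_summary <- function(counts) {
  per <- detection_metrics(counts)
  pooled <- detection_metrics(data.frame(
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn)
  ))
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  }
  tibble::tibble(
    summary = c("pooled", "mean_of_sessions"),
    precision = c(pooled$precision, mean(per$precision, na.rm = TRUE)),
    precision_sem = c(NA_real_, sem(per$precision)),
    recall = c(pooled$recall, mean(per$recall, na.rm = TRUE)),
    recall_sem = c(NA_real_, sem(per$recall))
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by summing, over the
#' hypergeometric support fixed by the table margins, the probabilities of
#' all tables at most as probable as the observed one (with the customary
#' `1 + 1e-7` relative tolerance when comparing probabilities).
#'
#' @param x A 2x2 matrix of non-negative integer counts, rows = groups
#'   (e.g. lick kind), columns = outcome (e.g. missed vs detected).
#' @return The two-sided p-value (a single number).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 17, 4, 199), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) abort("`x` must be a 2x2 matrix.")
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be non-negative integers.")
  }
  m <- sum(x[1, ])          # row 1 margin
  n2 <- sum(x[2, ])         # row 2 margin
  k <- sum(x[, 1])          # column 1 margin
  if (m + n2 == 0L) return(1)
  support <- max(0L, k - n2):min(k, m)
  pmf <- dhyper(support, m, n2, k)
  p_obs <- dhyper(x[1, 1], m, n2, k)
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

#' Apply the post hoc artifact filter to an event stream
#'
#' True licks have durations in a narrow window and never follow another
#' lick within the minimum physiological interlick interval; events
#' violating those rules are sensor artifacts (double detections, snout
#' beam breaks). The default rule keeps an event iff its duration lies in
#' `[dur_min, dur_max]` AND its onset-to-onset ILI against the previous
#' *kept* event exceeds `ili_min` (the first event has no predecessor and
#' passes the ILI criterion vacuously). Measuring the ILI against the
#' previous kept event means a removed double cannot shield a subsequent
#' double. `rule = "either"` keeps an event passing at least one
#' criterion, the alternative reading of duration-and/or-ILI inclusion.
#'
#' @param events An event stream tibble (sorted by onset).
#' @param cfg A [filter_config()].
#' @param rule `"both"` (default, conjunctive keep) or `"either"`.
#' @return A `filter_result`: `$events` (kept rows), `$removed` (dropped
#'   rows with a `reason` column: `duration`, `ili`, or
#'   `duration+ili`), `$rule`, `$config`.
#' @export
apply_posthoc_filter <- function(events, cfg = filter_config(),
                                 rule = c("both", "either")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cfg, "filter_config"))
  events <- events[order(events$onset), , drop = FALSE]
  n <- nrow(events)
  dur_ok <- (events$offset - events$onset) >= cfg$dur_min &
    (events$offset - events$onset) <= cfg$dur_max
  keep <- logical(n)
  ili_ok <- logical(n)
  last_kept <- -Inf
  for (i in seq_len(n)) {
    ili_ok[i] <- (events$onset[i] - last_kept) > cfg$ili_min
    keep[i] <- if (rule == "both") dur_ok[i] && ili_ok[i] else
      dur_ok[i] || ili_ok[i]
    if (keep[i]) last_kept <- events$onset[i]
  }
  reason <- dplyr::case_when(
    keep ~ NA_character_,
    !dur_ok & !ili_ok ~ "duration+ili",
    !dur_ok ~ "duration",
    TRUE ~ "ili"
  )
  structure(list(
    events = events[keep, , drop = FALSE],
    removed = dplyr::mutate(events[!keep, , drop = FALSE],
                            reason = reason[!keep]),
    rule = rule, config = cfg
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> kept %d, removed %d event(s) [rule: %s]\n",
              nrow(x$events), nrow(x$removed), x$rule))
  invisible(x)
}

#' Contingency table of misses by lick kind
#'
#' Cross-tabulates ground-truth (or video-scored) licks by kind and
#' detection outcome, in the layout used for the miss-enrichment test:
#' rows `short`/`sipper`, columns `missed`/`detected`.
#'
#' @param kind Character vector, `"short"` or `"sipper"` per lick.
#' @param detected Logical vector, whether each lick was detected.
#' @return A 2x2 integer matrix.
#' @export
miss_contingency <- function(kind, detected) {
  stopifnot(length(kind) == length(detected))
  matrix(
    c(sum(kind == "short" & !detected), sum(kind == "short" & detected),
      sum(kind == "sipper" & !detected), sum(kind == "sipper" & detected)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("short", "sipper"), c("missed", "detected"))
  )
}
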