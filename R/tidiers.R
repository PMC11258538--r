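# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a lick session into its lick table
#'
#' @param x A `lick_session`.
#' @param ... Unused.
#' @return A tibble with one row per lick (`onset`, `offset`, `kind`,
#'   `bout`) plus a `rewarded_bout` flag when rewards are annotated.
#' @export
tidy.lick_session <- function(x, ...) {
  licks <- x$licks
  if (!is.null(x$reward_times) && nrow(x$bouts)) {
    licks$rewarded_bout <- x$bouts$rewarded[licks$bout]
  }
  licks
}

#' @rdname tidy.lick_session
#' @export
glance.lick_session <- function(x, ...) {
  tibble::tibble(
    n_licks = nrow(x$licks),
    n_bouts = nrow(x$bouts),
    n_rewards = length(x$reward_times %||% numeric(0)),
    duration = x$duration
  )
}

#' Tidy a match result into its labelled event table
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return `tidy()`: the event tibble with `label` and `video_lick`;
#'   `glance()`: a one-row tibble of counts and metrics.
#' @export
tidy.match_result <- function(x, ...) {
  x$events
}

#' @rdname tidy.match_result
#' @export
glance.match_result <- function(x, ...) {
  detection_metrics(x)
}

#' Tidy a PETH into a long tibble
#'
#' @param x A `peth`.
#' @param ... Unused.
#' @return `tidy()`: one row per timepoint (`rel_time`, `mean`, `sem`,
#'   `group`); `glance()`: one row of sizes.
#' @export
tidy.peth <- function(x, ...) {
  tibble::tibble(
    rel_time = x$rel_time, mean = x$mean, sem = x$sem,
    group = x$group %||% NA_character_
  )
}

#' @rdname tidy.peth
#' @export
glance.peth <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials, n_timepoints = length(x$rel_time),
    dropped = x$dropped, group = x$group %||% NA_character_
  )
}

#' Tidy a PETH comparison
#'
#' @param x A `peth_anova`.
#' @param ... Unused.
#' @return `tidy()`: the ANOVA table (`term`, `df1`, `df2`, `statistic`,
#'   `p.value`); `glance()`: a one-row summary with the size of the
#'   significant post hoc window.
#' @export
tidy.peth_anova <- function(x, ...) {
  x$anova
}

#' @rdname tidy.peth_anova
#' @export
glance.peth_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_timepoints = length(x$mask),
    n_significant = sum(x$mask),
    correction = x$correction,
    alpha = x$alpha
  )
}
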