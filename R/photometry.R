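# Fiber-photometry processing: robust locally weighted regression
# (LOWESS) detrending of each channel, isosbestic subtraction, session
# z-scoring, peri-event time histograms, and a two-way repeated-measures
# comparison of rewarded vs unrewarded alignments.

#' Robust locally weighted regression (LOWESS) smoother
#'
#' Cleveland-style locally weighted linear regression on the sample index:
#' for each point, a weighted linear fit over its `ceiling(frac * n)`
#' nearest neighbours with tricube weights, followed by `it` robustifying
#' passes in which residuals are re-weighted by the bisquare function on
#' `r / (6 * median(|r|))`. When `delta > 0` exact fits are computed only
#' at anchor points at most `delta` index units apart and intermediate
#' points are linearly interpolated (with `delta = 0` every point is fit
#' exactly). `delta` is measured in sample-index units: 20 samples is
#' 0.4 s at a 50 Hz acquisition rate. When the residual scale collapses to
#' (numerically) zero the robustness pass is skipped, since re-weighting
#' would be ill-defined.
#'
#' @param y Numeric series to smooth.
#' @param frac Fraction of points in each local fit (0 < frac <= 1).
#' @param it Number of robustifying iterations.
#' @param delta Interpolation distance in sample-index units.
#' @return The fitted (smoothed) series, same length as `y`.
#' @examples
#' y <- exp(-(1:300) / 100) + rnorm(300, 0, 0.01)
#' fit <- lowess_smooth(y, frac = 0.1, it = 3, delta = 20)
#' @export
lowess_smooth <- function(y, frac = 0.1, it = 3, delta = 20) {
  check_number(frac, "frac", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(it, "it", lower = 0)
  check_number(delta, "delta", lower = 0)
  n <- length(y)
  if (n < 2L) abort("Need at least two points to smooth.")
  q <- min(n, max(2L, as.integer(ceiling(frac * n))))
  if (q < 2L) abort("`frac` is too small: the local window has < 2 points.")
  rw <- rep(1, n)
  x <- as.numeric(seq_len(n))
  fit <- numeric(n)
  scale0 <- mean(abs(y))

  fit_at <- function(i) {
    lo <- min(max(1L, i - q %/% 2L), n - q + 1L)
    hi <- lo + q - 1L
    xs <- x[lo:hi]
    ys <- y[lo:hi]
    h <- max(x[i] - xs[1], xs[q] - x[i])
    w <- if (h > 0) {
      d <- abs(xs - x[i]) / h
      (1 - pmin(d, 1)^3)^3
    } else {
      rep(1, q)
    }
    w <- w * rw[lo:hi]
    sw <- sum(w)
    if (sw <= 0) return(mean(ys))
    mx <- sum(w * xs) / sw
    my <- sum(w * ys) / sw
    vx <- sum(w * (xs - mx)^2)
    if (vx <= 1e-12 * h^2) return(my)
    b <- sum(w * (xs - mx) * (ys - my)) / vx
    my + b * (x[i] - mx)
  }

  for (iter in 0:it) {
    anchors <- 1L
    repeat {
      a <- anchors[length(anchors)]
      if (a >= n) break
      nxt <- if (delta > 0) {
        j <- a + as.integer(floor(delta))
        max(a + 1L, min(j, n))
      } else {
        a + 1L
      }
      anchors <- c(anchors, nxt)
    }
    afit <- vapply(anchors, fit_at, numeric(1))
    fit <- if (length(anchors) == n) {
      afit
    } else {
      approx(x[anchors], afit, xout = x)$y
    }
    if (iter == it) break
    res <- y - fit
    s6 <- 6 * median(abs(res))
    if (s6 <= 1e-7 * max(scale0, .Machine$double.eps)) break
    rw <- pmax(1 - pmin(abs(res) / s6, 1)^2, 0)^2
  }
  fit
}

#' Preprocess a two-channel photometry trace
#'
#' Implements the standard dLight processing chain: each channel is
#' detrended by subtracting its LOWESS fit (removing photobleaching), the
#' detrended isosbestic channel is subtracted from the detrended signal
#' channel (removing shared motion/artifact components), and the resulting
#' delta-fluorescence is z-scored over the whole session using the
#' population (divide-by-n) standard deviation.
#'
#' @param trace A tibble with columns `time_s`, `ch470`, `ch415`.
#' @param cfg A [photometry_config()].
#' @return The input tibble with added columns `fit470`, `fit415`,
#'   `resid470`, `resid415`, `dff` (the subtracted residual) and `z`.
#' @export
preprocess_photometry <- function(trace, cfg = photometry_config()) {
  stopifnot(inherits(cfg, "photometry_config"))
  need <- c("time_s", "ch470", "ch415")
  if (!all(need %in% names(trace))) {
    abort("`trace` needs columns `time_s`, `ch470`, `ch415`.")
  }
  fit470 <- lowess_smooth(trace$ch470, cfg$lowess_frac, cfg$lowess_it,
                          cfg$lowess_delta)
  fit415 <- lowess_smooth(trace$ch415, cfg$lowess_frac, cfg$lowess_it,
                          cfg$lowess_delta)
  resid470 <- trace$ch470 - fit470
  resid415 <- trace$ch415 - fit415
  dff <- resid470 - resid415
  n <- length(dff)
  s <- sqrt(sum((dff - mean(dff))^2) / n)
  if (s == 0) abort("Delta-fluorescence is constant; z-score is undefined.")
  dplyr::mutate(trace,
                fit470 = fit470, fit415 = fit415,
                resid470 = resid470, resid415 = resid415,
                dff = dff, z = (dff - mean(dff)) / s)
}

#' Peri-event time histogram
#'
#' Extracts one row per event from `signal`, aligned at the nearest sample
#' to the event time, spanning `window_pre` seconds before to
#' `window_post` seconds after. Events whose window would leave the
#' session are dropped (and counted in `$dropped`). An optional per-trial
#' baseline (mean over `cfg$baseline`) is subtracted.
#'
#' @param data A tibble with a time column and the signal column, e.g. the
#'   output of [preprocess_photometry()].
#' @param event_times Numeric vector of event times (seconds).
#' @param cfg A [peth_config()].
#' @param signal,time Column names of the signal and time axes.
#' @param group Optional label (e.g. `"rewarded"`) carried on the result.
#' @return A `peth` object: `$rel_time`, `$trials` (trials x timepoints
#'   matrix), `$mean`, `$sem`, `$n_trials`, `$dropped`, `$group`.
#' @export
compute_peth <- function(data, event_times, cfg = peth_config(),
                         signal = "z", time = "time_s", group = NULL) {
  stopifnot(inherits(cfg, "peth_config"))
  if (!signal %in% names(data)) {
    abort(sprintf("Column `%s` not found in `data`.", signal))
  }
  tt <- data[[time]]
  y <- data[[signal]]
  n <- length(y)
  if (n < 2L) abort("Signal too short for a PETH.")
  rate <- 1 / median(diff(tt))
  pre_n <- round(cfg$window_pre * rate)
  post_n <- round(cfg$window_post * rate)
  rel_idx <- seq.int(-pre_n, post_n)
  rel_time <- rel_idx / rate
  centre <- round((event_times - tt[1]) * rate) + 1
  usable <- centre - pre_n >= 1 & centre + post_n <= n
  dropped <- sum(!usable)
  centre <- centre[usable]
  if (length(centre) == 0L) {
    abort("No event has its full window inside the session.")
  }
  idx <- outer(as.integer(centre), as.integer(rel_idx), `+`)
  trials <- matrix(y[idx], nrow = length(centre))
  if (!is.null(cfg$baseline)) {
    in_base <- rel_time >= cfg$baseline[1] & rel_time <= cfg$baseline[2]
    if (!any(in_base)) abort("Baseline window contains no samples.")
    trials <- trials - rowMeans(trials[, in_base, drop = FALSE])
  }
  m <- colMeans(trials)
  sem <- if (nrow(trials) > 1L) {
    apply(trials, 2, sd) / sqrt(nrow(trials))
  } else {
    rep(0, ncol(trials))
  }
  structure(list(
    rel_time = rel_time, trials = trials, mean = m, sem = sem,
    n_trials = nrow(trials), dropped = dropped, group = group,
    rate = rate
  ), class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf(
    "<peth>%s %d trial(s) x %d timepoints (%.2f to %.2f s, %d dropped)\n",
    if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
    x$n_trials, length(x$rel_time), min(x$rel_time), max(x$rel_time),
    x$dropped
  ))
  invisible(x)
}

#' Compare rewarded vs unrewarded PETHs (two-way repeated measures)
#'
#' Classical two-way within-subjects ANOVA with factors time and trial
#' type, computed from sums of squares on one mean trace per subject and
#' condition. Each factor's F statistic uses its factor-by-subject
#' interaction as the error term, so with `T` timepoints and `n` subjects
#' the time and interaction effects are tested on
#' `(T - 1, (T - 1)(n - 1))` degrees of freedom and the trial-type effect
#' on `(1, n - 1)`. Per-timepoint post hoc paired t tests (with Sidak
#' correction across timepoints by default) produce the significance
#' mask.
#'
#' @param peth_r,peth_u `peth` objects (or plain subjects x timepoints
#'   matrices) whose rows are subject-level mean traces, same subjects in
#'   the same order, same timepoints.
#' @param posthoc Multiple-comparison correction for the per-timepoint
#'   paired tests: `"sidak"` (default), `"bonferroni"`, or `"none"`.
#' @param alpha Significance level for the mask.
#' @return A `peth_anova`: `$anova` (tibble with `term`, `df1`, `df2`,
#'   `statistic`, `p.value`), `$posthoc` (per-timepoint tibble), `$mask`
#'   (logical significance mask), `$rel_time`.
#' @export
compare_peths <- function(peth_r, peth_u,
                          posthoc = c("sidak", "bonferroni", "none"),
                          alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  rel_time <- NULL
  as_mat <- function(p) {
    if (inherits(p, "peth")) {
      rel_time <<- rel_time %||% p$rel_time
      p$trials
    } else {
      as.matrix(p)
    }
  }
  yr <- as_mat(peth_r)
  yu <- as_mat(peth_u)
  if (!all(dim(yr) == dim(yu))) {
    abort("Groups must have the same subjects and timepoints.")
  }
  n <- nrow(yr)
  tp <- ncol(yr)
  if (n < 2L || tp < 2L) abort("Need at least 2 subjects and 2 timepoints.")
  rel_time <- rel_time %||% seq_len(tp)

  # y[subject, type, time]
  y <- array(c(yr, yu), dim = c(n, tp, 2L))
  y <- aperm(y, c(1, 3, 2))
  grand <- mean(y)
  m_s <- apply(y, 1, mean)          # subject means
  m_g <- apply(y, 2, mean)          # trial-type means
  m_t <- apply(y, 3, mean)          # time means
  m_sg <- apply(y, c(1, 2), mean)
  m_st <- apply(y, c(1, 3), mean)
  m_gt <- apply(y, c(2, 3), mean)

  ss_type <- n * tp * sum((m_g - grand)^2)
  ss_time <- n * 2 * sum((m_t - grand)^2)
  ss_subj <- 2 * tp * sum((m_s - grand)^2)
  ss_sg <- tp * sum((m_sg - outer(m_s, rep(1, 2)) -
                       outer(rep(1, n), m_g) + grand)^2)
  ss_st <- 2 * sum((m_st - outer(m_s, rep(1, tp)) -
                      outer(rep(1, n), m_t) + grand)^2)
  ss_gt <- n * sum((m_gt - outer(m_g, rep(1, tp)) -
                      outer(rep(1, 2), m_t) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_type - ss_time - ss_subj - ss_sg - ss_st - ss_gt

  df_type <- 1L
  df_time <- tp - 1L
  df_sg <- n - 1L
  df_st <- (n - 1L) * (tp - 1L)
  df_res <- (n - 1L) * (tp - 1L)

  # degenerate strata (zero error SS) arise from identical inputs
  safe_f <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= 0) return(if (ss_eff <= 0) 0 else Inf)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  f_type <- safe_f(ss_type, df_type, ss_sg, df_sg)
  f_time <- safe_f(ss_time, df_time, ss_st, df_st)
  f_int <- safe_f(ss_gt, df_time, ss_res, df_res)

  anova_tbl <- tibble::tibble(
    term = c("time", "trial_type", "interaction"),
    df1 = c(df_time, df_type, df_time),
    df2 = c(df_st, df_sg, df_res),
    statistic = c(f_time, f_type, f_int),
    p.value = stats::pf(c(f_time, f_type, f_int),
                        c(df_time, df_type, df_time),
                        c(df_st, df_sg, df_res), lower.tail = FALSE)
  )

  diffs <- yr - yu
  p_raw <- vapply(seq_len(tp), function(j) {
    d <- diffs[, j]
    if (sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    t.test(d)$p.value
  }, numeric(1))
  p_adj <- switch(posthoc,
    sidak = 1 - (1 - p_raw)^tp,
    bonferroni = pmin(p_raw * tp, 1),
    none = p_raw
  )
  mask <- p_adj < alpha
  structure(list(
    anova = anova_tbl,
    posthoc = tibble::tibble(rel_time = rel_time, p.value = p_raw,
                             p.adjusted = pmin(p_adj, 1),
                             significant = mask),
    mask = mask, rel_time = rel_time,
    correction = posthoc, alpha = alpha, n_subjects = n
  ), class = "peth_anova")
}

#' @export
print.peth_anova <- function(x, ...) {
  cat(sprintf("<peth_anova> %d subjects, %d timepoints; %d significant (%s, alpha = %g)\n",
              x$n_subjects, length(x$mask), sum(x$mask), x$correction,
              x$alpha))
  print(x$anova)
  invisible(x)
}
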