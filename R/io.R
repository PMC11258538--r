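# Table I/O. Three CSV formats flow through the pipeline: event streams
# (`channel,onset_s,offset_s`), pose tracks (flat long format or the
# DeepLabCut three-header-row dialect), and photometry traces
# (`time_s,ch470,ch415`). All times are seconds, session-relative,
# `.`-decimal UTF-8 CSV. Parsers reject bad rows loudly, naming the row.

POSE_BODYPARTS <- c("nose", "tongue_tip")

#' Read and write sensor event streams
#'
#' Event CSVs have the header `channel,onset_s,offset_s`; intervals are
#' closed `[onset, offset]` with strictly positive duration. Rows are
#' sorted by onset on read (within channel ordering must be strict).
#'
#' @param path File path.
#' @return `read_events()` returns a tibble with columns `channel`,
#'   `onset`, `offset`; `write_events()` invisibly returns `path`.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' ev <- tibble::tibble(channel = "lick", onset = c(0, 1), offset = c(0.1, 1.1))
#' write_events(ev, p)
#' read_events(p)
#' @export
read_events <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    onset_s = readr::col_double(),
    offset_s = readr::col_double()
  ))
  missing_cols <- setdiff(c("channel", "onset_s", "offset_s"), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Event file is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(raw$onset_s) | !is.finite(raw$offset_s))
  if (length(bad)) {
    abort(sprintf("Non-numeric or missing timestamp at row %d of %s.",
                  bad[1] + 1L, path))
  }
  bad <- which(raw$offset_s <= raw$onset_s)
  if (length(bad)) {
    abort(sprintf("offset <= onset at row %d of %s.", bad[1] + 1L, path))
  }
  out <- tibble::tibble(channel = raw$channel, onset = raw$onset_s,
                        offset = raw$offset_s)
  out <- out[order(out$onset, out$offset), , drop = FALSE]
  validate_event_stream(out)
  out
}

#' @rdname read_events
#' @param events A tibble with columns `channel`, `onset`, `offset`.
#' @export
write_events <- function(events, path) {
  validate_event_stream(events)
  readr::write_csv(
    tibble::tibble(channel = events$channel, onset_s = events$onset,
                   offset_s = events$offset),
    path
  )
  invisible(path)
}

validate_event_stream <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("channel", "onset", "offset")
  if (!all(need %in% names(events))) {
    abort("An event stream needs columns `channel`, `onset`, `offset`.")
  }
  if (any(events$offset <= events$onset)) {
    abort("Every event must satisfy offset > onset.")
  }
  for (ch in unique(events$channel)) {
    sub <- events[events$channel == ch, , drop = FALSE]
    if (nrow(sub) > 1L) {
      if (any(diff(sub$onset) <= 0)) {
        abort(sprintf("Onsets must be strictly increasing within channel `%s`.", ch))
      }
      if (any(sub$offset[-nrow(sub)] > sub$onset[-1])) {
        abort(sprintf("Events overlap within channel `%s`.", ch))
      }
    }
  }
  invisible(events)
}

#' Read a pose-tracking table
#'
#' Supports two encodings of the same per-frame records: `"plain"` (flat
#' header `frame,time_s,bodypart,x,y,likelihood`) and `"dlc"`, the
#' DeepLabCut dialect with three header rows (scorer / bodyparts / coords)
#' and one `x,y,likelihood` triplet per bodypart. Frames whose likelihood
#' falls below `likelihood_min` are flagged `missing`, never dropped;
#' interpolation is left to the consumer.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"plain"`, or `"dlc"`.
#' @param frame_rate Frames per second used to derive `time_s` in the dlc
#'   dialect (which stores only frame indices), default 60.
#' @param likelihood_min Threshold below which a frame is flagged missing.
#' @return A tibble with columns `frame`, `time_s`, `bodypart`, `x`, `y`,
#'   `likelihood`, `missing`.
#' @export
read_pose <- function(path, dialect = c("auto", "plain", "dlc"),
                      frame_rate = 60, likelihood_min = 0) {
  dialect <- match.arg(dialect)
  first <- readr::read_lines(path, n_max = 1)
  if (dialect == "auto") {
    dialect <- if (grepl("^scorer", first)) "dlc" else "plain"
  }
  track <- if (dialect == "dlc") {
    read_pose_dlc(path, frame_rate)
  } else {
    read_pose_plain(path)
  }
  bad_parts <- setdiff(unique(track$bodypart), POSE_BODYPARTS)
  if (length(bad_parts)) {
    abort(sprintf("Unknown bodypart(s): %s.", paste(bad_parts, collapse = ", ")))
  }
  if (any(track$likelihood < 0 | track$likelihood > 1, na.rm = TRUE)) {
    abort("Likelihood values must lie in [0, 1].")
  }
  track$missing <- !is.finite(track$likelihood) |
    track$likelihood < likelihood_min
  track[order(track$bodypart, track$frame), , drop = FALSE]
}

read_pose_plain <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(),
    time_s = readr::col_double(),
    bodypart = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double(),
    likelihood = readr::col_double()
  ))
  need <- c("frame", "time_s", "bodypart", "x", "y", "likelihood")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Pose file is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(raw[need])
}

read_pose_dlc <- function(path, frame_rate) {
  hdr <- readr::read_lines(path, n_max = 3)
  if (length(hdr) < 3) abort("A dlc pose file needs three header rows.")
  parts <- strsplit(hdr[2], ",", fixed = TRUE)[[1]][-1]
  coords <- strsplit(hdr[3], ",", fixed = TRUE)[[1]][-1]
  if (length(parts) != length(coords) || length(parts) %% 3L != 0L) {
    abort("Ragged dlc header: each bodypart needs an x,y,likelihood triplet.")
  }
  body <- readr::read_csv(path, skip = 3, col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_double()))
  if (ncol(body) != length(parts) + 1L) {
    abort("Ragged dlc data rows: column count does not match the header.")
  }
  frame <- as.integer(body[[1]])
  out <- lapply(unique(parts), function(bp) {
    cols <- which(parts == bp) + 1L
    names(cols) <- coords[parts == bp]
    tibble::tibble(
      frame = frame, time_s = frame / frame_rate, bodypart = bp,
      x = body[[cols[["x"]]]], y = body[[cols[["y"]]]],
      likelihood = body[[cols[["likelihood"]]]]
    )
  })
  dplyr::bind_rows(out)
}

#' @rdname read_pose
#' @param track A pose tibble as returned by [read_pose()] or
#'   [simulate_pose_track()].
#' @param scorer Scorer label written into the dlc header row.
#' @export
write_pose <- function(track, path, dialect = c("plain", "dlc"),
                       scorer = "synthetic") {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    readr::write_csv(
      track[c("frame", "time_s", "bodypart", "x", "y", "likelihood")], path
    )
    return(invisible(path))
  }
  parts <- sort(unique(track$bodypart))
  wide <- NULL
  frames <- sort(unique(track$frame))
  cols <- list(tibble::tibble(frame = frames))
  for (bp in parts) {
    sub <- track[track$bodypart == bp, , drop = FALSE]
    sub <- sub[match(frames, sub$frame), , drop = FALSE]
    cols[[length(cols) + 1L]] <- setNames(
      sub[c("x", "y", "likelihood")],
      paste(bp, c("x", "y", "likelihood"), sep = "_")
    )
  }
  wide <- dplyr::bind_cols(cols)
  hdr1 <- paste(c("scorer", rep(scorer, 3L * length(parts))), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(parts, each = 3L)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
                collapse = ",")
  readr::write_lines(c(hdr1, hdr2, hdr3), path)
  readr::write_csv(wide, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Read and write photometry traces
#'
#' Photometry CSVs have the header `time_s,ch470,ch415`, uniformly sampled.
#'
#' @param path File path.
#' @return `read_photometry()` returns a tibble with those columns.
#' @export
read_photometry <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    ch470 = readr::col_double(),
    ch415 = readr::col_double()
  ))
  missing_cols <- setdiff(c("time_s", "ch470", "ch415"), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Photometry file is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) > 2L) {
    dt <- diff(raw$time_s)
    if (max(dt) - min(dt) > 1e-6) {
      abort("Photometry trace must be uniformly sampled.")
    }
  }
  tibble::as_tibble(raw)
}

#' @rdname read_photometry
#' @param trace A tibble with columns `time_s`, `ch470`, `ch415`.
#' @export
write_photometry <- function(trace, path) {
  readr::write_csv(trace[c("time_s", "ch470", "ch415")], path)
  invisible(path)
}

trace_rate <- function(trace) {
  if (nrow(trace) < 2L) abort("Need at least two samples to infer a rate.")
  1 / median(diff(trace$time_s))
}

#' Shift the clock of a stream or track by a constant offset
#'
#' Adds `offset` seconds to every timestamp column (`onset`/`offset` for
#' event streams, `time_s` otherwise), preserving order. A shift producing
#' negative session time triggers a warning, not an error.
#'
#' @param x An event stream, pose track, or photometry trace tibble.
#' @param offset Seconds to add (may be negative).
#' @return The same type of tibble, shifted.
#' @examples
#' ev <- tibble::tibble(channel = "lick", onset = 1, offset = 1.1)
#' align_clocks(ev, 0.25)
#' @export
align_clocks <- function(x, offset) {
  check_number(offset, "offset")
  if (all(c("onset", "offset") %in% names(x))) {
    x$onset <- x$onset + offset
    x$offset <- x$offset + offset
    if (any(x$onset < 0)) warn("Shift produced negative session time.")
  } else if ("time_s" %in% names(x)) {
    x$time_s <- x$time_s + offset
    if (any(x$time_s < 0)) warn("Shift produced negative session time.")
  } else {
    abort("Don't know how to shift this object: no time columns found.")
  }
  x
}
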