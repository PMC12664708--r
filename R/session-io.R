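#' Tracker streams and sessions
#'
#' A *tracker stream* is a tibble with one row per sample and columns
#' `t` (seconds from session start), `px, py, pz` (metres, global frame,
#' Z up) and `qw, qx, qy, qz` (unit quaternion, scalar first, rotating
#' tracker-local axes into the global frame). Stream-level metadata lives
#' in attributes: `tracker_id` (one of `"left_ankle"`, `"right_ankle"`,
#' `"navel"`), `nominal_rate` (Hz) and `gaps` (a tibble of half-open
#' dropout intervals `[t_start, t_end)`).
#'
#' A *session* is a list of class `vrgait_session` holding the three
#' streams plus `subject_id`, `condition` (`"no_wall"` or `"wall"`),
#' `visit` (`"immediate"` or `"delayed"`) and `maze_id`.
#'
#' @name session
NULL

TRACKER_IDS <- c("left_ankle", "right_ankle", "navel")

#' Construct a validated tracker stream
#'
#' @param samples data frame with columns `t, px, py, pz, qw, qx, qy, qz`.
#' @param tracker_id one of `"left_ankle"`, `"right_ankle"`, `"navel"`.
#' @param nominal_rate nominal sampling rate in Hz (default 90).
#' @param gaps optional tibble of dropout intervals with columns
#'   `t_start`, `t_end`; if `NULL`, gaps are detected from timestamp
#'   discontinuities via [detect_dropouts()].
#' @param max_gap_factor passed to [detect_dropouts()] when `gaps` is `NULL`.
#'
#' @return a tibble of class `vrgait_stream` with metadata attributes.
#' @export
tracker_stream <- function(samples, tracker_id, nominal_rate = 90,
                           gaps = NULL, max_gap_factor = 3) {
  tracker_id <- match.arg(tracker_id, TRACKER_IDS)
  cols <- c("t", "px", "py", "pz", "qw", "qx", "qy", "qz")
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols) > 0) {
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  samples <- tibble::as_tibble(samples)[cols]
  if (any(!is.finite(samples$t)) || any(samples$t < 0)) {
    stop("timestamps must be finite and non-negative")
  }
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
    stop("timestamps must be strictly increasing (tracker ", tracker_id, ")")
  }
  qn <- quat_norm(samples$qw, samples$qx, samples$qy, samples$qz)
  bad <- which(abs(qn - 1) > 1e-6)
  if (length(bad) > 0) {
    stop("non-unit quaternion in tracker ", tracker_id,
         " at sample index ", bad[1], " (|q| = ", format(qn[bad[1]]), ")")
  }
  out <- samples
  attr(out, "tracker_id") <- tracker_id
  attr(out, "nominal_rate") <- nominal_rate
  class(out) <- c("vrgait_stream", class(out))
  attr(out, "gaps") <- if (is.null(gaps)) {
    detect_dropouts(out, max_gap_factor = max_gap_factor)
  } else {
    tibble::as_tibble(gaps)[c("t_start", "t_end")]
  }
  out
}

#' @export
print.vrgait_stream <- function(x, ...) {
  cat("<tracker stream> id:", attr(x, "tracker_id"),
      " rate:", attr(x, "nominal_rate"), "Hz ",
      nrow(x), "samples,", nrow(stream_gaps(x)), "gap(s)\n")
  NextMethod()
}

#' Accessors for stream metadata
#' @param stream a `vrgait_stream`.
#' @return `stream_gaps()` returns the gap tibble; `stream_rate()` the
#'   nominal rate in Hz; `stream_id()` the tracker id.
#' @export
stream_gaps <- function(stream) {
  g <- attr(stream, "gaps")
  if (is.null(g)) tibble::tibble(t_start = double(), t_end = double()) else g
}

#' @rdname stream_gaps
#' @export
stream_rate <- function(stream) attr(stream, "nominal_rate")

#' @rdname stream_gaps
#' @export
stream_id <- function(stream) attr(stream, "tracker_id")

#' Detect tracking dropouts from timestamp discontinuities
#'
#' Any inter-sample interval longer than `max_gap_factor` nominal periods
#' is reported as a dropout. The gap interval is half-open and excludes
#' the expected position of the first missing sample's predecessor: a gap
#' between samples at `t_i` and `t_{i+1}` is
#' `[t_i + 1/rate, t_{i+1})`, i.e. the span the missing samples would
#' have occupied.
#'
#' @param stream a `vrgait_stream`, or any data frame with a `t` column
#'   (then `nominal_rate` is taken from the stream attribute or defaults
#'   to 90).
#' @param max_gap_factor threshold in nominal periods (default 3).
#'
#' @return tibble with columns `t_start`, `t_end`, sorted, non-overlapping.
#' @export
detect_dropouts <- function(stream, max_gap_factor = 3) {
  rate <- attr(stream, "nominal_rate")
  if (is.null(rate)) rate <- 90
  t <- stream$t
  if (length(t) < 2) {
    return(tibble::tibble(t_start = double(), t_end = double()))
  }
  period <- 1 / rate
  dt <- diff(t)
  idx <- which(dt > max_gap_factor * period)
  tibble::tibble(t_start = t[idx] + period, t_end = t[idx + 1])
}

#' Construct a session from three tracker streams
#'
#' @param streams named or unnamed list of the three `vrgait_stream`s
#'   (left_ankle, right_ankle, navel in any order).
#' @param subject_id subject identifier.
#' @param condition `"no_wall"` or `"wall"`.
#' @param visit `"immediate"` or `"delayed"`.
#' @param maze_id identifier of the maze navigated.
#'
#' @return object of class `vrgait_session`.
#' @export
session <- function(streams, subject_id = "S01", condition = c("no_wall", "wall"),
                    visit = c("immediate", "delayed"), maze_id = "maze") {
  condition <- match.arg(condition)
  visit <- match.arg(visit)
  ids <- vapply(streams, stream_id, character(1))
  if (length(streams) != 3 || !setequal(ids, TRACKER_IDS)) {
    missing_ids <- setdiff(TRACKER_IDS, ids)
    stop("session requires exactly the three trackers; missing: ",
         paste(missing_ids, collapse = ", "))
  }
  names(streams) <- ids
  streams <- streams[TRACKER_IDS]
  t_all <- unlist(lapply(streams, function(s) range(s$t)))
  out <- structure(
    list(
      subject_id = subject_id, condition = condition, visit = visit,
      maze_id = maze_id, streams = streams,
      start_t = min(t_all), end_t = max(t_all)
    ),
    class = "vrgait_session"
  )
  if (out$end_t <= out$start_t) stop("session must span positive time")
  out
}

#' @export
print.vrgait_session <- function(x, ...) {
  cat("<vrgait session>", x$subject_id, "|", x$condition, "|", x$visit,
      "| maze:", x$maze_id, sprintf("| %.1f s\n", x$end_t - x$start_t))
  invisible(x)
}

#' Write a session bundle to disk
#'
#' The bundle is a directory `<path>/` holding one CSV per tracker
#' (`left_ankle.csv`, `right_ankle.csv`, `navel.csv`, header
#' `t,px,py,pz,qw,qx,qy,qz`) plus `meta.json` with subject, condition,
#' visit, maze id, nominal rate and any recorded dropout gaps.
#'
#' @param session a `vrgait_session`.
#' @param path directory to create/write.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "vrgait_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  for (id in TRACKER_IDS) {
    readr::write_csv(tibble::as_tibble(session$streams[[id]]),
                     file.path(path, paste0(id, ".csv")))
  }
  meta <- list(
    subject_id = session$subject_id,
    condition = session$condition,
    visit = session$visit,
    maze_id = session$maze_id,
    nominal_rate = lapply(session$streams, stream_rate),
    gaps = lapply(session$streams, function(s) as.list(stream_gaps(s)))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a session bundle from disk
#'
#' Inverse of [write_session()]. Validates stream invariants and restores
#' recorded dropout gaps from the sidecar (falling back to detection from
#' timestamps when absent).
#'
#' @param path session bundle directory.
#' @return a `vrgait_session`.
#' @export
load_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  streams <- lapply(TRACKER_IDS, function(id) {
    f <- file.path(path, paste0(id, ".csv"))
    if (!file.exists(f)) stop("missing tracker file for '", id, "' in ", path)
    samples <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    gaps <- meta$gaps[[id]]
    gaps <- if (is.null(gaps)) NULL else tibble::tibble(
      t_start = as.numeric(unlist(gaps$t_start)),
      t_end = as.numeric(unlist(gaps$t_end))
    )
    rate <- meta$nominal_rate[[id]]
    if (is.null(rate)) rate <- 90
    tracker_stream(samples, id, nominal_rate = rate, gaps = gaps)
  })
  session(streams,
          subject_id = meta$subject_id, condition = meta$condition,
          visit = meta$visit, maze_id = meta$maze_id)
}
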