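#' Stride assembly, step classification and spatiotemporal parameters
#'
#' A stride is one gait cycle of one foot: heel strike, ipsilateral
#' toe-off, next ipsilateral heel strike. Five spatiotemporal parameters
#' are computed per stride (length, width, time, velocity, stance phase
#' percentage) and summarised per session as means and coefficients of
#' variation over *straight* strides only; strides whose foot heading
#' rotates past a threshold between the two heel strikes are turn steps
#' and are excluded from summaries, as are strides overlapping tracking
#' dropouts.
#'
#' @name stride-analysis
NULL

GAIT_PARAMS <- c("length", "width", "time", "velocity", "stance_pct")

#' Foot heading from tracker orientation
#'
#' The foot direction is the projection of the tracker's local x-axis
#' (rotated into the global frame) onto the horizontal plane, reported
#' as `atan2(y, x)` in degrees wrapped to `(-180, 180]`. Evaluated at
#' the sample nearest to `t`.
#'
#' @param stream an ankle `vrgait_stream`.
#' @param t time(s) at which to evaluate the heading (seconds).
#' @return heading(s) in degrees; `NA` where the x-axis is within 1e-6 of
#'   vertical (heading undefined).
#' @export
foot_heading <- function(stream, t) {
  idx <- vapply(t, function(ti) which.min(abs(stream$t - ti)), integer(1))
  heading_at_index(stream, idx)
}

heading_at_index <- function(stream, idx) {
  xg <- quat_rotate_x(stream$qw[idx], stream$qx[idx],
                      stream$qy[idx], stream$qz[idx])
  hx <- xg[, "x"]; hy <- xg[, "y"]
  h <- wrap_deg(rad2deg(atan2(hy, hx)))
  h[sqrt(hx^2 + hy^2) < 1e-6] <- NA_real_
  unname(h)
}

#' Classify a step as straight or turn
#'
#' A step is straight when the absolute (wrapped) change in foot
#' direction between two consecutive ipsilateral heel strikes stays
#' strictly below the threshold; a deviation equal to or above the
#' threshold makes it a turn step. The default threshold of 25 degrees
#' is the midpoint of the commonly used 20-30 degree range; see
#' [calibrate_threshold()] for a per-session data-driven choice.
#'
#' @param heading_initial,heading_terminal headings in degrees at the
#'   initial and terminal heel strikes.
#' @param threshold_deg classification threshold in degrees (default 25).
#' @return character vector, `"straight"` or `"turn"` (vectorised).
#' @export
classify_step <- function(heading_initial, heading_terminal,
                          threshold_deg = 25) {
  stopifnot(threshold_deg >= 0, threshold_deg <= 180)
  dev <- ang_diff_deg(heading_terminal, heading_initial)
  ifelse(dev < threshold_deg, "straight", "turn")
}

#' Assemble strides from detected events
#'
#' Builds one stride per (heel strike, toe-off, next heel strike) triple
#' per side and computes, from the ankle positions at the event samples:
#' * `length`: horizontal distance between the ipsilateral heel-strike
#'   positions;
#' * `time`: heel-strike to heel-strike; `velocity = length / time`;
#' * `stance_pct`: 100 x (toe-off - initial heel strike) / time;
#' * `width`: perpendicular horizontal distance from the contralateral
#'   ankle position at its intervening heel strike to the line joining
#'   the two ipsilateral heel-strike positions (`NA` when no intervening
#'   contralateral heel strike exists);
#' * `classification`: [classify_step()] on the foot headings at the two
#'   heel strikes; strides overlapping a dropout gap of any stream, or
#'   with undefined headings, are `"excluded"`.
#'
#' @param events event tibble from [detect_session_events()] (or
#'   [detect_events()] output bound for both sides).
#' @param streams named list with `left_ankle` and `right_ankle` streams
#'   (a full session's `$streams` works).
#' @param threshold_deg straight/turn threshold, see [classify_step()].
#' @return tibble with one row per stride.
#' @export
assemble_strides <- function(events, streams, threshold_deg = 25) {
  gaps <- dplyr::bind_rows(lapply(streams, stream_gaps))
  out <- lapply(c("left", "right"), function(sd) {
    ev <- events[events$side == sd, ]
    ev <- ev[order(ev$t), ]
    contra <- events[events$side != sd & events$kind == "heel_strike", ]
    stream <- streams[[paste0(sd, "_ankle")]]
    cstream <- streams[[paste0(setdiff(c("left", "right"), sd), "_ankle")]]
    hs <- which(ev$kind == "heel_strike")
    rows <- list()
    for (k in hs) {
      if (k + 2 > nrow(ev)) break
      if (ev$kind[k + 1] != "toe_off" || ev$kind[k + 2] != "heel_strike") next
      t0 <- ev$t[k]; t_to <- ev$t[k + 1]; t1 <- ev$t[k + 2]
      i0 <- ev$sample_index[k]; i1 <- ev$sample_index[k + 2]
      p0 <- c(stream$px[i0], stream$py[i0])
      p1 <- c(stream$px[i1], stream$py[i1])
      len <- sqrt(sum((p1 - p0)^2))
      time <- t1 - t0
      h0 <- heading_at_index(stream, i0)
      h1 <- heading_at_index(stream, i1)
      # intervening contralateral heel strike, if any
      cmid <- contra[contra$t > t0 & contra$t < t1, ]
      width <- NA_real_
      if (nrow(cmid) > 0) {
        ci <- cmid$sample_index[1]
        pc <- c(cstream$px[ci], cstream$py[ci])
        width <- point_line_distance(pc, p0, p1)
      }
      in_gap <- nrow(gaps) > 0 &&
        any(gaps$t_start < t1 & gaps$t_end > t0)
      cls <- if (in_gap || is.na(h0) || is.na(h1)) {
        "excluded"
      } else {
        classify_step(h0, h1, threshold_deg)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        side = sd, t_initial = t0, t_toe_off = t_to, t_terminal = t1,
        x_initial = p0[1], y_initial = p0[2],
        x_terminal = p1[1], y_terminal = p1[2],
        length = len, width = width, time = time,
        velocity = len / time,
        stance_pct = 100 * (t_to - t0) / time,
        heading_initial = h0, heading_terminal = h1,
        classification = cls
      )
    }
    dplyr::bind_rows(rows)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$t_initial)
}

#' Perpendicular distance from a point to the line through a and b
#' @keywords internal
point_line_distance <- function(p, a, b) {
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  if (nrm < 1e-9) return(sqrt(sum((p - a)^2)))
  abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / nrm
}

#' Calibrate the straight/turn threshold from straight-line walking
#'
#' Identifies strides that occur on straight segments of the maze's
#' solution path (both heel strikes inside cells of the same straight
#' run, away from corners), measures their foot-direction deviations,
#' and sets the threshold to the maximum observed deviation plus a
#' margin, clamped to the conventional 20-30 degree range. With fewer
#' than `min_strides` calibration strides the default of 25 degrees is
#' returned with a warning.
#'
#' @param session a `vrgait_session`.
#' @param maze the `vrgait_maze` navigated.
#' @param margin_deg safety margin added to the largest observed
#'   straight-walking deviation (default 5).
#' @param min_strides minimum calibration strides required (default 5).
#' @param ... passed to [detect_events()].
#' @return threshold in degrees, in `[20, 30]`.
#' @export
calibrate_threshold <- function(session, maze, margin_deg = 5,
                                min_strides = 5, ...) {
  events <- detect_session_events(session, ...)
  strides <- assemble_strides(events, session$streams)
  if (nrow(strides) == 0) {
    warning("no strides available for calibration; using default 25 degrees")
    return(25)
  }
  run_of <- straight_run_lookup(maze)
  run_initial <- run_of(strides$x_initial, strides$y_initial)
  run_terminal <- run_of(strides$x_terminal, strides$y_terminal)
  cal <- !is.na(run_initial) & !is.na(run_terminal) &
    run_initial == run_terminal &
    !is.na(strides$heading_initial) & !is.na(strides$heading_terminal)
  if (sum(cal) < min_strides) {
    warning("fewer than ", min_strides,
            " straight-segment strides; using default 25 degrees")
    return(25)
  }
  dev <- ang_diff_deg(strides$heading_terminal[cal],
                      strides$heading_initial[cal])
  min(30, max(20, max(dev) + margin_deg))
}

#' Map horizontal points to straight-run ids of the solution path
#'
#' Returns a function of (x, y) giving the run id of the containing path
#' cell, or `NA` for corner cells and off-path cells. A run is a maximal
#' sequence of path cells traversed without a direction change; corner
#' cells (where the path turns) belong to no run.
#' @keywords internal
straight_run_lookup <- function(maze) {
  path <- solution_path(maze)
  n <- nrow(path)
  dirs <- cbind(diff(path$col), diff(path$row))
  corner <- rep(FALSE, n)
  if (n > 2) {
    for (i in 2:(n - 1)) {
      corner[i] <- any(dirs[i - 1, ] != dirs[i, ])
    }
  }
  run <- cumsum(corner)            # increments at corners
  run[corner] <- NA                # corner cells belong to no run
  ids <- cell_id(path$row, path$col, maze$cols)
  run_by_cell <- rep(NA_real_, maze$rows * maze$cols)
  run_by_cell[ids] <- run
  function(x, y) {
    cells <- point_cell(x, y, maze)
    ok <- cells[, 1] >= 1 & cells[, 1] <= maze$rows &
      cells[, 2] >= 1 & cells[, 2] <= maze$cols
    out <- rep(NA_real_, length(x))
    out[ok] <- run_by_cell[cell_id(cells[ok, 1], cells[ok, 2], maze$cols)]
    out
  }
}

#' Coefficient of variation (sample SD / mean)
#'
#' Uses the n-1 (sample) standard deviation; returns 0 for a constant
#' series and `NA` for fewer than two values.
#'
#' @param x numeric vector (NAs dropped).
#' @return nonnegative scalar.
#' @export
cov_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / mean(x)
}

#' Summarise a session's straight strides
#'
#' Means and coefficients of variation of the five spatiotemporal
#' parameters over straight strides only, plus stride counts by class.
#' With fewer than two straight strides the summary is flagged
#' `insufficient` and the CoVs are `NA`.
#'
#' @param strides stride tibble from [assemble_strides()].
#' @param completion_time optional completion time in seconds to carry
#'   into the summary row.
#' @return one-row tibble: counts, `<param>_mean` and `<param>_cov` for
#'   the five parameters, `completion_time`, `insufficient`.
#' @export
summarize_session <- function(strides, completion_time = NA_real_) {
  straight <- strides[strides$classification == "straight", ]
  n_straight <- nrow(straight)
  stats_row <- lapply(GAIT_PARAMS, function(p) {
    v <- straight[[p]]
    out <- tibble::tibble(mean = if (n_straight >= 1) mean(v, na.rm = TRUE) else NA_real_,
                          cov = if (n_straight >= 2) cov_of(v) else NA_real_)
    names(out) <- paste0(p, c("_mean", "_cov"))
    out
  })
  dplyr::bind_cols(
    tibble::tibble(
      n_strides = nrow(strides),
      n_straight = n_straight,
      n_turn = sum(strides$classification == "turn"),
      n_excluded = sum(strides$classification == "excluded")
    ),
    dplyr::bind_cols(stats_row),
    tibble::tibble(
      completion_time = as.numeric(completion_time),
      insufficient = n_straight < 2
    )
  )
}
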