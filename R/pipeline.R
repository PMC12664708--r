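#' End-to-end session analysis
#'
#' Runs the full chain on one session: gait event detection on both
#' ankle shank-angle waveforms, stride assembly and straight/turn
#' classification, spatiotemporal summaries over straight strides,
#' per-cycle balance metrics (XCoM-based margin of stability, CoM
#' mediolateral displacement) and, when a maze is supplied, the
#' completion time and an optionally calibrated classification
#' threshold.
#'
#' @param session a `vrgait_session`.
#' @param maze optional `vrgait_maze` (enables completion time and
#'   threshold auto-calibration).
#' @param threshold_deg straight/turn threshold in degrees, or `"auto"`
#'   to calibrate from straight-segment strides (requires `maze`).
#' @param ... passed to [detect_events()].
#' @return list of class `vrgait_analysis`: `events`, `strides`,
#'   `cycles`, `summary` (one-row tibble joining gait and balance
#'   summaries plus `completion_time` and the threshold used).
#' @export
analyze_session <- function(session, maze = NULL, threshold_deg = 25, ...) {
  if (identical(threshold_deg, "auto")) {
    if (is.null(maze)) stop("threshold 'auto' requires a maze")
    threshold_deg <- calibrate_threshold(session, maze, ...)
  }
  events <- detect_session_events(session, ...)
  strides <- assemble_strides(events, session$streams,
                              threshold_deg = threshold_deg)
  ct <- if (is.null(maze)) NA_real_ else {
    suppressWarnings(as.numeric(completion_time(session, maze)))
  }
  gait <- summarize_session(strides, completion_time = ct)
  cycles <- if (nrow(strides) > 0) analyze_balance(session, strides) else
    tibble::tibble(side = character(), t_hs = double(),
                   classification = character(),
                   mos_ml = double(), com_ml = double())
  bal <- summarize_balance(cycles)
  summary <- dplyr::bind_cols(
    tibble::tibble(subject_id = session$subject_id,
                   condition = session$condition, visit = session$visit),
    gait,
    dplyr::rename(bal, balance_insufficient = "insufficient")
  )
  summary$threshold_deg <- threshold_deg
  structure(
    list(events = events, strides = strides, cycles = cycles,
         summary = summary),
    class = "vrgait_analysis"
  )
}

#' @export
print.vrgait_analysis <- function(x, ...) {
  cat("<session analysis>", nrow(x$strides), "strides (",
      sum(x$strides$classification == "straight"), "straight )\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.vrgait_analysis <- function(x, ...) x$summary

#' Analyse all sessions of a simulated study into a long outcome table
#'
#' Maps [analyze_session()] over the `sessions` element of a
#' [simulate_study()] result (kinematics = TRUE) and binds the one-row
#' summaries, giving a long table suitable for
#' [condition_visit_mixed_model()] and [build_association_table()].
#'
#' @param sessions list of `simulate_walk()` results with `$meta`/`$maze`.
#' @param threshold_deg passed to [analyze_session()].
#' @return tibble of per-session summaries.
#' @export
analyze_sessions <- function(sessions, threshold_deg = 25) {
  purrr::map_dfr(sessions, function(s) {
    tidy(analyze_session(s$session, maze = s$maze,
                         threshold_deg = threshold_deg))
  })
}
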