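#' Synthetic maze walker and cohort simulator
#'
#' Generates tracker streams of a walker traversing a maze with fully
#' known ground truth (events, per-stride parameters, CoM trajectory),
#' plus synthetic cohorts of covariates and cognitive scores with
#' optional planted gait-cognition effects. The walker lays heel strikes
#' along the maze solution path with configurable stride statistics,
#' builds a shank-angle waveform whose minima/maxima fall exactly at the
#' ground-truth heel strikes/toe-offs, and oscillates the navel tracker
#' mediolaterally about the path with a configurable sway amplitude.
#'
#' @name synthetic-walker
NULL

#' Gait profile for the synthetic walker
#'
#' @param stride_length_mean,stride_length_sd stride length in metres.
#' @param stride_time_mean,stride_time_sd stride duration in seconds.
#' @param stride_width_mean,stride_width_sd stride width in metres.
#' @param stance_fraction fraction of the stride spent in stance (0-1).
#' @param com_sway_amp mediolateral CoM sway amplitude in metres.
#' @param turn_slowdown_factor multiplicative slowdown (> 1) applied to
#'   steps that cross a maze corner.
#' @param noise_sd_pos tracker position noise SD in metres.
#' @param noise_sd_angle orientation noise SD in degrees.
#' @param dropout_rate expected tracking dropouts per minute.
#' @param seed RNG seed for the walk.
#' @return list of class `vrgait_profile`.
#' @export
gait_profile <- function(stride_length_mean = 1.00, stride_length_sd = 0.05,
                         stride_time_mean = 1.05, stride_time_sd = 0.05,
                         stride_width_mean = 0.12, stride_width_sd = 0.015,
                         stance_fraction = 0.62, com_sway_amp = 0.04,
                         turn_slowdown_factor = 1.3,
                         noise_sd_pos = 0.003, noise_sd_angle = 1.0,
                         dropout_rate = 0, seed = 1) {
  p <- list(
    stride_length_mean = stride_length_mean, stride_length_sd = stride_length_sd,
    stride_time_mean = stride_time_mean, stride_time_sd = stride_time_sd,
    stride_width_mean = stride_width_mean, stride_width_sd = stride_width_sd,
    stance_fraction = stance_fraction, com_sway_amp = com_sway_amp,
    turn_slowdown_factor = turn_slowdown_factor,
    noise_sd_pos = noise_sd_pos, noise_sd_angle = noise_sd_angle,
    dropout_rate = dropout_rate, seed = seed
  )
  means <- c(p$stride_length_mean, p$stride_time_mean, p$stride_width_mean)
  sds <- c(p$stride_length_sd, p$stride_time_sd, p$stride_width_sd)
  if (any(means <= 0)) stop("stride means must be positive")
  if (any(sds < 0)) stop("stride SDs must be non-negative")
  if (p$stance_fraction <= 0 || p$stance_fraction >= 1) {
    stop("stance_fraction must be in (0, 1)")
  }
  if (p$com_sway_amp < 0 || p$noise_sd_pos < 0 || p$noise_sd_angle < 0 ||
      p$dropout_rate < 0) {
    stop("amplitudes, noise levels and dropout rate must be non-negative")
  }
  structure(p, class = "vrgait_profile")
}

#' Default gait profiles per wall condition
#'
#' The wall condition is modelled with smaller and slower strides of
#' larger relative variability and with less mediolateral body sway than
#' the no-wall condition, reflecting the greater cognitive load of
#' navigating without a single vantage point.
#'
#' @param condition `"no_wall"` or `"wall"`.
#' @param seed RNG seed stored in the profile.
#' @return a `vrgait_profile`.
#' @export
default_profile <- function(condition = c("no_wall", "wall"), seed = 1) {
  condition <- match.arg(condition)
  if (condition == "no_wall") {
    gait_profile(
      stride_length_mean = 1.00, stride_length_sd = 0.05,
      stride_time_mean = 1.05, stride_time_sd = 0.05,
      stride_width_mean = 0.12, stride_width_sd = 0.015,
      stance_fraction = 0.62, com_sway_amp = 0.040,
      turn_slowdown_factor = 1.3, seed = seed
    )
  } else {
    gait_profile(
      stride_length_mean = 0.88, stride_length_sd = 0.062,
      stride_time_mean = 1.18, stride_time_sd = 0.083,
      stride_width_mean = 0.10, stride_width_sd = 0.016,
      stance_fraction = 0.65, com_sway_amp = 0.030,
      turn_slowdown_factor = 1.5, seed = seed
    )
  }
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    tries <- tries + 1
  }
  out[out < lo] <- lo; out[out > hi] <- hi
  out
}

#' Simulate a walk through a maze
#'
#' Lays alternating footfalls along the maze solution path with stride
#' statistics drawn from the profile, slows and shortens steps that
#' cross corners by `turn_slowdown_factor`, and emits three 90 Hz
#' tracker streams. Ankle quaternions encode a shank-angle waveform
#' whose local minima coincide exactly with ground-truth heel strikes
#' and maxima with toe-offs (a raised-cosine in a monotone cycle-phase
#' warp, so extrema are locally symmetric in time). The navel stream
#' follows the path with a mediolateral sinusoidal sway of amplitude
#' `com_sway_amp`, zero at each heel strike.
#'
#' Corners are negotiated with pivot steps: the pivoting foot lands on
#' the corner with its heading rotated toward the new direction, so
#' every stride spanning a corner shows a foot-direction deviation well
#' above the straight/turn threshold and is classifiable as a turn step
#' from the tracker data alone, while within-segment strides carry
#' exactly the drawn stride statistics.
#'
#' @param maze a `vrgait_maze`.
#' @param profile a `vrgait_profile`.
#' @param condition,visit session labels.
#' @param subject_id subject label for the session.
#' @param rate sampling rate in Hz (default 90).
#' @param class_threshold_deg threshold used for the ground-truth
#'   straight/turn stride labels (default 25).
#' @return list with `session` (a `vrgait_session`) and `truth` (list:
#'   `events`, `strides`, `com`, `completion_time`, `profile`).
#' @export
simulate_walk <- function(maze, profile, condition = "no_wall",
                          visit = "immediate", subject_id = "sim",
                          rate = 90, class_threshold_deg = 25) {
  stopifnot(inherits(maze, "vrgait_maze"), inherits(profile, "vrgait_profile"))
  if (profile$stride_length_mean > 2 * maze$block_size) {
    stop("stride_length_mean exceeds twice the block size; ",
         "the walker cannot negotiate corners")
  }
  with_preserved_seed(profile$seed, {
    sim_walk_impl(maze, profile, condition, visit, subject_id, rate,
                  class_threshold_deg)
  })
}

sim_walk_impl <- function(maze, profile, condition, visit, subject_id, rate,
                          class_threshold_deg) {
  b <- maze$block_size
  path <- solution_path(maze)
  pxy <- cbind(path$x, path$y)
  seg <- diff(pxy)
  seg_len <- sqrt(rowSums(seg^2))
  s_knots <- c(0, cumsum(seg_len))
  L <- s_knots[length(s_knots)]
  # arclengths of corners (direction changes at interior waypoints)
  is_corner <- if (nrow(seg) >= 2) {
    c(FALSE, rowSums(abs(diff(seg))) > 1e-9, FALSE)
  } else {
    rep(FALSE, nrow(seg) + 1)
  }
  corner_s <- s_knots[is_corner]

  dir_last <- seg[nrow(seg), ] / seg_len[nrow(seg)]
  pos_at_s <- function(s) {
    sc <- pmin(pmax(s, 0), L)
    out <- cbind(stats::approx(s_knots, pxy[, 1], sc)$y,
                 stats::approx(s_knots, pxy[, 2], sc)$y)
    over <- which(s > L)   # walker may overshoot past the exit centre
    if (length(over) > 0) {
      out[over, 1] <- pxy[nrow(pxy), 1] + (s[over] - L) * dir_last[1]
      out[over, 2] <- pxy[nrow(pxy), 2] + (s[over] - L) * dir_last[2]
    }
    out
  }
  dir_at_s <- function(s) {
    i <- pmin(findInterval(pmin(pmax(s, 0), L - 1e-9), s_knots), nrow(seg))
    i <- pmax(i, 1)
    seg[i, , drop = FALSE] / seg_len[i]
  }
  heading_at_s <- function(s) {
    d <- dir_at_s(s)
    rad2deg(atan2(d[, 2], d[, 1]))
  }
  # bisector heading, turn sense and grid row of each corner; the pivot
  # heading offset alternates with the corner's row parity, which keeps
  # the foot-direction deviation of every corner-spanning stride >= 30
  # degrees even in staircase and Z-jog corner patterns
  corner_idx <- which(is_corner)
  corner_bis <- corner_sense <- corner_delta <- numeric(length(corner_s))
  for (k in seq_along(corner_s)) {
    din <- dir_at_s(corner_s[k] - 1e-6)
    dout <- dir_at_s(corner_s[k] + 1e-6)
    v <- din + dout
    corner_bis[k] <- rad2deg(atan2(v[2], v[1]))
    corner_sense[k] <- sign(din[1] * dout[2] - din[2] * dout[1])
    corner_delta[k] <- 15 * (-1)^(path$row[corner_idx[k]])
  }

  # ---- footfalls along the path ---------------------------------------
  # Corner negotiation uses pivot steps: any step that would land within
  # 0.1 m of the next corner (or beyond it) lands exactly on the corner
  # with the foot rotated toward the new direction, so every stride that
  # spans a corner shows a foot-direction deviation well above the
  # straight/turn threshold, and within-segment strides carry exactly
  # the drawn stride statistics.
  sf <- 0.15; tf <- 0.8
  headf <- heading_at_s(0.15)
  pivot <- FALSE
  s <- 0.15; t <- 0.8
  last_piv <- FALSE
  repeat {
    step_len <- rnorm_trunc(1, profile$stride_length_mean / 2,
                            profile$stride_length_sd / sqrt(2), lo = 0.12)
    step_time <- rnorm_trunc(1, profile$stride_time_mean / 2,
                             profile$stride_time_sd / sqrt(2), lo = 0.15)
    nxt <- which(corner_s > s + 1e-9)
    c_idx <- if (length(nxt) > 0) nxt[1] else NA_integer_
    # a pivot chains straight into the next pivot across one-block legs,
    # so no lone intermediate footfall can sit between adjacent corners
    force_chain <- last_piv && !is.na(c_idx) &&
      (corner_s[c_idx] - s) <= 0.7
    if (!is.na(c_idx) &&
        (force_chain || s + step_len > corner_s[c_idx] - 0.1)) {
      # pivot landing on the corner
      s_new <- corner_s[c_idx]
      h_new <- corner_bis[c_idx] + corner_sense[c_idx] * corner_delta[c_idx]
      t_new <- t + step_time * profile$turn_slowdown_factor
      is_piv <- TRUE
    } else {
      s_new <- s + step_len
      h_new <- heading_at_s(min(s_new, L - 1e-6))
      t_new <- t + step_time
      is_piv <- FALSE
    }
    sf <- c(sf, s_new); tf <- c(tf, t_new)
    headf <- c(headf, h_new); pivot <- c(pivot, is_piv)
    s <- s_new; t <- t_new
    last_piv <- is_piv
    if (s >= L) break   # first footfall at/past the exit centre ends the walk
  }
  m <- length(sf)
  if (m < 6) stop("maze path too short for the requested stride length")
  sides <- rep(c("left", "right"), length.out = m)
  side_sign <- ifelse(sides == "left", 1, -1)
  wf <- rnorm_trunc(m, profile$stride_width_mean,
                    profile$stride_width_sd, lo = 0.01)

  base_pos <- pos_at_s(sf)
  dirs <- dir_at_s(sf)
  normals <- cbind(-dirs[, 2], dirs[, 1])          # left of travel
  foot_pos <- base_pos + normals * (side_sign * wf / 2)
  head_deg <- wrap_deg(headf)

  # ---- ground-truth events and strides --------------------------------
  # toe-off of a foot at stance_fraction of the way to its next footfall
  stance <- profile$stance_fraction
  to_time <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    if (k + 2 <= m) to_time[k] <- tf[k] + stance * (tf[k + 2] - tf[k])
  }
  # the last footfall of each side has no later ipsilateral footfall;
  # give it a nominal toe-off so the waveform ends with a full cycle
  for (sd_name in c("left", "right")) {
    k <- max(which(sides == sd_name))
    if (is.na(to_time[k]) && k < m) {
      to_time[k] <- tf[k] + stance * profile$stride_time_mean
    }
  }
  ev_rows <- list()
  tr_rows <- list()
  for (k in seq_len(m)) {
    ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
      side = sides[k], kind = "heel_strike", t = tf[k])
    if (!is.na(to_time[k])) {
      ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
        side = sides[k], kind = "toe_off", t = to_time[k])
    }
    if (k + 2 <= m) {
      len <- sqrt(sum((foot_pos[k + 2, ] - foot_pos[k, ])^2))
      tm <- tf[k + 2] - tf[k]
      dev <- ang_diff_deg(head_deg[k + 2], head_deg[k])
      width <- point_line_distance(foot_pos[k + 1, ],
                                   foot_pos[k, ], foot_pos[k + 2, ])
      tr_rows[[length(tr_rows) + 1]] <- tibble::tibble(
        side = sides[k], t_initial = tf[k], t_terminal = tf[k + 2],
        length = len, width = width, time = tm, velocity = len / tm,
        stance_pct = 100 * stance,
        classification = if (dev < class_threshold_deg) "straight" else "turn",
        crosses_corner = any(corner_s > sf[k] & corner_s <= sf[k + 2])
      )
    }
  }
  truth_events <- dplyr::arrange(dplyr::bind_rows(ev_rows), .data$t)
  truth_strides <- dplyr::bind_rows(tr_rows)

  # ---- sample grid -----------------------------------------------------
  t_end <- max(tf) + 0.6
  tg <- seq(0, t_end, by = 1 / rate)
  n <- length(tg)

  ankle_stream <- function(side_name) {
    idx <- which(sides == side_name)
    tfs <- tf[idx]; pfs <- foot_pos[idx, , drop = FALSE]
    tos <- to_time[idx]
    mm <- length(idx)
    j <- findInterval(tg, tfs)
    px <- py <- pz <- numeric(n)
    for (i in seq_len(n)) {
      jj <- j[i]
      if (jj < 1) {
        px[i] <- pfs[1, 1]; py[i] <- pfs[1, 2]; pz[i] <- 0.10
      } else if (jj >= mm || is.na(tos[jj]) && jj == mm) {
        px[i] <- pfs[mm, 1]; py[i] <- pfs[mm, 2]; pz[i] <- 0.10
      } else if (is.na(tos[jj]) || tg[i] <= tos[jj]) {
        px[i] <- pfs[jj, 1]; py[i] <- pfs[jj, 2]; pz[i] <- 0.10
      } else {
        u <- (tg[i] - tos[jj]) / (tfs[jj + 1] - tos[jj])
        sm <- u * u * (3 - 2 * u)
        px[i] <- pfs[jj, 1] + sm * (pfs[jj + 1, 1] - pfs[jj, 1])
        py[i] <- pfs[jj, 2] + sm * (pfs[jj + 1, 2] - pfs[jj, 2])
        pz[i] <- 0.10 + 0.06 * sin(pi * u)
      }
    }
    # cycle phase: 0 at HS_1, 0.5 at TO_1, 1 at HS_2, ... (monotone C1
    # warp, so the cosine's extrema sit exactly on the true events and
    # are locally symmetric in time); phantom half-cycle knots beyond
    # the first and last event make the boundary events interior
    # extrema of the waveform
    knot_t <- as.numeric(rbind(tfs, tos))
    knot_phi <- as.numeric(rbind(seq_len(mm) - 1, seq_len(mm) - 0.5))
    keep <- !is.na(knot_t)
    knot_t <- knot_t[keep]; knot_phi <- knot_phi[keep]
    half <- 0.45 * profile$stride_time_mean
    knot_t <- c(knot_t[1] - half, knot_t, knot_t[length(knot_t)] + half)
    knot_phi <- c(knot_phi[1] - 0.5, knot_phi,
                  knot_phi[length(knot_phi)] + 0.5)
    spl <- stats::splinefun(knot_t, knot_phi, method = "hyman")
    phi <- spl(pmin(pmax(tg, knot_t[1]), knot_t[length(knot_t)]))
    alpha <- 70 + 25 * (1 - cos(2 * pi * phi)) / 2

    # heading: hold during stance, linear during swing (unwrapped)
    hd <- head_deg[idx]
    hu <- cumsum(c(hd[1], wrap_deg(diff(hd))))
    heading <- numeric(n)
    for (i in seq_len(n)) {
      jj <- j[i]
      if (jj < 1) heading[i] <- hu[1]
      else if (jj >= mm) heading[i] <- hu[mm]
      else if (is.na(tos[jj]) || tg[i] <= tos[jj]) heading[i] <- hu[jj]
      else {
        u <- (tg[i] - tos[jj]) / (tfs[jj + 1] - tos[jj])
        heading[i] <- hu[jj] + u * (hu[jj + 1] - hu[jj])
      }
    }

    if (profile$noise_sd_angle > 0) {
      alpha <- alpha + stats::rnorm(n, 0, profile$noise_sd_angle)
      heading <- heading + stats::rnorm(n, 0, profile$noise_sd_angle)
      alpha <- pmin(179.5, pmax(0.5, alpha))
    }
    q <- quat_mul(quat_axis(deg2rad(heading), "z"),
                  quat_axis(deg2rad(alpha - 90), "y"))
    if (profile$noise_sd_pos > 0) {
      px <- px + stats::rnorm(n, 0, profile$noise_sd_pos)
      py <- py + stats::rnorm(n, 0, profile$noise_sd_pos)
      pz <- pz + stats::rnorm(n, 0, profile$noise_sd_pos)
    }
    tibble::tibble(t = tg, px = px, py = py, pz = pz,
                   qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  }

  left_df <- ankle_stream("left")
  right_df <- ankle_stream("right")

  # ---- navel / CoM -----------------------------------------------------
  s_com <- stats::approx(tf, sf, tg, rule = 2)$y
  jall <- findInterval(tg, tf)
  sway <- numeric(n)
  for (i in seq_len(n)) {
    jj <- jall[i]
    if (jj >= 1 && jj < m) {
      u <- (tg[i] - tf[jj]) / (tf[jj + 1] - tf[jj])
      sway[i] <- profile$com_sway_amp * side_sign[jj] * sin(pi * u)
    }
  }
  base_com <- pos_at_s(s_com)
  dcom <- dir_at_s(s_com)
  ncom <- cbind(-dcom[, 2], dcom[, 1])
  com_xy <- base_com + ncom * sway
  truth_com <- tibble::tibble(t = tg, x = com_xy[, 1], y = com_xy[, 2])

  qn <- quat_axis(deg2rad(-90), "y")  # local x-axis points up
  navel_df <- tibble::tibble(
    t = tg, px = com_xy[, 1], py = com_xy[, 2], pz = 1.05,
    qw = qn[1, 1], qx = qn[1, 2], qy = qn[1, 3], qz = qn[1, 4]
  )
  if (profile$noise_sd_pos > 0) {
    navel_df$px <- navel_df$px + stats::rnorm(n, 0, profile$noise_sd_pos)
    navel_df$py <- navel_df$py + stats::rnorm(n, 0, profile$noise_sd_pos)
    navel_df$pz <- navel_df$pz + stats::rnorm(n, 0, profile$noise_sd_pos)
  }

  apply_dropouts <- function(df) {
    if (profile$dropout_rate <= 0) return(df)
    n_drop <- stats::rpois(1, profile$dropout_rate * t_end / 60)
    if (n_drop == 0) return(df)
    for (k in seq_len(n_drop)) {
      start <- stats::runif(1, 0.5, t_end - 1)
      dur <- stats::runif(1, 0.2, 0.6)
      df <- df[df$t < start | df$t >= start + dur, ]
    }
    df
  }

  streams <- list(
    tracker_stream(apply_dropouts(left_df), "left_ankle", nominal_rate = rate),
    tracker_stream(apply_dropouts(right_df), "right_ankle", nominal_rate = rate),
    tracker_stream(apply_dropouts(navel_df), "navel", nominal_rate = rate)
  )
  sess <- session(streams, subject_id = subject_id, condition = condition,
                  visit = visit, maze_id = maze$maze_id)

  # ground-truth completion: time for the CoM to enter the exit cell
  s_exit <- L - b / 2
  i_exit <- which(s_com >= s_exit)[1]
  completion <- if (is.na(i_exit)) NA_real_ else tg[i_exit] - tg[1]

  list(
    session = sess,
    truth = list(
      events = truth_events,
      strides = truth_strides,
      footfalls = tibble::tibble(
        side = sides, t = tf, s = sf, x = foot_pos[, 1], y = foot_pos[, 2],
        heading = head_deg, pivot = pivot
      ),
      com = truth_com,
      completion_time = completion,
      profile = profile
    )
  )
}

#' F1 score of detected gait events against ground truth
#'
#' Greedy one-to-one matching of detected to true events of the same
#' side and kind within a time window.
#'
#' @param detected,truth event tibbles with columns `side`, `kind`, `t`.
#' @param window_s matching window in seconds (default 0.05).
#' @return list with `f1`, `precision`, `recall`, `n_matched` and the
#'   maximum absolute time error of matched events (`max_dt`).
#' @export
event_detection_f1 <- function(detected, truth, window_s = 0.05) {
  n_match <- 0L
  max_dt <- 0
  for (sd in unique(truth$side)) {
    for (kd in unique(truth$kind)) {
      tt <- sort(truth$t[truth$side == sd & truth$kind == kd])
      dt <- sort(detected$t[detected$side == sd & detected$kind == kd])
      used <- rep(FALSE, length(dt))
      for (ti in tt) {
        cand <- which(!used & abs(dt - ti) <= window_s)
        if (length(cand) > 0) {
          pick <- cand[which.min(abs(dt[cand] - ti))]
          used[pick] <- TRUE
          n_match <- n_match + 1L
          max_dt <- max(max_dt, abs(dt[pick] - ti))
        }
      }
    }
  }
  precision <- if (nrow(detected) > 0) n_match / nrow(detected) else 0
  recall <- if (nrow(truth) > 0) n_match / nrow(truth) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(f1 = f1, precision = precision, recall = recall,
       n_matched = n_match, max_dt = max_dt)
}
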