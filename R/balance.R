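#' Extrapolated centre of mass and margin of stability
#'
#' The body is modelled as an inverted pendulum: with CoM horizontal
#' position `u` (approximated by the navel tracker), CoM velocity
#' `u_dot`, and eigenfrequency `omega0 = sqrt(g / l)` (leg length `l` =
#' vertical navel-ankle tracker distance, `g = 9.8 m/s^2`), the
#' extrapolated centre of mass is
#'
#'   `XCoM = u + u_dot / omega0`.
#'
#' The base of support (BoS) is a rectangle covering both feet, aligned
#' with the step's anterior-posterior (AP) axis; the mediolateral margin
#' of stability `MoS_ml` is the signed distance along the mediolateral
#' (ML) axis from the XCoM to the nearer ML border of the BoS (positive
#' inside). Per gait cycle, the direction of progression (DoP) is the
#' vector from the CoM at the initial heel strike to the CoM at the
#' terminal heel strike, and `CoM_ml` is the maximum absolute deviation
#' of the CoM from the DoP line within the cycle.
#'
#' @name balance
NULL

#' Inverted-pendulum parameters
#'
#' @param l leg length in metres (> 0).
#' @param g gravitational acceleration in m/s^2 (default 9.8).
#' @return list with `l`, `g` and `omega0 = sqrt(g / l)`.
#' @export
pendulum_params <- function(l, g = 9.8) {
  if (!is.finite(l) || l <= 0) stop("leg length must be positive, got ", l)
  list(l = l, g = g, omega0 = sqrt(g / l))
}

#' Extrapolated centre of mass
#'
#' @param u CoM horizontal position, length-2 vector or n x 2 matrix (m).
#' @param u_dot CoM horizontal velocity, same shape (m/s).
#' @param params from [pendulum_params()].
#' @return XCoM position(s), same shape as `u`.
#' @export
xcom <- function(u, u_dot, params) {
  u + u_dot / params$omega0
}

#' Estimate CoM horizontal velocity from the navel stream
#'
#' Central finite differences of horizontal position on the native
#' timestamps (one-sided at the endpoints), followed by a zero-phase
#' low-pass Butterworth filter.
#'
#' @param navel_stream a `vrgait_stream`.
#' @param cutoff_hz low-pass cutoff (default 6 Hz); `NA` disables
#'   filtering.
#' @param order Butterworth order (default 2).
#' @return tibble with columns `t`, `vx`, `vy`.
#' @export
estimate_com_velocity <- function(navel_stream, cutoff_hz = 6, order = 2) {
  t <- navel_stream$t
  n <- length(t)
  if (n < 3) stop("need at least 3 samples to estimate velocity")
  diff_central <- function(p) {
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    v[1] <- (p[2] - p[1]) / (t[2] - t[1])
    v[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    v
  }
  vx <- diff_central(navel_stream$px)
  vy <- diff_central(navel_stream$py)
  rate <- stream_rate(navel_stream)
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  if (is.finite(cutoff_hz) && cutoff_hz < rate / 2 && n > 3 * (order + 1)) {
    bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
    # reflect-pad before the zero-phase filter to avoid edge transients
    np <- min(n - 1, 3 * ceiling(rate / cutoff_hz))
    pad <- function(v) {
      vp <- c(2 * v[1] - v[(np + 1):2], v, 2 * v[n] - v[(n - 1):(n - np)])
      as.numeric(signal::filtfilt(bf, vp))[(np + 1):(np + n)]
    }
    vx <- pad(vx)
    vy <- pad(vy)
  }
  tibble::tibble(t = t, vx = vx, vy = vy)
}

#' Leg length from tracker heights
#'
#' Median over a time window of the vertical distance between the navel
#' tracker and an ankle tracker; the median is robust to the swing-phase
#' excursions of the ankle.
#'
#' @param ankle_stream,navel_stream `vrgait_stream`s.
#' @param window optional `c(t_min, t_max)`; default is the full overlap.
#' @return leg length in metres.
#' @export
leg_length <- function(ankle_stream, navel_stream, window = NULL) {
  if (is.null(window)) {
    window <- c(max(min(ankle_stream$t), min(navel_stream$t)),
                min(max(ankle_stream$t), max(navel_stream$t)))
  }
  if (window[2] <= window[1]) stop("streams do not overlap in the window")
  a <- ankle_stream[ankle_stream$t >= window[1] & ankle_stream$t <= window[2], ]
  nv <- navel_stream[navel_stream$t >= window[1] & navel_stream$t <= window[2], ]
  if (nrow(a) == 0 || nrow(nv) == 0) stop("no samples in the window")
  # match navel samples to nearest ankle samples in time
  idx <- findInterval(nv$t, a$t, all.inside = TRUE)
  use_next <- abs(a$t[pmin(idx + 1, nrow(a))] - nv$t) < abs(a$t[idx] - nv$t)
  idx[use_next] <- pmin(idx[use_next] + 1, nrow(a))
  l <- stats::median(nv$pz - a$pz[idx])
  if (l <= 0) stop("navel tracker below ankle tracker: leg length ", l,
                   " m; check stream assignment")
  l
}

#' Base-of-support rectangle at a heel strike
#'
#' Each foot's footprint is a `foot_length` x `foot_width` rectangle
#' centred at its ankle-tracker position and oriented along its foot
#' heading; the BoS is the smallest rectangle aligned with the step
#' frame (AP axis, ML axis) containing both footprints. When `ap_axis`
#' is not supplied, the step AP axis is taken as the circular mean of
#' the two foot headings.
#'
#' @param left_pos,right_pos horizontal ankle positions, length-2 (m).
#' @param left_heading,right_heading foot headings in degrees.
#' @param ap_axis optional length-2 unit vector: the step's AP direction.
#' @param foot_length,foot_width nominal footprint dimensions in metres
#'   (defaults 0.25 and 0.10).
#' @return list of class `vrgait_bos`: `center` (2-vector),
#'   `ap_axis`, `ml_axis` (orthonormal 2-vectors), `half_extents`
#'   (length-2: AP, ML).
#' @export
base_of_support <- function(left_pos, right_pos, left_heading, right_heading,
                            ap_axis = NULL, foot_length = 0.25,
                            foot_width = 0.10) {
  if (is.null(ap_axis)) {
    h <- deg2rad(c(left_heading, right_heading))
    ap_axis <- c(mean(cos(h)), mean(sin(h)))
    nrm <- sqrt(sum(ap_axis^2))
    if (nrm < 1e-9) ap_axis <- c(cos(h[1]), sin(h[1])) else ap_axis <- ap_axis / nrm
  } else {
    ap_axis <- ap_axis / sqrt(sum(ap_axis^2))
  }
  ml_axis <- c(-ap_axis[2], ap_axis[1])
  corners <- rbind(
    footprint_corners(left_pos, left_heading, foot_length, foot_width),
    footprint_corners(right_pos, right_heading, foot_length, foot_width)
  )
  a <- corners %*% ap_axis
  m <- corners %*% ml_axis
  center <- mean(range(a)) * ap_axis + mean(range(m)) * ml_axis
  structure(
    list(center = as.numeric(center), ap_axis = ap_axis, ml_axis = ml_axis,
         half_extents = c(diff(range(a)) / 2, diff(range(m)) / 2)),
    class = "vrgait_bos"
  )
}

#' Corners of one foot's footprint rectangle
#' @keywords internal
footprint_corners <- function(pos, heading_deg, foot_length, foot_width) {
  th <- deg2rad(heading_deg)
  fwd <- c(cos(th), sin(th))
  lat <- c(-sin(th), cos(th))
  hl <- foot_length / 2; hw <- foot_width / 2
  t(vapply(list(c(hl, hw), c(hl, -hw), c(-hl, hw), c(-hl, -hw)),
           function(s) pos + s[1] * fwd + s[2] * lat, numeric(2)))
}

#' Signed mediolateral margin of stability
#'
#' Signed distance along the ML axis from the XCoM to the nearer ML
#' border of the base of support: positive when the XCoM lies inside the
#' ML extent of the BoS, negative when outside.
#'
#' @param xcom_point XCoM horizontal position, length-2 (m).
#' @param bos a `vrgait_bos` from [base_of_support()].
#' @param ml_axis optional override of the ML axis (unit 2-vector);
#'   defaults to the BoS's own.
#' @return signed margin in metres.
#' @export
mos_ml <- function(xcom_point, bos, ml_axis = NULL) {
  if (is.null(ml_axis)) ml_axis <- bos$ml_axis
  d <- sum((xcom_point - bos$center) * ml_axis)
  bos$half_extents[2] - abs(d)
}

#' Direction of progression of a gait cycle
#'
#' @param com_start,com_end CoM horizontal positions at the initial and
#'   terminal heel strikes, length-2 (m).
#' @return unit 2-vector; `c(NA, NA)` with a warning when the
#'   displacement is below 1e-6 m (cycle flagged).
#' @export
direction_of_progression <- function(com_start, com_end) {
  d <- com_end - com_start
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-6) {
    warning("near-zero CoM displacement; cycle flagged")
    return(c(NA_real_, NA_real_))
  }
  d / nrm
}

#' Maximum mediolateral CoM deviation within a cycle
#'
#' Maximum absolute perpendicular distance of the cycle's CoM samples
#' from the line through the cycle-initial CoM along the direction of
#' progression.
#'
#' @param com_xy n x 2 matrix (or data frame) of CoM horizontal
#'   positions in the cycle.
#' @param dop unit 2-vector from [direction_of_progression()].
#' @return maximum deviation in metres.
#' @export
com_ml_displacement <- function(com_xy, dop) {
  com_xy <- as.matrix(com_xy)
  if (nrow(com_xy) < 2) stop("need at least 2 CoM samples in the cycle")
  rel <- sweep(com_xy, 2, com_xy[1, ])
  perp <- rel[, 1] * dop[2] - rel[, 2] * dop[1]
  max(abs(perp))
}

#' Per-cycle balance metrics for a session
#'
#' For each assembled stride (gait cycle) computes the DoP, the maximum
#' mediolateral CoM deviation, and the mediolateral margin of stability
#' at the cycle's initial heel strike, using the double-foot BoS formed
#' by both ankle positions at that instant with the cycle's AP axis.
#'
#' @param session a `vrgait_session`.
#' @param strides stride tibble from [assemble_strides()].
#' @param g gravitational acceleration (default 9.8).
#' @param cutoff_hz CoM velocity low-pass cutoff (default 6 Hz).
#' @param foot_length,foot_width footprint dimensions for the BoS (m).
#' @return tibble with one row per cycle: `side`, `t_hs`,
#'   `classification`, `mos_ml`, `com_ml`.
#' @export
analyze_balance <- function(session, strides, g = 9.8, cutoff_hz = 6,
                            foot_length = 0.25, foot_width = 0.10) {
  nav <- session$streams$navel
  la <- session$streams$left_ankle
  ra <- session$streams$right_ankle
  l <- stats::median(c(leg_length(la, nav), leg_length(ra, nav)))
  params <- pendulum_params(l, g)
  vel <- estimate_com_velocity(nav, cutoff_hz)

  rows <- lapply(seq_len(nrow(strides)), function(k) {
    s <- strides[k, ]
    in_cycle <- nav$t >= s$t_initial & nav$t <= s$t_terminal
    if (sum(in_cycle) < 2) return(NULL)
    com <- cbind(nav$px[in_cycle], nav$py[in_cycle])
    dop <- suppressWarnings(
      direction_of_progression(com[1, ], com[nrow(com), ])
    )
    cml <- if (anyNA(dop)) NA_real_ else com_ml_displacement(com, dop)

    i_hs <- which.min(abs(nav$t - s$t_initial))
    u <- c(nav$px[i_hs], nav$py[i_hs])
    u_dot <- c(vel$vx[i_hs], vel$vy[i_hs])
    xc <- xcom(u, u_dot, params)
    il <- which.min(abs(la$t - s$t_initial))
    ir <- which.min(abs(ra$t - s$t_initial))
    hl <- heading_at_index(la, il)
    hr <- heading_at_index(ra, ir)
    mos <- NA_real_
    if (!is.na(hl) && !is.na(hr)) {
      ap <- if (anyNA(dop)) NULL else dop
      bos <- base_of_support(c(la$px[il], la$py[il]), c(ra$px[ir], ra$py[ir]),
                             hl, hr, ap_axis = ap,
                             foot_length = foot_length, foot_width = foot_width)
      mos <- mos_ml(xc, bos)
    }
    tibble::tibble(side = s$side, t_hs = s$t_initial,
                   classification = s$classification,
                   mos_ml = mos, com_ml = cml)
  })
  dplyr::bind_rows(rows)
}

#' Summarise per-cycle balance metrics
#'
#' Mean and coefficient of variation of the mediolateral CoM
#' displacement and mean mediolateral margin of stability over
#' straight-stride cycles. Flagged insufficient with fewer than two
#' valid cycles.
#'
#' @param cycles tibble from [analyze_balance()].
#' @return one-row tibble: `com_ml_mean`, `com_ml_cov`, `mos_ml_mean`,
#'   `n_cycles`, `insufficient`.
#' @export
summarize_balance <- function(cycles) {
  ok <- cycles[cycles$classification == "straight" & !is.na(cycles$com_ml), ]
  n <- nrow(ok)
  tibble::tibble(
    com_ml_mean = if (n >= 1) mean(ok$com_ml) else NA_real_,
    com_ml_cov = if (n >= 2) cov_of(ok$com_ml) else NA_real_,
    mos_ml_mean = if (n >= 1) mean(ok$mos_ml, na.rm = TRUE) else NA_real_,
    n_cycles = n,
    insufficient = n < 2
  )
}
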