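#' Gait event detection from shank orientation
#'
#' The ankle tracker is mounted with its local x-axis along the foot. As
#' the shank rotates over the stance foot the angle `alpha` between that
#' axis (rotated into the global frame) and the fixed global Z-axis
#' traces one arch per gait cycle: it rises from heel strike to toe-off
#' and falls from toe-off to the next heel strike. Heel strikes are
#' therefore detected as local minima of the alpha waveform and toe-offs
#' as local maxima.
#'
#' @name gait-events
NULL

#' Shank-angle waveform of an ankle stream
#'
#' Computes, per sample, the angle between the tracker's local x-axis
#' rotated into the global frame and the global Z-axis:
#' `alpha = acos(clamp((R(q) x_hat) . z_hat, -1, 1))`, in degrees.
#'
#' @param stream an ankle `vrgait_stream` (any stream with quaternion
#'   columns works).
#' @return tibble with columns `t`, `alpha` (degrees, in `[0, 180]`) and
#'   `sample_index`; carries the source stream's gaps as attribute.
#' @export
shank_angle <- function(stream) {
  xg <- quat_rotate_x(stream$qw, stream$qx, stream$qy, stream$qz)
  cz <- pmin(1, pmax(-1, xg[, "z"]))
  out <- tibble::tibble(
    t = stream$t,
    alpha = rad2deg(acos(cz)),
    sample_index = seq_len(nrow(stream))
  )
  attr(out, "gaps") <- stream_gaps(stream)
  attr(out, "nominal_rate") <- stream_rate(stream)
  out
}

#' All local extrema of a series, plateau-aware
#'
#' Brute-force scan: a sample is a local maximum (minimum) if it is
#' strictly greater (smaller) than the nearest differing neighbours on
#' both sides; flat plateaus yield their centre sample. Boundary samples
#' are never extrema.
#'
#' @param x numeric series.
#' @return tibble with columns `index` and `kind` (`"min"`/`"max"`).
#' @keywords internal
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(tibble::tibble(index = integer(), kind = character()))
  d <- diff(x)
  sgn <- sign(d)
  # propagate the sign of the last nonzero difference across plateaus
  run <- rle(sgn)
  idx <- integer(0); kind <- character(0)
  # positions where trend changes from + to - (max) or - to + (min)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  nz <- which(run$values != 0)
  for (j in seq_along(nz)[-1]) {
    prev <- run$values[nz[j - 1]]
    cur <- run$values[nz[j]]
    if (prev == cur) next
    # extremum spans samples [ends[nz[j-1]] + 1, starts[nz[j]]] in x-index
    lo <- ends[nz[j - 1]] + 1L
    hi <- starts[nz[j]]
    center <- as.integer(floor((lo + hi) / 2))
    idx <- c(idx, center)
    kind <- c(kind, if (prev > 0 && cur < 0) "max" else "min")
  }
  keep <- idx > 1L & idx < n
  tibble::tibble(index = idx[keep], kind = kind[keep])
}

#' Topographic prominence of extrema in a 1-D series
#'
#' For a maximum: the drop from the peak to the highest of the two
#' minima separating it from higher terrain (or the series edge). For a
#' minimum: computed on the negated series.
#'
#' @keywords internal
extremum_prominence <- function(x, index, kind) {
  vapply(seq_along(index), function(k) {
    i <- index[k]
    v <- if (kind[k] == "max") x else -x
    peak <- v[i]
    left <- v[seq_len(i - 1)]
    right <- v[seq(i + 1, length(v))]
    jl <- which(left > peak)           # nearest strictly-higher sample bounds the window
    left_min <- if (length(jl) == 0) min(left) else min(left[seq(max(jl), length(left))])
    jr <- which(right > peak)
    right_min <- if (length(jr) == 0) min(right) else min(right[seq_len(min(jr))])
    peak - max(left_min, right_min)
  }, numeric(1))
}

#' Detect heel-strike and toe-off events from a shank-angle waveform
#'
#' The waveform is smoothed with a centred moving average, all local
#' extrema are found by exhaustive scan, and extrema are kept if their
#' topographic prominence reaches `min_prominence_deg` and consecutive
#' accepted events are at least `min_interval_s` apart (the less
#' prominent of a too-close pair is dropped). Alternation is enforced:
#' within any run of same-kind events only the most prominent survives.
#' Each surviving event is then refined to the vertex of a local
#' least-squares parabola fitted to the *raw* waveform around the
#' extremum, which suppresses the timing jitter that sensor noise
#' induces in the smoothed argmin/argmax. Events falling inside dropout
#' gaps, and boundary samples, are never reported. Minima become heel
#' strikes, maxima toe-offs.
#'
#' @param waveform output of [shank_angle()].
#' @param side `"left"` or `"right"`, recorded on the output events.
#' @param smooth_window_s moving-average width in seconds (default 0.1).
#' @param min_prominence_deg minimum prominence in degrees (default 5).
#' @param min_interval_s refractory interval between events (default 0.3).
#' @param refine_window_s half-width of the parabolic refinement window
#'   in seconds (default 0.22; 0 disables refinement).
#'
#' @return tibble with columns `side`, `kind` (`"heel_strike"` /
#'   `"toe_off"`), `t`, `sample_index`.
#' @export
detect_events <- function(waveform, side = c("left", "right"),
                          smooth_window_s = 0.1,
                          min_prominence_deg = 5,
                          min_interval_s = 0.3,
                          refine_window_s = 0.22) {
  side <- match.arg(side)
  t <- waveform$t
  alpha <- waveform$alpha
  rate <- attr(waveform, "nominal_rate")
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  w <- max(1L, round(smooth_window_s * rate))
  if (w %% 2 == 0) w <- w + 1L
  if (length(alpha) < w) stop("waveform shorter than the smoothing window")
  smoothed <- if (w > 1) {
    stats::filter(alpha, rep(1 / w, w), sides = 2)
  } else alpha
  # centred moving average is NA at the edges; fall back to raw there so
  # extrema search sees a full-length series (edges are excluded anyway)
  smoothed <- ifelse(is.na(smoothed), alpha, as.numeric(smoothed))

  ex <- local_extrema(smoothed)
  if (nrow(ex) == 0) return(empty_events(side))
  ex$prominence <- extremum_prominence(smoothed, ex$index, ex$kind)
  ex <- ex[ex$prominence >= min_prominence_deg, ]
  if (nrow(ex) == 0) return(empty_events(side))

  # refractory spacing: greedily drop the less prominent of close pairs
  repeat {
    gaps_t <- diff(t[ex$index])
    close <- which(gaps_t < min_interval_s)
    if (length(close) == 0 || nrow(ex) < 2) break
    k <- close[1]
    drop <- if (ex$prominence[k] < ex$prominence[k + 1]) k else k + 1L
    ex <- ex[-drop, ]
  }

  # alternation: in any run of same-kind events keep the most prominent
  repeat {
    same <- which(diff(match(ex$kind, c("min", "max"))) == 0)
    if (length(same) == 0) break
    k <- same[1]
    drop <- if (ex$prominence[k] < ex$prominence[k + 1]) k else k + 1L
    ex <- ex[-drop, ]
  }

  # refine each extremum to the vertex of a parabola fitted to the raw
  # waveform in a window around it
  if (refine_window_s > 0 && nrow(ex) > 0) {
    n <- length(t)
    for (k in seq_len(nrow(ex))) {
      i0 <- ex$index[k]
      # symmetric window, kept clear of the neighbouring extrema
      gap_l <- if (k > 1) t[i0] - t[ex$index[k - 1]] else Inf
      gap_r <- if (k < nrow(ex)) t[ex$index[k + 1]] - t[i0] else Inf
      h <- min(refine_window_s, 0.45 * min(gap_l, gap_r))
      sel <- which(abs(t - t[i0]) <= h)
      if (length(sel) < 7) next
      x <- t[sel] - t[i0]
      # cubic fit captures the waveform's local skew, so the stationary
      # point is unbiased where a plain parabola vertex would drift
      fit <- stats::lm.fit(cbind(1, x, x^2, x^3), alpha[sel])
      b <- fit$coefficients
      if (any(!is.finite(b))) next
      disc <- b[3]^2 - 3 * b[4] * b[2]
      if (disc < 0) next
      roots <- if (abs(b[4]) > 1e-8) {
        (-b[3] + c(-1, 1) * sqrt(disc)) / (3 * b[4])
      } else if (abs(b[3]) > 1e-12) {
        -b[2] / (2 * b[3])
      } else next
      curv <- 2 * b[3] + 6 * b[4] * roots
      want <- if (ex$kind[k] == "min") curv > 0 else curv < 0
      roots <- roots[want]
      if (length(roots) == 0) next
      dt <- roots[which.min(abs(roots))]
      dt <- max(-refine_window_s / 2, min(refine_window_s / 2, dt))
      ex$index[k] <- max(2L, min(n - 1L, which.min(abs(t - (t[i0] + dt)))))
    }
    ex <- ex[order(ex$index), ]
  }

  # suppress events inside dropout gaps
  gaps <- attr(waveform, "gaps")
  if (!is.null(gaps) && nrow(gaps) > 0) {
    in_gap <- vapply(t[ex$index], function(ti) {
      any(ti >= gaps$t_start & ti < gaps$t_end)
    }, logical(1))
    ex <- ex[!in_gap, ]
  }

  tibble::tibble(
    side = rep(side, nrow(ex)),
    kind = ifelse(ex$kind == "min", "heel_strike", "toe_off"),
    t = t[ex$index],
    sample_index = ex$index
  )
}

empty_events <- function(side) {
  tibble::tibble(side = character(), kind = character(),
                 t = double(), sample_index = integer())[0, ]
}

#' Detect gait events for both ankles of a session
#'
#' Convenience wrapper running [shank_angle()] + [detect_events()] on the
#' left and right ankle streams and binding the results, time-ordered.
#'
#' @param session a `vrgait_session`.
#' @param ... passed on to [detect_events()].
#' @return tibble of events for both sides, sorted by `t`.
#' @export
detect_session_events <- function(session, ...) {
  ev <- dplyr::bind_rows(
    detect_events(shank_angle(session$streams$left_ankle), "left", ...),
    detect_events(shank_angle(session$streams$right_ankle), "right", ...)
  )
  dplyr::arrange(ev, .data$t)
}
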