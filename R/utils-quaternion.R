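#' Quaternion and angle helpers
#'
#' Internal vectorised helpers for unit-quaternion kinematics. Quaternions
#' use the (w, x, y, z) scalar-first convention and rotate tracker-local
#' axes into the right-handed global frame (Z up, metres).
#'
#' @name quaternion-helpers
#' @keywords internal
NULL

#' Rotate the tracker-local x-axis into the global frame
#'
#' Given unit quaternion components, returns the global-frame direction of
#' the local x-axis (the first column of the rotation matrix). All inputs
#' are recycled vectors.
#'
#' @param qw,qx,qy,qz quaternion components (scalar-first).
#' @return a matrix with columns `x`, `y`, `z`.
#' @keywords internal
quat_rotate_x <- function(qw, qx, qy, qz) {
  cbind(
    x = 1 - 2 * (qy^2 + qz^2),
    y = 2 * (qx * qy + qw * qz),
    z = 2 * (qx * qz - qw * qy)
  )
}

quat_norm <- function(qw, qx, qy, qz) sqrt(qw^2 + qx^2 + qy^2 + qz^2)

#' Hamilton product of two quaternions (vectorised)
#' @keywords internal
quat_mul <- function(a, b) {
  # a, b: matrices / data frames with columns qw, qx, qy, qz
  cbind(
    qw = a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    qx = a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    qy = a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    qz = a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' Quaternion for a rotation about a coordinate axis
#' @param angle_rad rotation angle in radians (vectorised).
#' @param axis one of "x", "y", "z".
#' @keywords internal
quat_axis <- function(angle_rad, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  h <- angle_rad / 2
  z <- rep(0, length(h))
  switch(axis,
    x = cbind(qw = cos(h), qx = sin(h), qy = z, qz = z),
    y = cbind(qw = cos(h), qx = z, qy = sin(h), qz = z),
    z = cbind(qw = cos(h), qx = z, qy = z, qz = sin(h))
  )
}

#' Wrap angles in degrees to (-180, 180]
#' @keywords internal
wrap_deg <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; the convention here keeps +180
  w[w == -180] <- 180
  w
}

#' Absolute angular difference in degrees, in [0, 180]
#' @keywords internal
ang_diff_deg <- function(a, b) abs(wrap_deg(a - b))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
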