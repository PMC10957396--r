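#' Wrap an angle to the interval [0, 2*pi)
#'
#' @param x angle(s) in radians.
#' @return Angle(s) in `[0, 2*pi)`.
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Counter-clockwise turn between two planar directions
#'
#' Returns the anticlockwise rotation taking `from` onto `to`, wrapped to
#' `[0, 2*pi)`. This is the convention used for all egocentric inbound turns:
#' the produced turn is assumed to be made with the short anticlockwise
#' rotation in the left-turn-canonical frame.
#'
#' @param from,to numeric length-2 vectors, or matrices with two columns
#'   (one direction per row). Need not be unit length.
#' @return Turn angle(s) in radians, in `[0, 2*pi)`.
#' @export
turn_angle <- function(from, to) {
  if (is.null(dim(from))) from <- matrix(from, ncol = 2)
  if (is.null(dim(to))) to <- matrix(to, ncol = 2)
  cross <- from[, 1] * to[, 2] - from[, 2] * to[, 1]
  dot <- from[, 1] * to[, 1] + from[, 2] * to[, 2]
  wrap_2pi(atan2(cross, dot))
}

#' Produced inbound turn from trial geometry
#'
#' The egocentric turn executed at the third cone: the anticlockwise angle
#' from the final outbound heading (cone2 to cone3) to the direction from
#' cone3 to the response endpoint, wrapped to `[0, 2*pi)`. Coordinates are
#' expected in the left-turn-canonical (standardised) frame.
#'
#' @param cone2,cone3 length-2 positions of the second and third cone (m).
#' @param endpoint length-2 position where the inbound path terminated:
#'   the response location, or the boundary-hit location for an
#'   out-of-bound trial (see [oob_angle()]).
#' @return Turn angle in radians in `[0, 2*pi)`, or `NA` when the endpoint
#'   coincides with cone3 (no defined direction; such trials are excluded
#'   upstream as short responses).
#' @export
produced_turn <- function(cone2, cone3, endpoint) {
  heading <- cone3 - cone2
  disp <- endpoint - cone3
  if (sqrt(sum(disp^2)) < 1e-12) return(NA_real_)
  turn_angle(heading, disp)
}

#' Inbound angle of an out-of-bound trial
#'
#' Out-of-bound trials are truncated at the tracking boundary: the distance
#' walked is uninformative but the initial inbound direction is not. The
#' angle is computed exactly as [produced_turn()] with the boundary-hit
#' location as the endpoint.
#'
#' @inheritParams produced_turn
#' @param oob_point length-2 location where the participant crossed the
#'   tracking boundary.
#' @return Turn angle in radians in `[0, 2*pi)`.
#' @export
oob_angle <- function(cone2, cone3, oob_point) {
  produced_turn(cone2, cone3, oob_point)
}

## ---- quaternions (w, x, y, z convention, Hamilton product) ----

quat_mul <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Rotate 3-D vectors by unit quaternions
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)` or a matrix with one
#'   quaternion per row. Non-unit quaternions are normalised; zero-norm
#'   quaternions are an error.
#' @param v numeric length-3 vector to rotate.
#' @return A matrix of rotated vectors (one per row).
#' @export
quat_rotate <- function(q, v) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("zero-norm quaternion")
  q <- q / nrm
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rows of the rotation matrix applied to v
  cbind(
    (1 - 2 * (y^2 + z^2)) * v[1] + 2 * (x * y - w * z) * v[2] + 2 * (x * z + w * y) * v[3],
    2 * (x * y + w * z) * v[1] + (1 - 2 * (x^2 + z^2)) * v[2] + 2 * (y * z - w * x) * v[3],
    2 * (x * z - w * y) * v[1] + 2 * (y * z + w * x) * v[2] + (1 - 2 * (x^2 + y^2)) * v[3]
  )
}

#' Quaternion for a heading (yaw) plus downward pitch
#'
#' The world frame is right-handed with `z` up and forward along `+x` for the
#' identity orientation. Yaw rotates about `z` (anticlockwise positive);
#' pitch rotates the head downward about the body's lateral axis.
#'
#' @param yaw heading angle in radians.
#' @param pitch downward pitch in radians (0 = level).
#' @return Length-4 quaternion `(w, x, y, z)`.
#' @export
quat_yaw_pitch <- function(yaw, pitch = 0) {
  qz <- c(cos(yaw / 2), 0, 0, sin(yaw / 2))
  qy <- c(cos(pitch / 2), 0, sin(pitch / 2), 0)
  quat_mul(qz, qy)
}

## distance along a ray from `origin` (inside the arena) in unit direction
## `dir` to the first crossing of the square [0, side]^2
ray_exit_distance <- function(origin, dir, side) {
  ts <- c(
    if (dir[1] > 0) (side - origin[1]) / dir[1] else if (dir[1] < 0) -origin[1] / dir[1] else Inf,
    if (dir[2] > 0) (side - origin[2]) / dir[2] else if (dir[2] < 0) -origin[2] / dir[2] else Inf
  )
  min(ts)
}
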