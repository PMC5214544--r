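## Rotation and pose helpers. Conventions: right-handed frames, rotation
## matrices map local -> world, body-fixed Euler sequences composed left to
## right (R = R1 %*% R2 %*% R3). SI units throughout; angles in radians.

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues' formula. The axis must have unit norm (not checked in the hot
#' path; assembly normalises declared axes).
#'
#' @param axis numeric length-3 unit vector.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle); v <- 1 - c_
  x <- axis[1L]; y <- axis[2L]; z <- axis[3L]
  matrix(c(
    x * x * v + c_,     x * y * v - z * s_, x * z * v + y * s_,
    x * y * v + z * s_, y * y * v + c_,     y * z * v - x * s_,
    x * z * v - y * s_, y * z * v + x * s_, z * z * v + c_),
    nrow = 3L, byrow = TRUE)
}

#' Body-fixed XYZ Euler rotation
#' @param rpy numeric length-3 angles (rad) about body-fixed x, y, z in order.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_xyz <- function(rpy) {
  rot_axis_angle(c(1, 0, 0), rpy[1L]) %*%
    rot_axis_angle(c(0, 1, 0), rpy[2L]) %*%
    rot_axis_angle(c(0, 0, 1), rpy[3L])
}

#' Skew-symmetric cross-product matrix
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, -v[3L], v[2L],
           v[3L], 0, -v[1L],
           -v[2L], v[1L], 0), nrow = 3L, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Degrees to radians / radians to degrees
#' @param x numeric vector.
#' @return numeric vector.
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

## Is q a valid rotation matrix (orthonormal, det +1)?
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}
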