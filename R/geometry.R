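#' @title Small rigid-geometry helpers
#' @description Rotation matrices, unit vectors, signed angles. All angles are
#'   in degrees at the interface (the clinical convention) and converted
#'   internally.
#' @name geometry
#' @keywords internal
NULL

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Unit-normalize a 3-vector
#' @param v numeric length-3
#' @return unit vector
#' @keywords internal
unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Right-handed rotation by `angle_deg` degrees about the (not necessarily
#' unit) axis `axis`, via Rodrigues' formula.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  a <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate points about an axis through a fixed point
#'
#' @param pts n x 3 matrix of points.
#' @param axis rotation axis (length 3).
#' @param angle_deg angle in degrees.
#' @param center point on the axis (default origin).
#' @return rotated n x 3 matrix.
#' @export
rotate_points <- function(pts, axis, angle_deg, center = c(0, 0, 0)) {
  R <- rotation_about(axis, angle_deg)
  pts <- as.matrix(pts)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}

# Signed angle (degrees) from vector u to v around axis n (all 3-vectors).
signed_angle <- function(u, v, n) {
  n <- unitv(n)
  u <- u - sum(u * n) * n
  v <- v - sum(v * n) * n
  u <- unitv(u); v <- unitv(v)
  s <- sum(n * pracma_cross(u, v))
  c_ <- sum(u * v)
  rad2deg(atan2(s, c_))
}

# cross product (avoid extra deps)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle in degrees between two vectors
angle_between <- function(u, v) {
  rad2deg(acos(max(-1, min(1, sum(unitv(u) * unitv(v))))))
}

# Householder reflection through the plane with normal `n` passing through
# origin; applied to rows of pts.
reflect_points <- function(pts, n = c(0, 1, 0)) {
  n <- unitv(n)
  H <- diag(3) - 2 * tcrossprod(n)
  as.matrix(pts) %*% t(H)
}

# Orthonormalize: given primary axis (kept) and a secondary hint, return a
# right-handed 3x3 with columns (x, y, z) built by Gram-Schmidt.
orthonormal_frame <- function(primary, secondary) {
  z <- unitv(primary)
  y <- secondary - sum(secondary * z) * z
  y <- unitv(y)
  x <- pracma_cross(y, z)
  cbind(x, y, z)
}
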