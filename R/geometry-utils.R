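# Small vector-geometry helpers shared across modules. Coordinates are
# row-per-atom N x 3 matrices in Angstrom throughout.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
# Rotation matrix (row-vector convention: x_rot = x %*% R) for a rotation of
# `theta` radians about the unit axis `axis`, following the right-hand rule.
rotation_about_axis <- function(axis, theta) {
  u <- unit_vec(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
  # column-vector convention matrix; transpose for row-vector use
  t(R)
}

# Minimal rotation taking unit vector `a` onto unit vector `b`
# (row-vector convention).
rotation_between <- function(a, b) {
  a <- unit_vec(a); b <- unit_vec(b)
  ax <- cross3(a, b)
  s <- vec_norm(ax)
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit_vec(cross3(a, ref))
    return(rotation_about_axis(perp, pi))
  }
  rotation_about_axis(ax / s, atan2(s, d))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Coordinate matrix helpers ---------------------------------------------

as_xyz_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 3) return(x)
  if (is.numeric(x)) return(matrix(x, ncol = 3, byrow = TRUE))
  stop("expected an N x 3 coordinate matrix or a flat xyz vector")
}

xyz_flat <- function(m) as.numeric(t(m))

centroid <- function(xyz) colMeans(as_xyz_matrix(xyz))
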