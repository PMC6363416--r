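# Small geometry helpers shared across modules.

#' Rotation matrix about an arbitrary axis
#'
#' Builds the 3x3 proper rotation matrix for a rotation of `angle` radians
#' about the axis `direction` (Rodrigues' formula). Acts on column vectors.
#'
#' @param direction numeric length-3 axis vector (need not be unit length).
#' @param angle rotation angle in radians.
#' @return A 3x3 rotation matrix with determinant +1.
#' @keywords internal
rotation_about_axis <- function(direction, angle) {
  n <- sqrt(sum(direction^2))
  if (n < .Machine$double.eps) stop("zero-length axis vector")
  u <- direction / n
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  v / n
}

vec_dist <- function(a, b) sqrt(sum((a - b)^2))

# Rotate the rows of an N x 3 coordinate matrix about an axis through `point`.
rotate_coords <- function(xyz, direction, angle, point = c(0, 0, 0)) {
  R <- rotation_about_axis(direction, angle)
  centred <- sweep(xyz, 2, point)
  sweep(centred %*% t(R), 2, point, FUN = "+")
}

# Minimum cross distance between the rows of two coordinate matrices.
min_cross_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
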