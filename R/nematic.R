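#' Traceless symmetric (nematic) 2x2 tensors
#'
#' A nematic tensor encodes an axis (not a direction) and a magnitude. It is
#' represented by its two independent components `c(xx, xy)`; the `yy`
#' component is `-xx` by tracelessness. All elongation, polarity, shear and
#' normalized-stress quantities in this package are nematics.
#'
#' @param xx,xy numeric vectors of equal length, the two independent
#'   components (dimensionless for elongation/polarity).
#' @return For `nematic()`, a numeric vector `c(xx, xy)` (or a two-column
#'   matrix for vector input). `nematic_norm()` returns `sqrt(xx^2 + xy^2)`,
#'   `nematic_angle()` the axis angle in `(-pi/2, pi/2]`.
#' @examples
#' q <- nematic_from_axis(0.1, pi / 4)
#' nematic_norm(q)
#' nematic_angle(q)
#' @export
nematic <- function(xx, xy) {
  stopifnot(length(xx) == length(xy), is.finite(xx), is.finite(xy))
  if (length(xx) == 1L) c(xx = unname(xx), xy = unname(xy))
  else cbind(xx = unname(xx), xy = unname(xy))
}

#' @rdname nematic
#' @param q a nematic as returned by [nematic()], or an n x 2 matrix of them.
#' @export
nematic_norm <- function(q) {
  if (is.matrix(q)) sqrt(q[, 1]^2 + q[, 2]^2) else sqrt(q[[1]]^2 + q[[2]]^2)
}

#' @rdname nematic
#' @export
nematic_angle <- function(q) {
  if (is.matrix(q)) a <- 0.5 * atan2(q[, 2], q[, 1])
  else a <- 0.5 * atan2(q[[2]], q[[1]])
  # map -pi/2 to +pi/2 (same axis)
  ifelse(a <= -pi / 2 + .Machine$double.eps, a + pi, a)
}

#' @rdname nematic
#' @param mag magnitude (>= 0); `angle` axis angle in radians.
#' @param angle axis angle in radians.
#' @export
nematic_from_axis <- function(mag, angle) {
  nematic(mag * cos(2 * angle), mag * sin(2 * angle))
}

#' Rotate a nematic tensor
#'
#' Rotating the frame by `theta` shifts the tensor axis by `theta` while the
#' norm is invariant; components transform with angle `2*theta`.
#'
#' @param q nematic (length-2 vector or n x 2 matrix).
#' @param theta rotation angle, radians.
#' @return rotated nematic of the same shape.
#' @export
nematic_rotate <- function(q, theta) {
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  if (is.matrix(q)) {
    cbind(xx = q[, 1] * c2 - q[, 2] * s2, xy = q[, 1] * s2 + q[, 2] * c2)
  } else {
    c(xx = q[[1]] * c2 - q[[2]] * s2, xy = q[[1]] * s2 + q[[2]] * c2)
  }
}

#' Radial projection of a nematic tensor
#'
#' Projects onto the radial axis at polar angle `phi`:
#' `Q_rr = Q_xx cos(2 phi) + Q_xy sin(2 phi)`. Negative values correspond to
#' tangential elongation.
#'
#' @param q nematic (length-2 vector or n x 2 matrix).
#' @param phi polar angle(s) of the element position, radians.
#' @return numeric vector of radial components.
#' @export
nematic_rr <- function(q, phi) {
  if (is.matrix(q)) q[, 1] * cos(2 * phi) + q[, 2] * sin(2 * phi)
  else q[[1]] * cos(2 * phi) + q[[2]] * sin(2 * phi)
}

# 2x2 rotation matrix
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# matrix exponential of the traceless symmetric matrix with components (xx, xy)
nematic_expm <- function(xx, xy) {
  n <- sqrt(xx^2 + xy^2)
  ch <- cosh(n)
  sh <- if (n < 1e-12) 1 else sinh(n) / n
  matrix(c(ch + sh * xx, sh * xy, sh * xy, ch - sh * xx), 2, 2)
}
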