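#' @useDynLib sphtrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# chart-singularity guard used by frame(), metric assembly, etc.
.X_CAP_HARD <- pi / 2 - 1e-6

#' Wrap angles to the principal branch (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped to (-pi, pi].
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Point on the SO(3) chart
#'
#' A rotation parameterized by latitude `x`, longitude `y` and orientation
#' `theta` (radians). `x` is the latitude on the sphere, restricted to
#' [-pi/2, pi/2]; `y` and `theta` are stored wrapped to (-pi, pi]. The
#' identity rotation is `(0, 0, 0)`.
#'
#' @param x,y,theta angles in radians.
#' @return an object of class `group_point` (named numeric of length 3).
#' @export
group_point <- function(x, y = NULL, theta = NULL) {
  if (is.null(y) && length(x) == 3) { y <- x[[2]]; theta <- x[[3]]; x <- x[[1]] }
  stopifnot(is.finite(x), is.finite(y), is.finite(theta))
  if (abs(x) > pi / 2 + 1e-12)
    stop("latitude x must lie in [-pi/2, pi/2]", call. = FALSE)
  g <- c(x = min(pi / 2, max(-pi / 2, x)), y = wrap_angle(y), theta = wrap_angle(theta))
  class(g) <- "group_point"
  g
}

#' @export
print.group_point <- function(x, ...) {
  cat(sprintf("<group_point> x = %.6f, y = %.6f, theta = %.6f\n", x[1], x[2], x[3]))
  invisible(x)
}

# skew matrix of v, i.e. hat(v) w = v x w
skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Rodrigues rotation about unit axis by angle
rotation_about <- function(axis, angle) {
  K <- skew(axis)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation matrix of a chart point
#'
#' Returns the 3x3 rotation `R(x, y, theta) = e^{y A3} e^{-x A2} e^{theta A1}`
#' where `A_i` are the standard so(3) generators (`A_i v = e_i x v`).
#'
#' @param g a `group_point` or numeric `(x, y, theta)`.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(g) {
  g <- as_group_point(g)
  rotation_about(c(0, 0, 1), g[2]) %*%
    rotation_about(c(0, 1, 0), -g[1]) %*%
    rotation_about(c(1, 0, 0), g[3])
}

as_group_point <- function(g) {
  if (inherits(g, "group_point")) g else group_point(g[[1]], g[[2]], g[[3]])
}

#' Chart coordinates of a rotation matrix
#'
#' Inverse of [rotation_matrix()] on the chart domain, using principal-branch
#' `arg` extraction:
#' `x = arg(sqrt(R11^2 + R21^2) + i R31)`, `y = arg(R11 + i R21)`,
#' `theta = arg(R33 + i R32)`.
#'
#' @param R 3x3 rotation matrix.
#' @return a `group_point`.
#' @export
chart_from_rotation <- function(R) {
  group_point(atan2(R[3, 1], sqrt(R[1, 1]^2 + R[2, 1]^2)),
              atan2(R[2, 1], R[1, 1]),
              atan2(R[3, 2], R[3, 3]))
}

#' Spherical projection of a chart point
#'
#' Projects a rotation to the sphere by its action on the first basis vector,
#' `R e1 = (cos x cos y, cos x sin y, sin x)`.
#'
#' @param g a `group_point` or numeric `(x, y, theta)`.
#' @return unit 3-vector on the sphere.
#' @export
spherical_projection <- function(g) {
  g <- as_group_point(g)
  c(cos(g[[1]]) * cos(g[[2]]), cos(g[[1]]) * sin(g[[2]]), sin(g[[1]]))
}

#' Left-invariant frame at a chart point
#'
#' Coefficients of the basis left-invariant vector fields w.r.t. the
#' coordinate frame (d/dx, d/dy, d/dtheta):
#' `X1 = cos(theta) dx - sec(x) sin(theta) dy + tan(x) sin(theta) dtheta`,
#' `X2 = dtheta`, `X3 = [X1, X2]`. `X1` is the spatial generator (motion
#' along the current orientation on the sphere), `X2` rotates in place.
#'
#' @param g a `group_point`; requires `|x| < pi/2` (chart singularity).
#' @return 3x3 matrix whose rows are X1, X2, X3.
#' @export
so3_frame <- function(g) {
  g <- as_group_point(g)
  if (abs(g[[1]]) >= .X_CAP_HARD)
    stop("chart singularity: |x| too close to pi/2 for frame evaluation", call. = FALSE)
  x <- g[[1]]; th <- g[[3]]
  rbind(
    X1 = c(cos(th), -sin(th) / cos(x), tan(x) * sin(th)),
    X2 = c(0, 0, 1),
    X3 = c(sin(th), cos(th) / cos(x), -tan(x) * cos(th))
  )
}

#' Left-invariant coframe at a chart point
#'
#' Coefficients of the dual one-forms w.r.t. (dx, dy, dtheta):
#' `w1 = cos(theta) dx - cos(x) sin(theta) dy`,
#' `w2 = sin(x) dy + dtheta`,
#' `w3 = sin(theta) dx + cos(x) cos(theta) dy`,
#' satisfying `<w_i, X_j> = delta_ij` wherever the frame is defined.
#'
#' @param g a `group_point`.
#' @return 3x3 matrix whose rows are w1, w2, w3.
#' @export
so3_coframe <- function(g) {
  g <- as_group_point(g)
  x <- g[[1]]; th <- g[[3]]
  rbind(
    w1 = c(cos(th), -cos(x) * sin(th), 0),
    w2 = c(0, sin(x), 1),
    w3 = c(sin(th), cos(x) * cos(th), 0)
  )
}

# group product and inverse in chart coordinates
group_compose <- function(g1, g2) {
  chart_from_rotation(rotation_matrix(g1) %*% rotation_matrix(g2))
}

group_inverse <- function(g) {
  chart_from_rotation(t(rotation_matrix(g)))
}
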