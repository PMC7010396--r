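#' Schematic (reduced) eye camera model
#'
#' Optical model of fundus photography: the eyeball is a unit sphere, the
#' camera performs a central projection through the nodal point. All lengths
#' are in eyeball radii.
#'
#' @param a nodal-point offset from the eyeball center (dimensionless,
#'   `0 <= a < 1`). Default `13/21`, the clinical maximum (6.5 mm / 10.5 mm).
#' @param c distance from the eyeball to the image plane beyond the nodal
#'   point (dimensionless, `> 0`). Default `4/5`.
#' @param eta scale factor of the camera (dimensionless, `> 0`). Default 1.
#' @param psi_max camera half-angle in radians. Default `pi/8`, the angular
#'   range of a standard fundus camera.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(a = 13 / 21, c = 4 / 5, eta = 1, psi_max = pi / 8) {
  stopifnot(a >= 0, a < 1, c > 0, eta > 0, a + c > 0, psi_max > 0, psi_max < pi / 2)
  structure(list(a = a, c = c, eta = eta, psi_max = psi_max), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> a = %.6f, c = %.6f, eta = %g, psi_max = %.6f rad\n",
              x$a, x$c, x$eta, x$psi_max))
  invisible(x)
}

#' Maximal object angle imaged at a given camera angle
#'
#' Solves the schematic-eye relation
#' `(a + cos|y|)^2 / cos^2(psi) = (a + cos|y|)^2 + sin^2|y|`
#' for the unique nonnegative root of `cos|y|`, giving the largest retinal
#' angle `|y|` visible at camera half-angle `psi`. With the default constants
#' and `psi = pi/8` this is about 0.63 rad (36 degrees).
#'
#' @param cam a [camera_model()].
#' @param psi camera angle in radians, `0 <= psi < pi/2`. Defaults to
#'   `cam$psi_max`.
#' @return the object angle in radians.
#' @export
max_object_angle <- function(cam = camera_model(), psi = cam$psi_max) {
  stopifnot(psi >= 0, psi < pi / 2)
  if (psi == 0) return(0)
  tp2 <- tan(psi)^2
  a <- cam$a
  # (a + u)^2 tan^2 psi = 1 - u^2, u = cos|y|
  A <- 1 + tp2; B <- 2 * a * tp2; C <- a^2 * tp2 - 1
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("no object angle solves the schematic-eye relation", call. = FALSE)
  u <- (-B + sqrt(disc)) / (2 * A)
  if (u < -1 - 1e-12 || u > 1 + 1e-12)
    stop("no admissible cosine root in [0, 1]", call. = FALSE)
  acos(min(1, max(-1, u)))
}

#' Project spherical coordinates to the flat camera image
#'
#' Central projection from spherical image coordinates `(x, y)` to flat
#' camera coordinates `(X, Y)`:
#' `X = (a + c) sin(x) / (a + cos(x) cos(y)) * eta`,
#' `Y = (a + c) cos(x) sin(y) / (a + cos(x) cos(y)) * eta`.
#'
#' @param cam a [camera_model()].
#' @param x,y spherical coordinates in radians (vectorized).
#' @return a two-column matrix with columns `X`, `Y`.
#' @export
retina_project <- function(cam, x, y) {
  den <- cam$a + cos(x) * cos(y)
  if (any(den <= 0))
    stop("singular projection: a + cos(x) cos(y) <= 0", call. = FALSE)
  cbind(X = (cam$a + cam$c) * sin(x) / den * cam$eta,
        Y = (cam$a + cam$c) * cos(x) * sin(y) / den * cam$eta)
}

#' Unproject flat camera coordinates to the sphere
#'
#' Inverse of [retina_project()]. For `eta != 1` the inputs are rescaled
#' `X -> X/eta, Y -> Y/eta` first (the general case follows from the unit
#' case by congruency and scaling). With `rho2 = X^2 + Y^2` and
#' `Xi = sqrt(rho2 (1 - a^2) + (a + c)^2)` the closed form is
#' `x = arcsin(X * pbar)`, `y = arg(p1 + i Y pbar)`, where
#' `pbar = (a (a + c) + Xi) / (rho2 + (a + c)^2)` and
#' `p1 = ((a + c) Xi - a rho2) / (rho2 + (a + c)^2)`.
#'
#' @param cam a [camera_model()].
#' @param X,Y flat camera coordinates (vectorized).
#' @return a two-column matrix with columns `x`, `y` (radians).
#' @export
retina_unproject <- function(cam, X, Y) {
  X <- X / cam$eta; Y <- Y / cam$eta
  a <- cam$a; ac <- cam$a + cam$c
  rho2 <- X^2 + Y^2
  Xi <- sqrt(rho2 * (1 - a^2) + ac^2)
  pbar <- (a * ac + Xi) / (rho2 + ac^2)
  p1 <- (ac * Xi - a * rho2) / (rho2 + ac^2)
  arg <- X * pbar
  if (any(abs(arg) > 1 + 1e-12))
    stop("unproject: arcsin argument outside [-1, 1]", call. = FALSE)
  cbind(x = asin(pmin(1, pmax(-1, arg))), y = atan2(Y * pbar, p1))
}

#' Jacobian determinant of the sphere-to-plane projection
#'
#' Local area distortion of [retina_project()]:
#' `J(x, y) = (a + c)^2 cos(x) (1 + a cos(x) cos(y)) / (a + cos(x) cos(y))^3 * eta^2`.
#' With the default constants, `J(0, 0) ~ 0.77` at the chart center and
#' `J(0.63, 0.63) ~ 1.1` at the edge of the field of view.
#'
#' @param cam a [camera_model()].
#' @param x,y spherical coordinates in radians (vectorized).
#' @return the Jacobian determinant (dimensionless).
#' @export
camera_jacobian <- function(cam, x, y) {
  den <- cam$a + cos(x) * cos(y)
  if (any(den <= 0))
    stop("singular projection: a + cos(x) cos(y) <= 0", call. = FALSE)
  (cam$a + cam$c)^2 * cos(x) * (1 + cam$a * cos(x) * cos(y)) / den^3 * cam$eta^2
}

#' Global distortion along the horizontal meridian
#'
#' Relative length distortion `GD(y) = |y - Y(0, y)| / |y|` of the flat image
#' along the line `x = 0`. At `y = 0` the removable singularity is filled
#' with the analytic limit `|1 - (a + c) eta / (a + 1)|`.
#'
#' @param cam a [camera_model()].
#' @param y object angle in radians (vectorized).
#' @return relative distortion (dimensionless).
#' @export
global_distortion <- function(cam, y) {
  lim <- abs(1 - (cam$a + cam$c) * cam$eta / (cam$a + 1))
  Yv <- (cam$a + cam$c) * sin(y) / (cam$a + cos(y)) * cam$eta
  out <- abs(y - Yv) / abs(y)
  out[y == 0] <- lim
  out
}

#' Resample a flat camera image onto the spherical chart (or back)
#'
#' Bilinear resampling between the flat image plane `(X, Y)` and the
#' spherical chart `(x, y)` of the retina, through the schematic-eye
#' projection.
#'
#' @param img numeric matrix; rows index Y (downward), columns index X.
#' @param cam a [camera_model()].
#' @param direction `"flat2sphere"` or `"sphere2flat"`.
#' @param xlim,ylim chart extent (radians) of the spherical raster.
#' @param XYlim half-extent of the flat raster in camera units.
#' @param dim output dimensions `c(nrow, ncol)`; defaults to `dim(img)`.
#' @param fill value for samples outside the source raster.
#' @return numeric matrix of the resampled image.
#' @export
resample_retina_image <- function(img, cam, direction = c("flat2sphere", "sphere2flat"),
                                  xlim = c(-0.63, 0.63), ylim = c(-0.63, 0.63),
                                  XYlim = NULL, dim = base::dim(img), fill = NA_real_) {
  direction <- match.arg(direction)
  if (is.null(XYlim)) {
    corner <- retina_project(cam, xlim[2], ylim[2])
    XYlim <- max(abs(corner)) * 1.0
  }
  nr <- dim[1]; nc <- dim[2]
  if (direction == "flat2sphere") {
    xs <- seq(xlim[1], xlim[2], length.out = nc)
    ys <- seq(ylim[1], ylim[2], length.out = nr)
    gr <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    XY <- retina_project(cam, xs[gr$col], ys[gr$row])
    # source pixel coordinates in the flat raster
    src_c <- (XY[, 1] + XYlim) / (2 * XYlim) * (ncol(img) - 1) + 1
    src_r <- (XY[, 2] + XYlim) / (2 * XYlim) * (nrow(img) - 1) + 1
  } else {
    Xs <- seq(-XYlim, XYlim, length.out = nc)
    Ys <- seq(-XYlim, XYlim, length.out = nr)
    gr <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    xy <- retina_unproject(cam, Xs[gr$col], Ys[gr$row])
    src_c <- (xy[, 1] - xlim[1]) / diff(xlim) * (ncol(img) - 1) + 1
    src_r <- (xy[, 2] - ylim[1]) / diff(ylim) * (nrow(img) - 1) + 1
  }
  vals <- bilinear_sample(img, src_r, src_c, fill)
  matrix(vals, nr, nc)
}

# bilinear interpolation of matrix img at fractional (row, col) positions
bilinear_sample <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  r0 <- pmin(pmax(floor(r[ok]), 1), nr - 1); c0 <- pmin(pmax(floor(c[ok]), 1), nc - 1)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  out[ok] <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}
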