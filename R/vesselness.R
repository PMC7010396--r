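#' Vesselness filter parameters
#'
#' Tunables of the multiscale Hessian vesselness filter and of the external
#' cost built from it.
#'
#' @param beta plate/line discriminator of the vesselness response
#'   (dimensionless, default 0.3).
#' @param c_resp structureness constant (grey-value units, default 0.3).
#' @param scales Gaussian scales `s = sigma^2 / 2` in pixel units
#'   (default `c(2, 3, 4, 5)`).
#' @param lam cost strength `lambda > 0`: small values make the internal
#'   geometry dominate, large values make the image data dominate.
#' @param normalize_vesselness divide the response by its sup-norm before
#'   building the cost (default `FALSE`: the cost formula uses the raw
#'   response with the squared sup-norm).
#' @return an object of class `vesselness_params`.
#' @export
vesselness_params <- function(beta = 0.3, c_resp = 0.3, scales = c(2, 3, 4, 5),
                              lam = 50, normalize_vesselness = FALSE) {
  stopifnot(beta > 0, c_resp > 0, length(scales) >= 1, all(scales > 0), lam > 0)
  structure(list(beta = beta, c_resp = c_resp, scales = scales, lam = lam,
                 normalize_vesselness = isTRUE(normalize_vesselness)),
            class = "vesselness_params")
}

# 1D Gaussian (derivative) kernel, truncated at 4 sigma
gauss_kernel <- function(sigma, order = 0) {
  rad <- max(1L, ceiling(4 * sigma))
  x <- seq(-rad, rad)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) return(-x / sigma^2 * g)
  if (order == 2) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    return(k - mean(k))   # zero-sum: constants map exactly to zero
  }
  stop("order must be 0, 1 or 2")
}

# separable convolution along rows/cols with reflective padding
conv_sep <- function(img, krow, kcol) {
  pad_reflect <- function(v, r) c(v[r:1], v, v[length(v):(length(v) - r + 1)])
  conv1 <- function(v, k) {
    r <- (length(k) - 1) / 2
    stats::convolve(pad_reflect(v, r), rev(k), type = "filter")
  }
  out <- apply(img, 2, conv1, k = kcol)      # along rows (Y direction)
  t(apply(out, 1, conv1, k = krow))          # along columns (X direction)
}

#' Gaussian Hessian eigenvalues of an image
#'
#' Computes the Hessian of `G_sigma * F` by separable Gaussian-derivative
#' convolution at scale `s = sigma^2/2` (so `sigma = sqrt(2 s)`), with
#' reflective boundary padding and kernels truncated at `4 sigma`, and
#' returns its eigenvalues per pixel ordered by absolute value
#' `|lambda1| <= |lambda2|`.
#'
#' @param img numeric matrix (rows = Y, columns = X).
#' @param scale Gaussian scale `s` in squared pixels, positive.
#' @return list with matrices `lambda1`, `lambda2`.
#' @export
hessian_eigenvalues <- function(img, scale) {
  stopifnot(scale > 0, nrow(img) >= 16, ncol(img) >= 16, all(is.finite(img)))
  sigma <- sqrt(2 * scale)
  g0 <- gauss_kernel(sigma, 0); g1 <- gauss_kernel(sigma, 1); g2 <- gauss_kernel(sigma, 2)
  # rows index Y, columns index X
  Fxx <- conv_sep(img, g2, g0)
  Fyy <- conv_sep(img, g0, g2)
  Fxy <- conv_sep(img, g1, g1)
  tr <- Fxx + Fyy
  disc <- sqrt(pmax(0, (Fxx - Fyy)^2 + 4 * Fxy^2))
  e1 <- (tr - disc) / 2
  e2 <- (tr + disc) / 2
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  list(lambda1 = l1, lambda2 = l2)
}

#' Multiscale Hessian vesselness response
#'
#' Frangi-style vesselness of a 2D image: per scale
#' `exp(-lambda1^2 / (2 beta^2 lambda2^2)) *
#'  (1 - exp(-(lambda1^2 + lambda2^2) / (2 c^2))) * U(lambda2)`,
#' maximized over the scales, where `U` is the unit step (`1` for
#' `lambda2 >= 0`). With the eigenvalue convention used here, `lambda2 > 0`
#' selects dark tubes on a bright background (vessels in fundus images).
#' Pixels with `lambda2 = 0` get response 0.
#'
#' @param img numeric matrix.
#' @param p a [vesselness_params()].
#' @return numeric matrix of the response `VF`.
#' @export
vesselness <- function(img, p = vesselness_params()) {
  vf <- matrix(0, nrow(img), ncol(img))
  for (s in p$scales) {
    ev <- hessian_eigenvalues(img, s)
    l1 <- ev$lambda1; l2 <- ev$lambda2
    resp <- matrix(0, nrow(img), ncol(img))
    nz <- l2 != 0
    resp[nz] <- exp(-l1[nz]^2 / (2 * p$beta^2 * l2[nz]^2)) *
      (1 - exp(-(l1[nz]^2 + l2[nz]^2) / (2 * p$c_resp^2)))
    resp[l2 < 0] <- 0
    vf <- pmax(vf, resp)
  }
  vf
}

#' Uniform grid on the (x, y, theta) chart
#'
#' Discretization of the chart: latitude `x` on `[-x_cap, x_cap]`
#' (non-periodic), longitude `y` and orientation `theta` on `[-pi, pi)`
#' (periodic).
#'
#' @param nx,ny,ntheta node counts per axis, in the closed-interval
#'   convention (e.g. `ny = 401` means nodes at `-pi, ..., 0, ..., pi` with
#'   spacing `2 pi / 400`; the duplicate seam node at `+pi` is stored once).
#'   Use odd counts so that 0 is a node on every axis.
#' @param x_cap latitude cap in radians (chart singularity at `pi/2`).
#' @return an object of class `chart_grid`. Fields `ny`, `ntheta` hold the
#'   number of *unique* periodic nodes (`ny - 1` input nodes).
#' @export
chart_grid <- function(nx = 51, ny = 101, ntheta = 101, x_cap = 1.4) {
  stopifnot(nx >= 3, ny >= 5, ntheta >= 5, x_cap > 0, x_cap < pi / 2)
  ny_u <- as.integer(ny - 1)          # unique periodic nodes
  nt_u <- as.integer(ntheta - 1)
  structure(list(
    x = seq(-x_cap, x_cap, length.out = nx),
    y = seq(-pi, pi, length.out = ny)[seq_len(ny_u)],
    theta = seq(-pi, pi, length.out = ntheta)[seq_len(nt_u)],
    nx = as.integer(nx), ny = ny_u, ntheta = nt_u,
    hx = 2 * x_cap / (nx - 1), hy = 2 * pi / ny_u, htheta = 2 * pi / nt_u,
    x_cap = x_cap), class = "chart_grid")
}

#' @export
print.chart_grid <- function(x, ...) {
  cat(sprintf("<chart_grid> %d x %d x %d, x in [-%.3f, %.3f], y/theta periodic\n",
              x$nx, x$ny, x$ntheta, x$x_cap, x$x_cap))
  invisible(x)
}

#' External cost field on the chart from a vesselness response
#'
#' Lifts the flat-image vesselness to a cost on the spherical chart:
#' `G(x, y) = (1 + VF(Pi(x, y)) / (lambda * ||VF||_inf^2))^-1`,
#' where `Pi` is the schematic-eye projection and `VF` is sampled bilinearly.
#' The cost is constant along `theta` (it depends on the sphere point only),
#' equals 1 outside the image, and is floored at `delta_floor`. Low cost on
#' vessels makes geodesics hug them.
#'
#' If `p$normalize_vesselness` is `TRUE`, `VF` is divided by its sup-norm
#' first, so `lambda` acts on a unit-range response.
#'
#' @param VF vesselness response matrix (rows = Y, columns = X).
#' @param cam a [camera_model()].
#' @param p a [vesselness_params()].
#' @param grid a [chart_grid()].
#' @param XYlim half-extent of the flat raster in camera units; defaults to
#'   the projection of the field-of-view corner.
#' @param delta_floor positive lower bound on the cost.
#' @return an object of class `cost_field`: list with `values`
#'   (`nx x ny` matrix, the theta-constant slice), `grid`, `delta_floor`.
#' @export
external_cost <- function(VF, cam = camera_model(), p = vesselness_params(),
                          grid = chart_grid(), XYlim = NULL,
                          delta_floor = 1e-3) {
  stopifnot(delta_floor > 0)
  vmax <- max(VF)
  if (vmax <= 0) {
    vals <- matrix(1, grid$nx, grid$ny)
    return(new_cost_field(vals, grid, delta_floor))
  }
  if (p$normalize_vesselness) { VF <- VF / vmax; vmax <- 1 }
  if (is.null(XYlim)) {
    corner <- retina_project(cam, 0.63, 0.63)
    XYlim <- max(abs(corner))
  }
  gxy <- expand.grid(x = grid$x, y = grid$y)
  # only the camera-visible part of the sphere projects to the image
  ok <- abs(gxy$x) < pi / 2 &
    cam$a + cos(gxy$x) * cos(gxy$y) > 1e-6
  XY <- matrix(NA_real_, nrow(gxy), 2)
  XY[ok, ] <- retina_project(cam, gxy$x[ok], gxy$y[ok])
  src_c <- (XY[, 1] + XYlim) / (2 * XYlim) * (ncol(VF) - 1) + 1
  src_r <- (XY[, 2] + XYlim) / (2 * XYlim) * (nrow(VF) - 1) + 1
  v <- bilinear_sample(VF, src_r, src_c, fill = NA_real_)
  cost <- 1 / (1 + v / (p$lam * vmax^2))
  cost[is.na(cost)] <- 1                      # chart nodes outside the image
  vals <- matrix(pmax(cost, delta_floor), grid$nx, grid$ny)
  new_cost_field(vals, grid, delta_floor)
}

new_cost_field <- function(values, grid, delta_floor = 1e-3) {
  stopifnot(nrow(values) == grid$nx, ncol(values) == grid$ny,
            all(values >= delta_floor - 1e-15))
  structure(list(values = values, grid = grid, delta_floor = delta_floor),
            class = "cost_field")
}

#' Uniform cost field on a chart grid
#'
#' @param grid a [chart_grid()].
#' @param value constant cost value (default 1).
#' @return a `cost_field`.
#' @export
uniform_cost <- function(grid = chart_grid(), value = 1) {
  new_cost_field(matrix(value, grid$nx, grid$ny), grid,
                 delta_floor = min(1e-3, value))
}

#' @export
print.cost_field <- function(x, ...) {
  cat(sprintf("<cost_field> %d x %d (theta-invariant), range [%.4g, %.4g]\n",
              x$grid$nx, x$grid$ny, min(x$values), max(x$values)))
  invisible(x)
}

# cost at arbitrary chart points (bilinear in (x, y), periodic in y)
cost_at <- function(cost, x, y) {
  g <- cost$grid
  ci <- (x + g$x_cap) / g$hx + 1
  yi <- (wrap_angle(y) + pi) / g$hy + 1
  # periodic wrap for y: replicate first column
  vals <- cbind(cost$values, cost$values[, 1])
  out <- bilinear_sample(t(vals), yi, ci, fill = 1)  # rows = y index
  out
}
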