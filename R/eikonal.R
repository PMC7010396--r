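#' Solver parameters for the sub-Riemannian eikonal equation
#'
#' @param xi stiffness `xi > 0` (see [model_params()]).
#' @param eps anisotropy `epsilon` of the Riemannian approximation, in
#'   `(0, 1]`. Motion transverse to the allowed directions is penalized by
#'   `1/eps^2`; the sub-Riemannian model is the limit `eps -> 0`. Default
#'   0.1, which already gives a close approximation.
#' @param seed the source point (a [group_point()]); the distance map
#'   vanishes there. Default: the identity.
#' @param scheme `"anisotropic_fast_marching"` (label-correcting priority
#'   queue, default) or `"iterative_sweeping"` (Gauss-Seidel). Both solve the
#'   same discrete system.
#' @return an object of class `solver_params`.
#' @export
solver_params <- function(xi = 1, eps = 0.1,
                          seed = group_point(0, 0, 0),
                          scheme = c("anisotropic_fast_marching", "iterative_sweeping")) {
  stopifnot(xi > 0, eps > 0, eps <= 1)
  structure(list(xi = xi, eps = eps, seed = as_group_point(seed),
                 scheme = match.arg(scheme)), class = "solver_params")
}

#' Anisotropic Riemannian metric matrix on the chart
#'
#' The Riemannian approximation of the sub-Riemannian metric, in the fixed
#' coordinate coframe `(dx, dy, dtheta)`:
#' `M_eps = R diag(C^2 xi^2, C^2, C^2 xi^2 / eps^2) R^T`, where the columns
#' of `R` are the left-invariant coframe coefficients. For a tangent vector
#' `v`, `v' M_eps v = C^2 (xi^2 <w1,v>^2 + <w2,v>^2 + (xi/eps)^2 <w3,v>^2)`.
#'
#' @param g a [group_point()].
#' @param C_val external cost at `g`, positive.
#' @param params a [solver_params()].
#' @return symmetric positive-definite 3x3 matrix.
#' @export
metric_matrix <- function(g, C_val, params) {
  stopifnot(C_val > 0)
  g <- as_group_point(g)
  x <- g[[1]]; th <- g[[3]]
  R <- cbind(c(cos(th), -cos(x) * sin(th), 0),
             c(0, sin(x), 1),
             c(sin(th), cos(x) * cos(th), 0))
  D <- diag(c(params$xi^2, 1, params$xi^2 / params$eps^2))
  C_val^2 * (R %*% D %*% t(R))
}

#' Solve the sub-Riemannian eikonal equation on the chart
#'
#' Computes the discrete viscosity solution `W` of
#' `sqrt((X1 W)^2 / xi^2 + (X2 W)^2) = C` with `W(seed) = 0`, through the
#' anisotropic Riemannian approximation with metric `M_eps`, discretized via
#' the *inverse* metric: at every `(x, theta)` the inverse metric is
#' decomposed by Selling's algorithm into nonnegative rank-one terms with
#' integer grid offsets, giving a monotone upwind scheme whose stencils
#' adapt to the anisotropy (offsets elongate along the cheap sub-Riemannian
#' directions). The two drivers (label-correcting "fast marching" and
#' Gauss-Seidel sweeping) reach the same fixed point; output is
#' deterministic per scheme.
#'
#' @param cost a `cost_field` (see [external_cost()], [uniform_cost()]).
#' @param params a [solver_params()].
#' @param grid a [chart_grid()]; defaults to the cost field's grid.
#' @param tol update tolerance.
#' @param max_sweeps iteration cap for the sweeping scheme.
#' @param until_target optional [group_point()]: stop once the distance at
#'   this point is final (fast-marching scheme only).
#' @param order accuracy order of the upwind differences: 1 (strictly
#'   monotone scheme; exactly symmetric stencils) or 2 (default; adds the
#'   standard high-accuracy one-sided correction, roughly halving the
#'   distance error at the cost of exact monotonicity).
#' @return an object of class `scalar_field3d`: list with `values`
#'   (3D array `nx x ny x ntheta`, `+Inf` on unreachable nodes), `grid`,
#'   `seed`, `params`.
#' @export
solve_eikonal <- function(cost, params = solver_params(), grid = cost$grid,
                          tol = 1e-10, max_sweeps = 200, until_target = NULL,
                          order = 2) {
  stopifnot(order %in% c(1, 2))
  stopifnot(inherits(cost, "cost_field"), identical(grid, cost$grid))
  seed <- params$seed
  si <- c(which.min(abs(grid$x - seed[[1]])),
          which.min(abs(grid$y - seed[[2]])),
          which.min(abs(grid$theta - seed[[3]])))
  target <- -1
  if (!is.null(until_target)) {
    tg <- as_group_point(until_target)
    ti <- c(which.min(abs(grid$x - tg[[1]])),
            which.min(abs(grid$y - tg[[2]])),
            which.min(abs(grid$theta - tg[[3]])))
    target <- (ti[1] - 1) + grid$nx * ((ti[2] - 1) + grid$ny * (ti[3] - 1))
  }
  scheme <- if (params$scheme == "anisotropic_fast_marching") 0L else 1L
  w <- solve_eikonal_cpp(cost$values, grid$x, grid$y, grid$theta,
                         params$xi, params$eps, as.integer(si - 1L),
                         scheme, tol, as.integer(max_sweeps), as.numeric(target),
                         as.integer(order))
  structure(list(values = array(w, c(grid$nx, grid$ny, grid$ntheta)),
                 grid = grid, seed = seed, params = params),
            class = "scalar_field3d")
}

#' @export
print.scalar_field3d <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<scalar_field3d> %d x %d x %d, finite range [%.4g, %.4g]\n",
              x$grid$nx, x$grid$ny, x$grid$ntheta, min(v), max(v)))
  invisible(x)
}

#' Interpolate a chart field (with gradient) at arbitrary points
#'
#' Tricubic (third-order, Catmull-Rom) interpolation, periodic in `y` and
#' `theta`, clamped in `x`.
#'
#' @param W a `scalar_field3d`.
#' @param pts matrix with columns `(x, y, theta)`.
#' @return list with `value` (vector) and `grad` (n x 3 matrix of
#'   derivatives w.r.t. `x`, `y`, `theta`).
#' @export
interp_field <- function(W, pts) {
  pts <- matrix(pts, ncol = 3)
  g <- W$grid
  pts[, 2] <- wrap_from(pts[, 2], g$y[1])
  pts[, 3] <- wrap_from(pts[, 3], g$theta[1])
  interp_tricubic_cpp(as.numeric(W$values),
                      c(g$nx, g$ny, g$ntheta),
                      g$x[1], g$hx, g$y[1], g$hy, g$theta[1], g$htheta, pts)
}

# wrap angle a into [lo, lo + 2 pi)
wrap_from <- function(a, lo) (a - lo) %% (2 * pi) + lo

#' Extract an isosurface of the distance map
#'
#' Samples the level set `{W = T}` by locating sign changes of `W - T` along
#' all grid edges (x-, y- and theta-directed), with linear interpolation of
#' the crossing -- a point-cloud representation of the numerical
#' sub-Riemannian sphere of radius `T`.
#'
#' @param W a `scalar_field3d`.
#' @param T level value, `0 < T < max(W)`.
#' @return matrix with columns `(x, y, theta)` of surface samples.
#' @export
level_set <- function(W, T) {
  g <- W$grid
  v <- W$values
  stopifnot(T > 0)
  if (T < max(g$hx, g$hy, g$htheta))
    warning("level value below one grid spacing; surface may be empty")
  f <- v - T
  f[!is.finite(f)] <- 1e6
  pts <- list()
  cross_axis <- function(f1, f2, c1, c2) {
    s <- f1 * f2 < 0
    a <- f1[s] / (f1[s] - f2[s])
    lapply(seq_len(3), function(j) c1[s, j] + a * (c2[s, j] - c1[s, j]))
  }
  coords <- as.matrix(expand.grid(x = g$x, y = g$y, theta = g$theta))
  dims <- c(g$nx, g$ny, g$ntheta)
  arr_idx <- array(seq_len(prod(dims)), dims)
  shifts <- list(
    x = list(arr_idx[-g$nx, , ], arr_idx[-1, , ]),
    y = list(arr_idx, arr_idx[, c(2:g$ny, 1), ]),
    theta = list(arr_idx, arr_idx[, , c(2:g$ntheta, 1)])
  )
  out <- list()
  for (ax in names(shifts)) {
    i1 <- as.vector(shifts[[ax]][[1]]); i2 <- as.vector(shifts[[ax]][[2]])
    f1 <- f[i1]; f2 <- f[i2]
    s <- which(f1 * f2 < 0 & abs(f1) < 1e5 & abs(f2) < 1e5)
    if (!length(s)) next
    a <- f1[s] / (f1[s] - f2[s])
    c1 <- coords[i1[s], , drop = FALSE]; c2 <- coords[i2[s], , drop = FALSE]
    # periodic seam: step is one spacing, never the long way around
    d <- c2 - c1
    d[, 2] <- wrap_angle(d[, 2]); d[, 3] <- wrap_angle(d[, 3])
    out[[ax]] <- c1 + a * d
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), 0, 3,
                           dimnames = list(NULL, c("x", "y", "theta")))
  else { colnames(res) <- c("x", "y", "theta"); res }
}
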