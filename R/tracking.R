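# directional derivatives of W along the frame: h1 = X1(W), h2 = X2(W)
frame_derivatives <- function(W, pts) {
  ip <- interp_field(W, pts)
  n <- nrow(ip$grad)
  h1 <- numeric(n); h2 <- numeric(n)
  for (i in seq_len(n)) {
    Fm <- so3_frame(group_point(min(.X_CAP_HARD, max(-.X_CAP_HARD, pts[i, 1])),
                                pts[i, 2], pts[i, 3]))
    h1[i] <- sum(Fm["X1", ] * ip$grad[i, ])
    h2[i] <- sum(Fm["X2", ] * ip$grad[i, ])
  }
  list(value = ip$value, h1 = h1, h2 = h2)
}

#' Backtrack a minimizing geodesic through the distance map
#'
#' Integrates the backtracking equation
#' `gamma' = -(u1 X1 + u2 X2)` with controls read from the distance map,
#' `u1 = X1(W) / (xi^2 C^2)`, `u2 = X2(W) / C^2`, by fixed-step RK4 on the
#' tricubic interpolant of `W`. With these controls the path is traversed at
#' unit sub-Riemannian speed, so `W` decreases at unit rate; integration
#' stops within one grid spacing of the seed, which is then appended. The
#' returned path runs seed-to-endpoint on normalized time `tau in [0, 1]`
#' with total sub-Riemannian length `W(endpoint)`.
#'
#' @param W a `scalar_field3d` distance map from [solve_eikonal()].
#' @param cost the `cost_field` used to compute `W`.
#' @param endpoint a [group_point()] with finite `W`.
#' @param params the [solver_params()] used to compute `W`.
#' @param step RK4 step in sub-Riemannian arclength; default half the
#'   smallest grid spacing.
#' @param cuspless forbid reverse spatial motion by clamping `u1 >= 0`
#'   (experimental).
#' @return an object of class `track_result`: list with `path` (a
#'   `geodesic_path` on normalized tau), `sr_length`, `curvature_g`,
#'   `endpoint`, `seed`.
#' @export
backtrack <- function(W, cost, endpoint, params = W$params, step = NULL,
                      cuspless = FALSE) {
  g <- W$grid
  if (is.null(step)) step <- min(g$hx, g$hy, g$htheta) / 2
  endpoint <- as_group_point(endpoint)
  xi <- params$xi
  w_end <- interp_field(W, matrix(unclass(endpoint), 1))$value
  if (!is.finite(w_end)) stop("endpoint not reached by the distance map", call. = FALSE)
  stop_radius <- max(g$hx, g$hy, g$htheta)
  vel <- function(p) {
    fd <- frame_derivatives(W, matrix(p, 1))
    C2 <- cost_at(cost, p[1], p[2])^2
    u1 <- fd$h1 / (xi^2 * C2)
    u2 <- fd$h2 / C2
    if (cuspless) u1 <- max(u1, 0)
    Fm <- so3_frame(group_point(min(.X_CAP_HARD, max(-.X_CAP_HARD, p[1])),
                                p[2], p[3]))
    -(u1 * Fm["X1", ] + u2 * Fm["X2", ])
  }
  max_steps <- ceiling(w_end / step * 4) + 50
  pts <- matrix(NA_real_, max_steps + 1, 3)
  wv <- numeric(max_steps + 1)
  p <- as.numeric(unclass(endpoint))
  pts[1, ] <- p; wv[1] <- w_end
  n_out <- 1
  stall <- 0
  for (k in seq_len(max_steps)) {
    k1 <- vel(p)
    k2 <- vel(p + step / 2 * k1)
    k3 <- vel(p + step / 2 * k2)
    k4 <- vel(p + step * k3)
    p <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p[2] <- wrap_angle(p[2]); p[3] <- wrap_angle(p[3])
    if (abs(p[1]) > g$x_cap)
      stop("backtracked path left the chart grid", call. = FALSE)
    wcur <- interp_field(W, matrix(p, 1))$value
    n_out <- n_out + 1
    pts[n_out, ] <- p; wv[n_out] <- wcur
    if (wcur < stop_radius) break
    if (wcur >= wv[n_out - 1] - 1e-12) stall <- stall + 1 else stall <- 0
    if (stall >= 10) {
      # the interpolated W plateaus at the seed's kink; arriving there is fine
      if (wcur < 3 * stop_radius) break
      stop("backtracking stalled: distance map fails to decrease", call. = FALSE)
    }
  }
  pts <- pts[seq_len(n_out), , drop = FALSE]
  wv <- wv[seq_len(n_out)]
  # append the seed and reverse to run seed -> endpoint
  seed <- as.numeric(unclass(W$seed))
  pts <- rbind(pts, seed); wv <- c(wv, 0)
  ord <- rev(seq_len(nrow(pts)))
  pts <- pts[ord, , drop = FALSE]; wv <- wv[ord]
  tau <- if (w_end > 0) pmin(1, pmax(0, wv / w_end)) else seq(0, 1, length.out = nrow(pts))
  tau <- cummax(tau) + (seq_along(wv) - 1) * 1e-12   # strictly increasing
  fd <- frame_derivatives(W, pts)
  denom <- sqrt(fd$h1^2 + fd$h2^2)
  cuspish <- abs(fd$h1) < 0.05 * pmax(denom, 1e-300)
  kg <- xi^2 * fd$h2 / fd$h1
  kg[cuspish] <- sign(fd$h2[cuspish]) * Inf
  path <- new_geodesic_path(tau, pts, cbind(fd$h1, fd$h2, rep(NA_real_, nrow(pts))),
                            list(xi = xi), "normalized_tau")
  structure(list(path = path, sr_length = w_end, curvature_g = kg,
                 cusp_flag = cuspish, endpoint = endpoint, seed = W$seed),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("<track_result> %d samples, sr_length = %.5g, %d cusp-suspect\n",
              nrow(x$path), x$sr_length, sum(x$cusp_flag)))
  invisible(x)
}

#' Geodesic curvature along a path from the distance map
#'
#' Reads the geodesic curvature of the spherical projection directly from
#' the value function: `k_g = xi^2 X2(W) / X1(W)`. Samples where
#' `|X1(W)| < 0.05 ||(X1 W, X2 W)||` are cusp-suspect (the spatial control
#' changes sign in a cusp) and are reported as signed `Inf`.
#'
#' @param W a `scalar_field3d`.
#' @param path a `geodesic_path` (or matrix of chart points).
#' @param params a [solver_params()].
#' @return list with `k_g` (numeric, `+-Inf` at flagged samples) and
#'   `cusp_flag` (logical).
#' @export
curvature_from_W <- function(W, path, params = W$params) {
  pts <- if (inherits(path, "data.frame")) as.matrix(path[, c("x", "y", "theta")])
         else matrix(path, ncol = 3)
  fd <- frame_derivatives(W, pts)
  denom <- sqrt(fd$h1^2 + fd$h2^2)
  flag <- abs(fd$h1) < 0.05 * pmax(denom, 1e-300)
  kg <- params$xi^2 * fd$h2 / fd$h1
  kg[flag] <- sign(fd$h2[flag]) * Inf
  list(k_g = kg, cusp_flag = flag)
}

#' Planar curvature of the flat-image projection of a path
#'
#' Projects the chart path to the flat camera image through the schematic
#' eye and returns the signed curvature of the planar curve
#' `kappa = (X' Y'' - Y' X'') / (X'^2 + Y'^2)^(3/2)` by central differences
#' (arclength-invariant form). Useful for comparing curvature measured in
#' distorted camera coordinates against the geodesic curvature measured on
#' the retinal sphere.
#'
#' @param path a `geodesic_path` or matrix of chart points.
#' @param cam a [camera_model()].
#' @return numeric vector of signed curvatures (endpoints copied).
#' @export
planar_curvature <- function(path, cam = camera_model()) {
  pts <- if (inherits(path, "data.frame")) as.matrix(path[, c("x", "y")])
         else matrix(path, ncol = 3)[, 1:2, drop = FALSE]
  if (nrow(pts) < 5) stop("need at least 5 samples", call. = FALSE)
  XY <- retina_project(cam, pts[, 1], pts[, 2])
  n <- nrow(XY)
  seg <- sqrt(rowSums(diff(XY)^2))
  if (any(seg == 0)) stop("degenerate spacing: coincident projected points", call. = FALSE)
  kap <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    h1 <- seg[i - 1]; h2 <- seg[i]
    d1 <- (XY[i + 1, ] - XY[i - 1, ]) / (h1 + h2)
    d2 <- 2 * (h1 * XY[i + 1, ] - (h1 + h2) * XY[i, ] + h2 * XY[i - 1, ]) /
      (h1 * h2 * (h1 + h2))
    kap[i] <- (d1[1] * d2[2] - d1[2] * d2[1]) / sum(d1^2)^1.5
  }
  kap[1] <- kap[2]; kap[n] <- kap[n - 1]
  kap
}

#' End-to-end vessel tracking in a flat fundus-style image
#'
#' Full pipeline: multiscale vesselness of the flat image, external cost
#' lifted to the chart, left shift of the cost so the seed sits at the
#' identity (the eikonal boundary condition lives at the identity), eikonal
#' solve, and backtracking from the shifted endpoint; the path is mapped
#' back by the inverse shift.
#'
#' @param image numeric matrix (flat camera image; dark vessels on bright
#'   background).
#' @param seed_pt,end_pt [group_point()]s: start and end of the track
#'   (position and orientation on the chart).
#' @param cfg a [track_config()].
#' @return a `track_result` (path in the original, unshifted coordinates),
#'   with `planar_curvature` attached.
#' @export
track_vessel <- function(image, seed_pt, end_pt, cfg = track_config()) {
  seed_pt <- as_group_point(seed_pt); end_pt <- as_group_point(end_pt)
  if (isTRUE(all.equal(unclass(seed_pt), unclass(end_pt))))
    stop("seed and endpoint coincide", call. = FALSE)
  vp <- vesselness_params(beta = cfg$beta, c_resp = cfg$c_resp,
                          scales = cfg$scales, lam = cfg$lam,
                          normalize_vesselness = cfg$normalize_vesselness)
  grid <- chart_grid(cfg$grid[1], cfg$grid[2], cfg$grid[3], cfg$x_cap)
  VF <- vesselness(image, vp)
  cost <- external_cost(VF, cfg$cam, vp, grid, XYlim = cfg$XYlim)
  # shift the cost by the left action taking the seed to the identity
  Rs <- rotation_matrix(seed_pt)
  shifted <- shift_cost(cost, Rs)
  end_sh <- chart_from_rotation(t(Rs) %*% rotation_matrix(end_pt))
  sp <- solver_params(xi = cfg$xi, eps = cfg$eps, scheme = cfg$scheme)
  W <- solve_eikonal(shifted, sp, grid)
  tr <- backtrack(W, shifted, end_sh, sp, cuspless = cfg$cuspless)
  # map the path back to the original coordinates
  back <- t(apply(as.matrix(tr$path[, c("x", "y", "theta")]), 1, function(p) {
    unclass(chart_from_rotation(Rs %*% rotation_matrix(group_point(p[1], p[2], p[3]))))
  }))
  tr$path$x <- back[, 1]; tr$path$y <- back[, 2]; tr$path$theta <- back[, 3]
  tr$seed <- seed_pt; tr$endpoint <- end_pt
  tr$planar_curvature <- planar_curvature(tr$path, cfg$cam)
  tr
}

# resample a theta-invariant cost field under the left action g -> R0 g
shift_cost <- function(cost, R0) {
  g <- cost$grid
  gxy <- expand.grid(x = g$x, y = g$y)
  n <- cbind(cos(gxy$x) * cos(gxy$y), cos(gxy$x) * sin(gxy$y), sin(gxy$x))
  n2 <- n %*% t(R0)      # rows: R0 %*% n
  x2 <- asin(pmin(1, pmax(-1, n2[, 3])))
  y2 <- atan2(n2[, 2], n2[, 1])
  vals <- matrix(cost_at(cost, x2, y2), g$nx, g$ny)
  new_cost_field(pmax(vals, cost$delta_floor), g, cost$delta_floor)
}

#' Tidy a track result
#'
#' @param x a `track_result`.
#' @param ... unused.
#' @return tibble of samples: normalized `tau`, chart coordinates, controls
#'   read from the distance map, and geodesic curvature (signed `Inf` at
#'   cusp-suspect samples).
#' @export
tidy.track_result <- function(x, ...) {
  out <- tidy(x$path)
  out$k_g <- x$curvature_g
  out$cusp_flag <- x$cusp_flag
  if (!is.null(x$planar_curvature)) out$k_planar <- x$planar_curvature
  out
}

#' One-row summary of a track result
#'
#' @param x a `track_result`.
#' @param ... unused.
#' @return tibble with sub-Riemannian length, sample count and cusp count.
#' @export
glance.track_result <- function(x, ...) {
  tibble::tibble(sr_length = x$sr_length, n = nrow(x$path),
                 n_cusp_suspect = sum(x$cusp_flag),
                 mean_abs_kg = mean(abs(x$curvature_g[is.finite(x$curvature_g)])))
}

#' Plot a track result on the chart
#'
#' @param object a `track_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.track_result <- function(object, ...) {
  autoplot(object$path, ...)
}
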