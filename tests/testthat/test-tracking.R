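test_that("backtracking recovers the meridian geodesic", {
  fx <- fixture_W("xi15", 1.5)
  W <- fx$W; cost <- fx$cost; sp <- fx$sp; grid <- fx$grid
  hsp <- max(grid$hx, grid$hy)
  endp <- group_point(0.8, 0, 0)      # meridian endpoint, t = xi * x
  tr <- backtrack(W, cost, endp, sp)
  expect_lt(max(abs(tr$path$y)), 2 * hsp)
  expect_lt(max(abs(tr$path$theta)), 2 * hsp)
  expect_equal(tr$sr_length, 1.5 * 0.8, tolerance = 0.03)
  # path runs seed -> endpoint on strictly increasing tau in [0, 1]
  expect_true(all(diff(tr$path$param) > 0))
  expect_lt(chart_dist(as.numeric(tr$path[1, c("x", "y", "theta")]),
                       c(0, 0, 0)), 2 * hsp)
  expect_lt(chart_dist(as.numeric(tr$path[nrow(tr$path), c("x", "y", "theta")]),
                       unclass(endp)), 1e-9)
  # value function property: recomputed path length matches W(endpoint)
  bp <- as.matrix(tr$path[, c("x", "y", "theta")])
  seg <- diff(bp); seg[, 2] <- wrap_angle(seg[, 2]); seg[, 3] <- wrap_angle(seg[, 3])
  len <- 0
  for (i in seq_len(nrow(seg))) {
    g <- group_point(bp[i, 1], bp[i, 2], bp[i, 3])
    om <- so3_coframe(g) %*% seg[i, ]
    len <- len + sqrt(1.5^2 * om[1]^2 + om[2]^2)   # C = 1
  }
  expect_lt(abs(len - tr$sr_length) / tr$sr_length, 0.02)
})

test_that("curvature read-out from W is near zero on the meridian", {
  fx <- fixture_W("xi15", 1.5)
  pts <- cbind(seq(0.25, 0.75, length.out = 15), 0, 0)
  cw <- curvature_from_W(fx$W, pts, fx$sp)
  expect_lt(max(abs(cw$k_g[!cw$cusp_flag])), 0.05)
  expect_lt(mean(cw$cusp_flag), 0.2)
})

test_that("tracking is approximately reversible for uniform cost", {
  fx <- fixture_W("xi15", 1.5)
  grid <- fx$grid
  hsp <- max(grid$hx, grid$hy)
  endp <- group_point(0.55, 0.35, 0.45)
  trA <- backtrack(fx$W, fx$cost, endp, fx$sp)
  # seed at the endpoint: shift by the left action, solve, backtrack to e
  Rs <- rotation_matrix(endp)
  e_sh <- chart_from_rotation(t(Rs))      # image of the identity
  WB <- solve_eikonal(fx$cost, fx$sp, grid)  # cost uniform: same field
  trB <- backtrack(WB, fx$cost, e_sh, fx$sp)
  # map trB back: g -> endp * g, then compare the two chart curves
  bB <- t(apply(as.matrix(trB$path[, c("x", "y", "theta")]), 1, function(p)
    unclass(chart_from_rotation(Rs %*% rotation_matrix(group_point(p[1], p[2], p[3]))))))
  bA <- as.matrix(trA$path[, c("x", "y", "theta")])
  dAB <- max(curve_dist(bA, bB))
  dBA <- max(curve_dist(bB, bA))
  expect_lt(max(dAB, dBA), 3 * hsp)
})

test_that("planar curvature recovers analytic circles and straight lines", {
  cam <- camera_model()
  # straight line in the image: small-x chart meridian-ish path
  yy <- seq(-0.3, 0.3, length.out = 60)
  path_line <- cbind(0, yy, 0)
  k <- planar_curvature(path_line, cam)
  expect_lt(max(abs(k)), 1e-3)
  # circle of radius rho in the flat plane: unproject, then measure
  rho <- 0.3
  phi <- seq(0, 1.8 * pi, length.out = 200)
  XY <- cbind(rho * cos(phi), rho * sin(phi))
  xy <- retina_unproject(cam, XY[, 1], XY[, 2])
  k <- planar_curvature(cbind(xy[, 1], xy[, 2], 0), cam)
  expect_lt(max(abs(abs(k[5:195]) - 1 / rho)) * rho, 1e-3)
  # near the chart center, planar curvature times the local metric factor
  # (a + c)/(a + 1) of the projection agrees with geodesic curvature to 10%
  pr <- model_params(1.5)
  ss <- seq(0, 0.1, length.out = 80)
  cp <- cuspless_geodesic_s(0.3, 0, pr, ss)
  expect_lt(max(abs(cp$x)), 0.1 + 1e-9)
  expect_lt(max(abs(cp$y)), 0.1)
  kpl <- planar_curvature(cp, cam)
  kg <- pr$xi^2 * cp$h2 / cp$h1
  scale <- (cam$a + cam$c) / (cam$a + 1)
  i <- 10:70
  expect_lt(median(abs(abs(kpl[i]) * scale - kg[i]) / kg[i]), 0.1)
  expect_error(planar_curvature(cbind(0, c(1, 1, 1, 1, 1), 0), cam), "degenerate")
})

test_that("cusp-suspect flags appear near the analytic cusp", {
  fx <- fixture_W("xi15", 1.5)
  pr <- model_params(1.5)
  # geodesic with a nearby cusp: sample in t across t_cusp
  h2_0 <- 0.75; h3_0 <- 0
  smax <- cusp_arclength_smax(h2_0, h3_0, pr)
  # t_cusp = integral of xi^2 / h1 up to the cusp (integrable singularity)
  t_cusp <- stats::integrate(function(s)
    pr$xi^2 / vertical_solution_s(h2_0, h3_0, pr, s)[, "h1"],
    0, smax, rel.tol = 1e-9)$value
  # continue past the cusp with the exponential map
  h0 <- momentum(pr$xi * sqrt(1 - h2_0^2), h2_0, h3_0)
  tp <- seq(0.55 * t_cusp, min(1.45 * t_cusp, 3.2), length.out = 25)
  pth <- geodesic_closed_form_t(h0, pr, tp)
  pth <- pth[pth$param > 0, ]
  cw <- curvature_from_W(fx$W, pth, fx$sp)
  dt <- diff(tp)[1]
  near <- abs(pth$param - t_cusp) <= 3 * dt
  far_before <- pth$param < t_cusp - 4 * dt
  expect_true(any(cw$cusp_flag[near]))
  expect_true(mean(cw$cusp_flag[far_before]) < 0.5)
})
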