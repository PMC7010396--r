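test_that("metric matrix reproduces the coframe quadratic form", {
  sp <- solver_params(xi = 1.7, eps = 0.2)
  M <- metric_matrix(group_point(0, 0.5, 0), 1, sp)
  expect_equal(M, diag(c(1.7^2, 1.7^2 / 0.04, 1)), tolerance = 1e-12)
  set.seed(11)
  for (k in 1:20) {
    g <- group_point(runif(1, -1.3, 1.3), runif(1, -pi, pi), runif(1, -pi, pi))
    Cv <- runif(1, 0.2, 2)
    M <- metric_matrix(g, Cv, sp)
    expect_equal(M, t(M))
    v <- rnorm(3)
    om <- so3_coframe(g) %*% v
    q <- Cv^2 * (1.7^2 * om[1]^2 + om[2]^2 + 1.7^2 / 0.04 * om[3]^2)
    expect_equal(drop(t(v) %*% M %*% v), drop(q), tolerance = 1e-10)
  }
})

test_that("distance map fundamentals: seed, axes, monotone level sets", {
  grid <- chart_grid(31, 61, 61)
  cost <- uniform_cost(grid)
  sp <- solver_params(xi = 1.5, eps = 0.1)
  W <- solve_eikonal(cost, sp, grid)
  ctr <- c(which.min(abs(grid$x)), which.min(abs(grid$y)),
           which.min(abs(grid$theta)))
  expect_equal(W$values[ctr[1], ctr[2], ctr[3]], 0)
  expect_true(all(W$values[is.finite(W$values)] >= 0))
  # motion along the meridian costs xi per radian; pure rotation costs 1
  expect_equal(interp_field(W, matrix(c(0.5, 0, 0), 1))$value, 1.5 * 0.5,
               tolerance = 0.02)
  expect_equal(interp_field(W, matrix(c(0, 0, 1), 1))$value, 1,
               tolerance = 0.02)
  # nesting of level sets
  l1 <- level_set(W, 0.8); l2 <- level_set(W, 1.6)
  expect_gt(nrow(l1), 0); expect_gt(nrow(l2), 0)
  w_on_l1 <- interp_field(W, l1[sample(nrow(l1), 200), ])$value
  expect_lt(max(abs(w_on_l1 - 0.8)), 0.1)
})

test_that("both drivers converge to the same discrete solution", {
  grid <- chart_grid(21, 41, 41)
  cost <- uniform_cost(grid)
  WF <- solve_eikonal(cost, solver_params(xi = 1, eps = 0.1), grid)
  WS <- solve_eikonal(cost, solver_params(xi = 1, eps = 0.1,
                                          scheme = "iterative_sweeping"), grid)
  d <- abs(WF$values - WS$values)
  expect_lt(max(d[is.finite(d)]), 1e-8)
})

test_that("first-order scheme is exactly reflection symmetric in (y, theta)", {
  grid <- chart_grid(21, 41, 41)
  W <- solve_eikonal(uniform_cost(grid), solver_params(xi = 1.2, eps = 0.1),
                     grid, order = 1)
  v <- W$values
  vm <- v[, c(1, grid$ny:2), ][, , c(1, grid$ntheta:2)]
  expect_lt(max(abs(v - vm), na.rm = TRUE), 1e-9)
})

test_that("comparison principle: raising the cost never decreases W", {
  grid <- chart_grid(17, 31, 31)
  base <- matrix(1, grid$nx, grid$ny)
  bump <- base
  bump[5:12, 10:20] <- 1.8
  c1 <- sphtrack:::new_cost_field(base, grid)
  c2 <- sphtrack:::new_cost_field(bump, grid)
  sp <- solver_params(xi = 1, eps = 0.15)
  W1 <- solve_eikonal(c1, sp, grid, order = 1)
  W2 <- solve_eikonal(c2, sp, grid, order = 1)
  fin <- is.finite(W1$values) & is.finite(W2$values)
  expect_true(all(W2$values[fin] >= W1$values[fin] - 1e-9))
})

test_that("W is continuous across the periodic seams", {
  grid <- chart_grid(17, 31, 31)
  W <- solve_eikonal(uniform_cost(grid), solver_params(xi = 1, eps = 0.15), grid)
  v <- W$values
  # wrap-around jump along y and theta bounded by one-cell variation inside
  seam_y <- max(abs(v[, grid$ny, ] - v[, 1, ]), na.rm = TRUE)
  inner_y <- max(abs(v[, 2, ] - v[, 1, ]), na.rm = TRUE)
  expect_lt(seam_y, 2 * inner_y + 0.1)
  seam_t <- max(abs(v[, , grid$ntheta] - v[, , 1]), na.rm = TRUE)
  inner_t <- max(abs(v[, , 2] - v[, , 1]), na.rm = TRUE)
  expect_lt(seam_t, 2 * inner_t + 0.1)
})

test_that("the eps-approximation is stable at resolved probe points", {
  # halving eps changes W by < 2% where the grid resolves the eps-layer
  # (meridian and in-place-rotation probes; strongly curved regions need
  # h << eps and are examined in the vignette instead)
  grid <- chart_grid(31, 61, 61)
  cost <- uniform_cost(grid)
  Wa <- solve_eikonal(cost, solver_params(xi = 1, eps = 0.1), grid)
  Wb <- solve_eikonal(cost, solver_params(xi = 1, eps = 0.05), grid)
  probes <- rbind(c(0.5, 0, 0), c(0.9, 0, 0), c(1.1, 0, 0),
                  c(0, 0, 1), c(0, 0, 1.8))
  va <- interp_field(Wa, probes)$value
  vb <- interp_field(Wb, probes)$value
  expect_lt(max(abs(va - vb) / va), 0.02)
})
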