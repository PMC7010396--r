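test_that("vertical dynamics classification covers all regimes", {
  expect_equal(classify_case(model_params(0.5), 1), "elliptic")
  expect_equal(classify_case(model_params(1), 1), "line_segment")
  expect_equal(classify_case(model_params(1), 1.5), "linear")
  expect_equal(classify_case(model_params(2), 2), "crossing_segments")
  expect_equal(classify_case(model_params(2), 1.5), "hyperbolic")
  expect_equal(classify_case(model_params(0.5), 0.5), "equilibrium_point")
  expect_equal(classify_case(model_params(0.5), 0.1), "no_solution")
  # chi branches
  expect_equal(model_params(0.5)$chi, sqrt(0.75) * 1i, tolerance = 1e-14)
  expect_equal(model_params(2)$chi, sqrt(3) + 0i, tolerance = 1e-14)
})

test_that("pendulum form is consistent with the momentum dynamics", {
  pr <- model_params(1)
  expect_equal(unname(pendulum_dynamics(0.7, 0, pr)), c(0, 0))
  expect_equal(unname(pendulum_dynamics(0, 0, model_params(0.5))), c(0, 0))
  # a pendulum trajectory mapped through the phase substitution solves the
  # vertical momentum equations
  pr <- model_params(0.7)
  rhs <- function(t, s, p) list(unname(pendulum_dynamics(s[1], s[2], pr)))
  sol <- deSolve::ode(c(1.1, 0.4), seq(0, 2, 0.05), rhs, NULL,
                      method = "lsoda", atol = 1e-12, rtol = 1e-12)
  xi <- pr$xi
  h <- cbind(xi * cos(sol[, 2] / 2), sin(sol[, 2] / 2), xi * sol[, 3] / 2)
  hd1 <- -h[, 2] * h[, 3]
  hd2 <- h[, 1] * h[, 3] / xi^2
  # compare with finite differences of the substituted trajectory
  dt <- 0.05
  fd1 <- (h[3:41, 1] - h[1:39, 1]) / (2 * dt)
  fd2 <- (h[3:41, 2] - h[1:39, 2]) / (2 * dt)
  expect_lt(max(abs(fd1 - hd1[2:40])), 1e-3)
  expect_lt(max(abs(fd2 - hd2[2:40])), 1e-3)
})

test_that("exponential map integrates the Hamiltonian flow and conserves H, M^2", {
  # zero-curvature momentum: great circle x(t) = t/xi
  pr <- model_params(1.3)
  p <- exponential_map(momentum(1.3, 0, 0), pr, T = 1, n_steps = 50)
  expect_lt(max(abs(p$x - p$param / 1.3)), 1e-9)
  expect_lt(max(abs(p$y)), 1e-9)
  expect_lt(max(abs(p$theta)), 1e-9)
  # xi = 1: vertical solution rotates (h1, h2) at rate h3
  pr1 <- model_params(1)
  h0 <- unit_momentum(0.8, 0.6, pr1)
  p1 <- exponential_map(h0, pr1, T = 2, n_steps = 80)
  z0 <- complex(real = h0[[1]], imaginary = h0[[2]])
  zt <- z0 * exp(1i * h0[[3]] * p1$param)
  expect_lt(max(abs(p1$h1 - Re(zt))), 1e-8)
  expect_lt(max(abs(p1$h2 - Im(zt))), 1e-8)
  expect_lt(max(abs(p1$h3 - h0[[3]])), 1e-10)
  # conservation across regimes
  set.seed(7)
  for (xi in c(0.5, 1, 1.5)) {
    pr <- model_params(xi)
    h0 <- unit_momentum(runif(1, 0, 4 * pi), runif(1, -1.5, 1.5), pr)
    p <- exponential_map(h0, pr, T = 3, n_steps = 60)
    gl <- glance(p)
    expect_lt(gl$max_dev_2H, 1e-7)
    expect_lt(gl$max_dev_M2, 1e-7)
  }
  # step-halving oracle for a generic case
  pr <- model_params(0.7)
  h0 <- momentum(0.7 * cos(0.4), sin(0.4), 0.3)
  pa <- exponential_map(h0, pr, T = 2, n_steps = 40, atol = 1e-10, rtol = 1e-10)
  pb <- exponential_map(h0, pr, T = 2, n_steps = 40, atol = 1e-13, rtol = 1e-13)
  expect_lt(chart_dist(as.numeric(pa[nrow(pa), c("x", "y", "theta")]),
                       as.numeric(pb[nrow(pb), c("x", "y", "theta")])), 1e-7)
})

test_that("closed-form geodesics agree with the integrated Hamiltonian flow", {
  set.seed(8)
  for (xi in c(0.5, 1, 1.5)) {
    pr <- model_params(xi)
    for (k in 1:7) {
      h0 <- unit_momentum(runif(1, 0, 4 * pi), runif(1, -1.5, 1.5), pr)
      tt <- seq(0, 3, length.out = 51)
      ode <- exponential_map(h0, pr, 3, n_steps = 50, atol = 1e-12, rtol = 1e-12)
      if (isTRUE(attr(ode, "chart_exit"))) next
      cf <- geodesic_closed_form_t(h0, pr, tt)
      err <- max(abs(cbind(ode$x - cf$x, wrap_angle(ode$y - cf$y),
                           wrap_angle(ode$theta - cf$theta))))
      expect_lt(err, 1e-6)
    }
  }
  # t = 0 returns the identity
  cf0 <- geodesic_closed_form_t(momentum(1.5 * cos(0.3), sin(0.3), 0.4),
                                model_params(1.5), 0)
  expect_equal(as.numeric(cf0[1, c("x", "y", "theta")]), c(0, 0, 0))
})

test_that("vertical solution in spherical arclength matches its ODE", {
  pr1 <- model_params(1)
  s <- seq(0, 0.8, 0.1)
  v <- vertical_solution_s(0.3, 0.2, pr1, s)
  expect_equal(unname(v[, "h2"]), 0.3 + 0.2 * s)
  expect_equal(unname(v[, "h3"]), rep(0.2, length(s)))
  v0 <- vertical_solution_s(0.3, 0.2, model_params(0.5), 0)
  expect_equal(unname(v0[1, ]), c(0.5 * sqrt(1 - 0.09), 0.3, 0.2), tolerance = 1e-12)
  # ODE oracle, elliptic regime
  pr <- model_params(0.5)
  rhs <- function(s, st, p) list(c(st[2], (0.25 - 1) * st[1]))
  sol <- deSolve::ode(c(0.3, 0.2), seq(0, 1, 0.1), rhs, NULL,
                      method = "lsoda", atol = 1e-13, rtol = 1e-13)
  v <- vertical_solution_s(0.3, 0.2, pr, seq(0, 1, 0.1))
  expect_lt(max(abs(v[, "h2"] - sol[, 2])), 1e-9)
  expect_lt(max(abs(v[, "h3"] - sol[, 3])), 1e-9)
  expect_error(vertical_solution_s(0.2, 1.5, model_params(2), 3), "cusp|momentum")
})

test_that("first-cusp arclength: closed form equals bisection", {
  expect_equal(cusp_arclength_smax(0, 1, model_params(1)), 1)
  expect_equal(cusp_arclength_smax(0, 0, model_params(1)), Inf)
  expect_error(cusp_arclength_smax(1, 0.3, model_params(1)), "cusp")
  set.seed(9)
  for (k in 1:200) {
    xi <- runif(1, 0.3, 3); h2 <- runif(1, -0.99, 0.99); h3 <- runif(1, -2, 2)
    pr <- model_params(xi)
    s_cf <- cusp_arclength_smax(h2, h3, pr)
    s_bi <- sphtrack:::smax_bisect(h2, h3, pr)
    if (is.finite(s_cf) || is.finite(s_bi)) {
      expect_lt(abs(s_cf - s_bi), 1e-8)
      # the cuspless-validity property: h1 > 0 before s_max, = 0 at s_max
      # (h1 = xi sqrt(1 - h2^2) halves the working precision, so the root is
      # asserted on 1 - h2^2 at machine accuracy)
      h1_at <- vertical_solution_s(h2, h3, pr, s_cf)[, "h1"]
      expect_lt(abs(h1_at), xi * 2e-5)
      expect_lt(abs(1 - vertical_solution_s(h2, h3, pr, s_cf)[, "h2"]^2), 2e-10)
      h1_mid <- vertical_solution_s(h2, h3, pr, seq(0, 0.999 * s_cf,
                                                    length.out = 20))[, "h1"]
      expect_true(all(h1_mid > 0))
    }
  }
})

test_that("cuspless geodesics in spherical arclength match the ODE oracle", {
  set.seed(10)
  for (xi in c(0.5, 1, 1.5)) {
    pr <- model_params(xi)
    for (k in 1:4) {
      h2 <- runif(1, -0.9, 0.9); h3 <- runif(1, -1, 1)
      smax <- cusp_arclength_smax(h2, h3, pr)
      send <- 0.95 * min(smax, pi / 2)
      ss <- seq(0, send, length.out = 25)
      cp <- cuspless_geodesic_s(h2, h3, pr, ss)
      sol <- cuspless_ode_oracle(h2, h3, xi, ss)
      err <- max(abs(cbind(cp$x - sol[, 2], wrap_angle(cp$y - sol[, 3]),
                           wrap_angle(cp$theta - sol[, 4]))))
      expect_lt(err, 1e-6)
    }
  }
  # trivial meridian
  cp <- cuspless_geodesic_s(0, 0, model_params(1.2), seq(0, 1, 0.1))
  expect_lt(max(abs(cp$x - cp$param)), 1e-9)
  expect_lt(max(abs(cp$y)) + max(abs(cp$theta)), 1e-9)
  expect_error(cuspless_geodesic_s(0, 1, model_params(1), c(0, 1.5)), "cusp")
})

test_that("reparameterization to sub-Riemannian arclength is consistent", {
  pr <- model_params(1.4)
  # zero curvature: t = xi * s
  cp <- cuspless_geodesic_s(0, 0, pr, seq(0, 1, length.out = 40))
  expect_equal(t_of_s(cp), 1.4 * cp$param, tolerance = 1e-9)
  # cost linearity
  expect_equal(t_of_s(cp, cost = 2), 2 * t_of_s(cp), tolerance = 1e-12)
  # two-route consistency: quadrature slope equals xi^2 / h1
  h2 <- 0.4; h3 <- 0.2
  smax <- cusp_arclength_smax(h2, h3, pr)
  ss <- seq(0, 0.8 * smax, length.out = 400)
  cp <- cuspless_geodesic_s(h2, h3, pr, ss)
  tt <- t_of_s(cp)
  slope <- diff(tt) / diff(cp$param)
  mid_h1 <- (cp$h1[-1] + cp$h1[-nrow(cp)]) / 2
  expect_lt(max(abs(slope - pr$xi^2 / mid_h1)), 1e-3)
  # against the exponential map: endpoint at matched t
  ss <- seq(0, 0.8 * smax, length.out = 1500)
  cp <- cuspless_geodesic_s(h2, h3, pr, ss)
  tt <- t_of_s(cp)
  h0 <- momentum(pr$xi * sqrt(1 - h2^2), h2, h3)
  om <- exponential_map(h0, pr, max(tt), n_steps = 100, atol = 1e-12, rtol = 1e-12)
  gend <- as.numeric(om[nrow(om), c("x", "y", "theta")])
  expect_lt(chart_dist(as.numeric(cp[nrow(cp), c("x", "y", "theta")]), gend), 1e-5)
})

test_that("pendulum symmetry relates the elliptic and hyperbolic regimes", {
  # if beta solves the r-pendulum then beta + pi solves the (-r)-pendulum;
  # integrate the (-r)-pendulum and compare with the shifted closed form
  t <- seq(0, 2, 0.25)
  a <- sphtrack:::pendulum_closed(0.8, 0.5, 0.6, t)
  sol <- deSolve::ode(c(0.8 + pi, 0.5), t, function(tt, s, p)
    list(c(s[2], -(-0.6) * sin(s[1]))), NULL, method = "lsoda",
    atol = 1e-12, rtol = 1e-12)
  expect_lt(max(abs(a$beta + pi - sol[, 2])), 1e-8)
  expect_lt(max(abs(a$c - sol[, 3])), 1e-8)
  # and the closed form itself satisfies the pendulum equation
  h <- 1e-4
  for (tt in c(0.5, 1.2)) {
    b <- sapply(c(tt - h, tt, tt + h),
                function(u) sphtrack:::pendulum_closed(0.8, 0.5, 0.6, u)$beta)
    expect_equal((b[1] - 2 * b[2] + b[3]) / h^2, -0.6 * sin(b[2]), tolerance = 1e-3)
  }
})

test_that("Gauss-Bonnet curvature recovers classical closed forms", {
  # great circle
  ss <- seq(0, 2, length.out = 100)
  n_mat <- cbind(cos(ss), sin(ss), 0 * ss)
  expect_lt(max(abs(geodesic_curvature_gauss_bonnet(n_mat, ss))), 1e-4)
  # latitude circle at x0: k_g = tan(x0)
  x0 <- 0.5
  phi <- ss / cos(x0)
  n_mat <- cbind(cos(x0) * cos(phi), cos(x0) * sin(phi), rep(sin(x0), 100))
  kg <- geodesic_curvature_gauss_bonnet(n_mat, ss)
  expect_lt(max(abs(kg - tan(x0)) / tan(x0)), 1e-3)
  # along a cuspless geodesic: matches xi^2 h2 / h1
  pr <- model_params(1.5)
  smax <- cusp_arclength_smax(0.4, 0.3, pr)
  ss <- seq(0, 0.9 * smax, length.out = 150)
  cp <- cuspless_geodesic_s(0.4, 0.3, pr, ss)
  n_mat <- cbind(cos(cp$x) * cos(cp$y), cos(cp$x) * sin(cp$y), sin(cp$x))
  kg <- geodesic_curvature_gauss_bonnet(n_mat, cp$param)
  mom <- pr$xi^2 * cp$h2 / cp$h1
  i <- 5:145
  expect_lt(max(abs(kg[i] - mom[i]) / abs(mom[i])), 1e-2)
  expect_error(geodesic_curvature_gauss_bonnet(n_mat[1:4, ], ss[1:4]), "5 samples")
})

test_that("wavefront endpoints are exponential-map endpoints", {
  pr <- model_params(1)
  wf <- wavefront(pr, T = 0.05, n_beta = 8, n_c = 5, c_cap = 4)
  # all endpoints within O(T) of the identity
  d <- apply(as.matrix(wf[, c("x", "y", "theta")]), 1, function(p)
    chart_dist(p, c(0, 0, 0)))
  expect_lt(max(d), 0.05 * 3)
  expect_gt(max(d), 0.01)
  # spot check: each point equals its own exponential-map endpoint
  for (i in c(1, 17, 33)) {
    h0 <- unit_momentum(wf$beta0[i], pr$xi * wf$c0[i] / 2, pr)
    p <- exponential_map(h0, pr, 0.05, n_steps = 8)
    expect_lt(chart_dist(as.numeric(p[nrow(p), c("x", "y", "theta")]),
                         as.numeric(wf[i, c("x", "y", "theta")])), 1e-8)
  }
})
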