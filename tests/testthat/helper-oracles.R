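# shared oracles and fixtures for the test suite

# chart distance with periodic wrap in y and theta
chart_dist <- function(a, b) {
  sqrt((a[1] - b[1])^2 + wrap_angle(a[2] - b[2])^2 + wrap_angle(a[3] - b[3])^2)
}

# distance from each row of pts to the nearest sample of a reference curve
curve_dist <- function(pts, ref) {
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (ref[, 1] - pts[i, 1])^2 +
      wrap_angle(ref[, 2] - pts[i, 2])^2 +
      wrap_angle(ref[, 3] - pts[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

# matrix exponential by scaling and squaring on the Taylor series
# (independent of the closed-form Rodrigues route used by the package)
expm_oracle <- function(A, k = 12L) {
  B <- A / 2^k
  S <- diag(nrow(A)); P <- diag(nrow(A))
  for (j in 1:16) { P <- P %*% B / j; S <- S + P }
  for (j in seq_len(k)) S <- S %*% S
  S
}

so3_gen <- function(i) {
  e <- c(0, 0, 0); e[i] <- 1
  matrix(c(0, e[3], -e[2], -e[3], 0, e[1], e[2], -e[1], 0), 3, 3)
}

# finite-difference Lie bracket of two vector fields on the chart
lie_bracket_fd <- function(f1, f2, g, h = 1e-5) {
  jac <- function(f, g) {
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- c(0, 0, 0); e[j] <- h
      J[, j] <- (f(g + e) - f(g - e)) / (2 * h)
    }
    J
  }
  jac(f2, g) %*% f1(g) - jac(f1, g) %*% f2(g)
}

# full Hamiltonian system integrated in spherical arclength (vertical +
# horizontal), the independent oracle for the cuspless closed forms
cuspless_ode_oracle <- function(h2_0, h3_0, xi, s_values) {
  rhs <- function(s, st, p) {
    x <- st[1]; th <- st[3]; h2 <- st[4]; h3 <- st[5]
    h1 <- xi * sqrt(max(1e-14, 1 - h2^2))
    kg <- xi^2 * h2 / h1
    list(c(cos(th), -sin(th) / cos(x), tan(x) * sin(th) + kg,
           h3, (xi^2 - 1) * h2))
  }
  deSolve::ode(c(0, 0, 0, h2_0, h3_0), s_values, rhs, NULL,
               method = "lsoda", atol = 1e-12, rtol = 1e-12)
}

# shared heavy fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

fixture_W <- function(name, xi, grid_dims = c(51, 101, 101), eps = 0.1,
                      order = 2) {
  key <- paste0(name, "_", order)
  if (is.null(.fixtures[[key]])) {
    grid <- chart_grid(grid_dims[1], grid_dims[2], grid_dims[3])
    cost <- uniform_cost(grid)
    sp <- solver_params(xi = xi, eps = eps)
    .fixtures[[key]] <- list(W = solve_eikonal(cost, sp, grid, order = order),
                             cost = cost, grid = grid, sp = sp)
  }
  .fixtures[[key]]
}
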