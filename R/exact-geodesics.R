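#' Model parameters of the sub-Riemannian problem
#'
#' Bundles the curve-stiffness parameter `xi > 0` with the derived constant
#' `chi = sqrt(xi^2 - 1)` (principal square root: purely imaginary for
#' `xi < 1`, zero for `xi = 1`, real positive for `xi > 1`). `xi` balances
#' spherical length against geodesic curvature in the energy
#' `integral C sqrt(xi^2 + k_g^2) ds`; large `xi` favours short, stiff curves.
#'
#' @param xi stiffness, positive scalar.
#' @return an object of class `model_params` with fields `xi`, `chi`
#'   (complex), `r = 1/xi^2 - 1` (the pendulum constant).
#' @export
model_params <- function(xi) {
  stopifnot(is.numeric(xi), length(xi) == 1, xi > 0)
  structure(list(xi = xi, chi = sqrt(as.complex(xi^2 - 1)), r = 1 / xi^2 - 1),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> xi = %g, chi = %s, r = %g\n",
              x$xi, format(x$chi), x$r))
  invisible(x)
}

#' Left-invariant momentum on a unit-speed geodesic
#'
#' Momentum components `(h1, h2, h3)` w.r.t. the left-invariant coframe.
#' On a unit-speed geodesic the Hamiltonian constraint `h1^2/xi^2 + h2^2 = 1`
#' holds; `unit_momentum()` builds such a momentum from the phase
#' `(h1, h2) = (xi cos(b/2), sin(b/2))`.
#'
#' @param h1,h2,h3 momentum components.
#' @return named numeric of length 3.
#' @export
momentum <- function(h1, h2, h3) c(h1 = h1, h2 = h2, h3 = h3)

#' @rdname momentum
#' @param beta phase angle on the Hamiltonian cylinder, in R/4piZ.
#' @param h3 third momentum component.
#' @param params a [model_params()].
#' @export
unit_momentum <- function(beta, h3, params) {
  momentum(params$xi * cos(beta / 2), sin(beta / 2), h3)
}

# 2H of a momentum; must equal 1 on unit-speed geodesics
hamiltonian2H <- function(h, params) h[[1]]^2 / params$xi^2 + h[[2]]^2

casimirM2 <- function(h) sum(h^2)

check_unit_speed <- function(h, params, tol = 1e-9) {
  if (abs(hamiltonian2H(h, params) - 1) > tol)
    stop("momentum is not unit speed: h1^2/xi^2 + h2^2 must equal 1", call. = FALSE)
  invisible(TRUE)
}

#' Classify the vertical dynamics by (xi, M)
#'
#' The momentum trajectory is the intersection of the Hamiltonian cylinder
#' `h1^2/xi^2 + h2^2 = 1` with the Casimir sphere `|h| = M`. Its type
#' depends on the stiffness regime and on M.
#'
#' @param params a [model_params()].
#' @param M nonnegative Casimir value `sqrt(h1^2 + h2^2 + h3^2)`.
#' @return one of `"elliptic"`, `"linear"`, `"hyperbolic"`,
#'   `"equilibrium_point"`, `"line_segment"`, `"crossing_segments"`,
#'   `"no_solution"`.
#' @export
classify_case <- function(params, M) {
  stopifnot(M >= 0)
  xi <- params$xi
  tol <- 1e-12
  if (abs(xi - 1) < tol) {
    if (abs(M - 1) < tol) return("line_segment")
    if (M > 1) return("linear")
    return("no_solution")
  }
  if (xi < 1) {
    if (abs(M^2 - xi^2) < tol) return("equilibrium_point")
    if (M^2 > xi^2) return("elliptic")
    return("no_solution")
  }
  # xi > 1
  if (abs(M^2 - xi^2) < tol) return("crossing_segments")
  if (M > 1) return("hyperbolic")
  "no_solution"
}

#' Pendulum form of the vertical dynamics
#'
#' In phase coordinates `h1 = xi cos(beta/2)`, `h2 = sin(beta/2)`,
#' `h3 = xi c / 2` the momentum equations reduce to a mathematical pendulum
#' `beta' = c`, `c' = -r sin(beta)` with `r = 1/xi^2 - 1`.
#'
#' @param beta,c pendulum state.
#' @param params a [model_params()].
#' @return named numeric `(dbeta, dc)`.
#' @export
pendulum_dynamics <- function(beta, c, params) {
  c(dbeta = c, dc = -params$r * sin(beta))
}

# incomplete elliptic integral of the first kind F(phi | m), scalar phi
elliptic_F <- function(phi, m) {
  if (phi == 0) return(0)
  # quasi-periodic extension beyond [-pi/2, pi/2]
  n <- round(phi / pi)
  ph <- phi - n * pi
  K <- pracma::ellipke(m)$k
  2 * n * K + stats::integrate(function(t) 1 / sqrt(1 - m * sin(t)^2),
                               0, ph, rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# Closed-form pendulum trajectory beta'' = -r sin beta for r >= 0, via
# Jacobi elliptic functions; vectorized over t.
# Returns list(beta, c). beta is continuous (not wrapped).
pendulum_closed <- function(beta0, c0, r, t) {
  if (abs(r) < 1e-14) return(list(beta = beta0 + c0 * t, c = rep(c0, length(t))))
  stopifnot(r > 0)
  sr <- sqrt(r)
  E <- c0^2 / 2 - r * cos(beta0)
  k2 <- (E + r) / (2 * r)
  sep_tol <- 1e-12
  if (k2 < 1 - sep_tol) {
    # oscillation about the nearest stable equilibrium (0 or 2pi mod 4pi)
    ctr <- 2 * pi * round(beta0 / (2 * pi))
    sgn <- if (cos(ctr / 2) >= 0) 1 else -1   # sin(beta/2) = sgn * sin(btilde/2)
    b0 <- beta0 - ctr
    k2 <- max(k2, 0); k <- sqrt(k2)
    if (k < 1e-14) return(list(beta = rep(beta0, length(t)), c = rep(0, length(t))))
    sn0 <- min(1, max(-1, sin(b0 / 2) / k))
    phi0 <- elliptic_F(asin(sn0), k2)
    if (c0 < 0) phi0 <- 2 * pracma::ellipke(k2)$k - phi0
    ej <- pracma::ellipj(sr * t + phi0, k2)
    list(beta = ctr + 2 * asin(pmin(1, pmax(-1, k * ej$sn))),
         c = 2 * sr * k * ej$cn)
  } else if (k2 > 1 + sep_tol) {
    # rotation: beta/2 = am(u), u = sign(c0) sr t / kt + u0
    kt2 <- 1 / k2; kt <- sqrt(kt2)
    u0 <- elliptic_F(beta0 / 2, kt2)
    sg <- if (c0 >= 0) 1 else -1
    u <- sg * sr * t / kt + u0
    ej <- pracma::ellipj(u, kt2)
    K <- pracma::ellipke(kt2)$k
    n <- floor((u + K) / (2 * K))
    am <- n * pi + atan2(ej$sn * (-1)^n, ej$cn * (-1)^n)
    list(beta = 2 * am, c = 2 * sg * sr / kt * ej$dn)
  } else {
    # separatrix through the unstable equilibria
    ctr <- 2 * pi * round(beta0 / (2 * pi))
    b0 <- beta0 - ctr
    sg <- if (c0 != 0) sign(c0) else sign(sin(b0))  # direction of motion
    if (sg == 0) sg <- 1
    a0 <- atanh(min(1 - 1e-15, max(-1 + 1e-15, sg * sin(b0 / 2))))
    u <- sr * t + a0
    list(beta = ctr + sg * 2 * asin(tanh(u)), c = sg * 2 * sr / cosh(u))
  }
}

# closed-form momentum along a unit-speed geodesic, vectorized over t;
# handles all xi > 0 via the pendulum symmetry (beta, r) -> (beta + pi, -r)
momentum_closed_t <- function(h0, params, t) {
  xi <- params$xi
  beta0 <- 2 * atan2(h0[[2]], h0[[1]] / xi)
  c0 <- 2 * h0[[3]] / xi
  if (params$r >= 0) {
    pc <- pendulum_closed(beta0, c0, params$r, t)
    beta <- pc$beta
  } else {
    pc <- pendulum_closed(beta0 + pi, c0, -params$r, t)
    beta <- pc$beta - pi
  }
  cbind(h1 = xi * cos(beta / 2), h2 = sin(beta / 2), h3 = xi * pc$c / 2)
}

# ---------------------------------------------------------------------------
# Hamiltonian flow (ODE route)

# right-hand side of the full Hamiltonian system in the chart,
# state = (x, y, theta, h1, h2, h3)
hamiltonian_rhs <- function(t, st, p) {
  xi <- p$xi
  x <- st[1]; th <- st[3]; h1 <- st[4]; h2 <- st[5]; h3 <- st[6]
  u1 <- h1 / xi^2; u2 <- h2
  list(c(u1 * cos(th),
         -u1 * sin(th) / cos(x),
         u1 * tan(x) * sin(th) + u2,
         -h2 * h3,
         h1 * h3 / xi^2,
         (1 - 1 / xi^2) * h1 * h2))
}

#' Exponential map: integrate the Hamiltonian flow from the identity
#'
#' Numerically integrates the full Hamiltonian system (vertical momentum
#' dynamics plus horizontal chart dynamics with controls `u1 = h1/xi^2`,
#' `u2 = h2`) from the identity with initial momentum `h0`, for
#' sub-Riemannian arclength `t` in `[0, T]`. The Hamiltonian `2H = 1` and the
#' Casimir `M^2 = |h|^2` are conserved along the output.
#'
#' Integration stops early (with attribute `chart_exit = TRUE`) if the path
#' approaches the chart singularity `|x| = pi/2`.
#'
#' @param h0 initial momentum `(h1, h2, h3)` with `h1^2/xi^2 + h2^2 = 1`.
#' @param params a [model_params()].
#' @param T final sub-Riemannian arclength, positive.
#' @param n_steps number of output samples.
#' @param atol,rtol integrator tolerances.
#' @return a `geodesic_path` tibble (param kind `"sr_arclength_t"`).
#' @export
exponential_map <- function(h0, params, T, n_steps = 200, atol = 1e-10, rtol = 1e-10) {
  stopifnot(T > 0, n_steps >= 2)
  check_unit_speed(h0, params)
  times <- seq(0, T, length.out = n_steps + 1)
  rootfun <- function(t, st, p) abs(st[1]) - .X_CAP_HARD
  sol <- deSolve::ode(c(0, 0, 0, h0[[1]], h0[[2]], h0[[3]]), times,
                      hamiltonian_rhs, list(xi = params$xi),
                      method = "lsodar", atol = atol, rtol = rtol,
                      rootfunc = rootfun)
  chart_exit <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  new_geodesic_path(sol[, 1], sol[, 2:4, drop = FALSE], sol[, 5:7, drop = FALSE],
                    params, "sr_arclength_t", chart_exit = chart_exit)
}

# ---------------------------------------------------------------------------
# Closed-form route: conserved spatial momentum + rank-1 reconstruction

# minimal rotation taking unit vector a to unit vector b (|a + b| > 0)
minimal_rotation <- function(a, b) {
  w <- pracma::cross(a, b)
  K <- skew(w)
  diag(3) + K + K %*% K / (1 + sum(a * b))
}

# Rate of the residual rotation angle about the conserved axis m_ref, for a
# trajectory with body momentum m(t) (unit), mdot = -omega x m, and body
# angular velocity omega. Factorization R = exp(phi [m_ref]x) B(m -> m_ref).
phi_rate <- function(m, omega, m_ref) {
  md <- -pracma::cross(omega, m)
  w <- pracma::cross(m, m_ref); d <- sum(m * m_ref)
  wd <- pracma::cross(md, m_ref); dd <- sum(md * m_ref)
  K <- skew(w); Kd <- skew(wd)
  B <- diag(3) + K + K %*% K / (1 + d)
  Bd <- Kd + (Kd %*% K + K %*% Kd) / (1 + d) - K %*% K * (dd / (1 + d)^2)
  bm <- Bd %*% t(B)
  b <- c(bm[3, 2], bm[1, 3], bm[2, 1])
  sum(m_ref * (B %*% omega)) - sum(m_ref * b)
}

# Reconstruct the rotation path from closed-form momentum.
#   h_at(t): 3-vector momentum (analytic);  omega_at(h): body angular velocity.
# The spatial momentum vector q = R(t) p(t), p = (h2, -h1, h3), is conserved,
# so on any segment starting at t_ref the relative rotation factors as
#   R(t_ref)^-1 R(t) = exp(phi(t) [m_ref]x) B(m(t) -> m_ref),
# with m = p/|p|, B the minimal rotation, and phi a single quadrature of an
# analytic rate. Segments are re-based whenever m(t) approaches the antipode
# of m_ref (singularity of B); re-basing uses left invariance of the flow.
reconstruct_rotations <- function(h_at, omega_at, tvals, rel_tol = 1e-11) {
  n <- length(tvals)
  out <- vector("list", n)
  h0 <- h_at(tvals[1])
  M <- sqrt(sum(h0^2))
  if (M < 1e-14) stop("zero Casimir: momentum vanishes", call. = FALSE)
  m_at <- function(t) { h <- h_at(t); c(h[2], -h[1], h[3]) / M }
  integrand <- function(tt, mref) {
    vapply(tt, function(ti) {
      h <- h_at(ti)
      phi_rate(c(h[2], -h[1], h[3]) / M, omega_at(h), mref)
    }, numeric(1))
  }
  R_base <- diag(3)
  t_ref <- tvals[1]
  m_ref <- m_at(t_ref)
  phi_acc <- 0
  out[[1]] <- R_base
  if (n == 1) return(out)
  for (i in 2:n) {
    m_i <- m_at(tvals[i])
    if (1 + sum(m_i * m_ref) < 0.2) {
      t_ref <- tvals[i - 1]
      m_ref <- m_at(t_ref)
      R_base <- out[[i - 1]]
      phi_acc <- 0
    }
    t_prev <- max(t_ref, tvals[i - 1])
    dphi <- tryCatch(
      stats::integrate(integrand, t_prev, tvals[i], mref = m_ref,
                       rel.tol = rel_tol, abs.tol = 1e-13,
                       subdivisions = 400L)$value,
      error = function(e)
        # sqrt-type endpoint singularity (cusp): retry with a laxer target
        stats::integrate(integrand, t_prev, tvals[i], mref = m_ref,
                         rel.tol = 1e-7, abs.tol = 1e-9,
                         subdivisions = 2000L)$value)
    phi_acc <- phi_acc + dphi
    out[[i]] <- R_base %*% rotation_about(m_ref, phi_acc) %*%
      minimal_rotation(m_i, m_ref)
  }
  out
}

#' Closed-form geodesic in sub-Riemannian arclength
#'
#' Evaluates the unit-speed geodesic with initial momentum `h0` at
#' sub-Riemannian arclength values `t`, without integrating the horizontal
#' ODE: the pendulum phase `(beta, c)` is evaluated in Jacobi elliptic
#' functions, the momentum follows from `h1 = xi cos(beta/2)`,
#' `h2 = sin(beta/2)`, `h3 = xi c/2`, and the rotation is rebuilt from the
#' conserved spatial momentum vector with one quadrature for the residual
#' rotation angle about the conserved axis.
#'
#' @param h0 initial momentum with `h1^2/xi^2 + h2^2 = 1`.
#' @param params a [model_params()].
#' @param t nonnegative arclength value(s).
#' @return a `geodesic_path` tibble (param kind `"sr_arclength_t"`).
#' @export
geodesic_closed_form_t <- function(h0, params, t) {
  check_unit_speed(h0, params)
  stopifnot(all(t >= 0), !is.unsorted(t))
  if (t[1] > 0) t <- c(0, t)
  xi <- params$xi
  h_at <- function(tt) drop(momentum_closed_t(h0, params, tt))
  omega_at <- function(h) c(h[2], -h[1] / xi^2, 0)
  Rs <- reconstruct_rotations(h_at, omega_at, t)
  states <- t(vapply(Rs, function(R) unclass(chart_from_rotation(R)), numeric(3)))
  momenta <- momentum_closed_t(h0, params, t)
  new_geodesic_path(t, states, momenta, params, "sr_arclength_t")
}

# ---------------------------------------------------------------------------
# spherical-arclength (cuspless) machinery

#' Vertical momentum solution in spherical arclength
#'
#' Closed-form momentum along a cuspless geodesic parameterized by spherical
#' arclength `s`:
#' `h2(s) = h2_0 cosh(s chi) + (h3_0/chi) sinh(s chi)`,
#' `h3(s) = h3_0 cosh(s chi) + chi h2_0 sinh(s chi)`,
#' `h1(s) = xi sqrt(1 - h2(s)^2)`,
#' with `chi = sqrt(xi^2 - 1)` evaluated with the principal complex root
#' (trigonometric behaviour for `xi < 1`); for `xi = 1` the linear branch
#' `h2(s) = h2_0 + h3_0 s`, `h3(s) = h3_0` is used.
#'
#' @param h2_0,h3_0 initial momentum components, `|h2_0| <= 1`.
#' @param params a [model_params()].
#' @param s spherical arclength value(s), `>= 0`.
#' @return matrix with columns `h1`, `h2`, `h3`.
#' @export
vertical_solution_s <- function(h2_0, h3_0, params, s) {
  stopifnot(abs(h2_0) <= 1)
  xi <- params$xi
  if (abs(xi - 1) < 1e-14) {
    h2 <- h2_0 + h3_0 * s
    h3 <- rep(h3_0, length(s))
  } else {
    chi <- params$chi
    h2c <- h2_0 * cosh(s * chi) + h3_0 / chi * sinh(s * chi)
    h3c <- h3_0 * cosh(s * chi) + chi * h2_0 * sinh(s * chi)
    if (max(abs(Im(h2c)), abs(Im(h3c))) > 1e-10)
      stop("vertical solution acquired a nonreal part", call. = FALSE)
    h2 <- Re(h2c); h3 <- Re(h3c)
  }
  if (any(abs(h2) > 1 + 1e-12))
    stop("invalid momentum: |h2(s)| > 1 requested beyond the cusp", call. = FALSE)
  h2 <- pmin(1, pmax(-1, h2))
  cbind(h1 = xi * sqrt(1 - h2^2), h2 = h2, h3 = h3)
}

#' First-cusp spherical arclength
#'
#' Smallest `s > 0` at which `h1(s) = 0`, i.e. where the spherical projection
#' of the geodesic would develop a cusp (the spatial control changes sign).
#' Returns `Inf` when `h1` never vanishes. Uses the per-regime closed form of
#' the vertical solution; the root is verified against [vertical_solution_s()]
#' and falls back to bisection (with a warning) on disagreement.
#'
#' @param h2_0,h3_0 initial momentum components, `|h2_0| < 1`.
#' @param params a [model_params()].
#' @return positive scalar or `Inf`.
#' @export
cusp_arclength_smax <- function(h2_0, h3_0, params) {
  if (abs(h2_0) >= 1)
    stop("immediate cusp: |h2_0| = 1 means h1(0) = 0", call. = FALSE)
  xi <- params$xi
  s_cf <- smax_closed_form(h2_0, h3_0, xi)
  if (!is.finite(s_cf)) return(Inf)
  # verify on 1 - h2^2 (h1 itself only carries half the working precision)
  h2_at <- vertical_solution_s(h2_0, h3_0, params, s_cf)[, "h2"]
  if (abs(1 - h2_at^2) < 1e-9) return(s_cf)
  warning("closed-form cusp arclength failed verification; using bisection")
  smax_bisect(h2_0, h3_0, params)
}

smax_closed_form <- function(h2_0, h3_0, xi) {
  if (abs(xi - 1) < 1e-14) {
    if (h3_0 == 0) return(Inf)
    return((sign(h3_0) - h2_0) / h3_0)
  }
  if (xi < 1) {
    om <- sqrt(1 - xi^2)
    rho <- sqrt(h2_0^2 + (h3_0 / om)^2)
    if (rho < 1) return(Inf)
    psi0 <- atan2(h2_0, h3_0 / om)      # h2 = rho sin(psi0 + om s)
    alpha <- asin(min(1, 1 / rho))
    cand <- c(alpha, pi - alpha, -alpha, pi + alpha)
    cand <- as.vector(outer(cand, 2 * pi * (-1:2), `+`))
    s <- (cand - psi0) / om
    s <- s[s > 1e-12]
    if (!length(s)) return(Inf)
    return(min(s))
  }
  om <- sqrt(xi^2 - 1)
  A <- (h2_0 + h3_0 / om) / 2
  B <- (h2_0 - h3_0 / om) / 2
  if (abs(A) < 1e-15) return(Inf)       # |h2| decays, never reaches 1
  roots <- c()
  for (target in c(1, -1)) {
    disc <- target^2 - 4 * A * B
    if (disc < 0) next
    z <- (target + c(1, -1) * sqrt(disc)) / (2 * A)
    z <- z[z > 1 + 1e-12]
    roots <- c(roots, log(z) / om)
  }
  if (!length(roots)) return(Inf)
  min(roots)
}

smax_bisect <- function(h2_0, h3_0, params, s_hi = 50) {
  h1s <- function(s) vertical_solution_s(h2_0, h3_0, params, s)[, "h1"]
  ss <- seq(0, s_hi, length.out = 20000)
  h2v <- if (abs(params$xi - 1) < 1e-14) h2_0 + h3_0 * ss else
    Re(h2_0 * cosh(ss * params$chi) + h3_0 / params$chi * sinh(ss * params$chi))
  idx <- which(abs(h2v) >= 1)[1]
  if (is.na(idx)) return(Inf)
  f <- function(s) 1 - (if (abs(params$xi - 1) < 1e-14) (h2_0 + h3_0 * s)^2 else
    Re(h2_0 * cosh(s * params$chi) + h3_0 / params$chi * sinh(s * params$chi))^2)
  stats::uniroot(f, c(ss[max(1, idx - 1)], ss[idx]), tol = 1e-12)$root
}

#' Cuspless geodesic in spherical arclength
#'
#' Evaluates the cuspless geodesic with initial momentum `(h2_0, h3_0)`
#' (and `h1(0) = xi sqrt(1 - h2_0^2) > 0`) at spherical arclength values
#' `s in [0, s_max]`, using the elementary closed form of the vertical
#' momentum and the conserved-momentum rotation reconstruction. The chart
#' coordinates are extracted as
#' `x = arg(sqrt(R11^2 + R21^2) + i R31)`, `y = arg(R11 + i R21)`,
#' `theta = arg(R33 + i R32)`.
#'
#' @param h2_0,h3_0 initial momentum components, `|h2_0| < 1`.
#' @param params a [model_params()].
#' @param s nonnegative, nondecreasing spherical arclength value(s).
#' @return a `geodesic_path` tibble (param kind `"spherical_arclength_s"`).
#' @export
cuspless_geodesic_s <- function(h2_0, h3_0, params, s) {
  stopifnot(all(s >= 0), !is.unsorted(s))
  if (abs(h2_0) >= 1) stop("immediate cusp: need |h2_0| < 1", call. = FALSE)
  smax <- cusp_arclength_smax(h2_0, h3_0, params)
  if (max(s) > smax + 1e-10)
    stop(sprintf("cusp exceeded: s beyond s_max = %.6g", smax), call. = FALSE)
  if (s[1] > 0) s <- c(0, s)
  xi <- params$xi
  h_at <- function(ss) drop(vertical_solution_s(h2_0, h3_0, params, min(ss, smax)))
  omega_at <- function(h) {
    h1 <- max(h[1], 1e-6)          # integrable cusp singularity, clipped
    c(xi^2 * h[2] / h1, -1, 0)
  }
  Rs <- reconstruct_rotations(h_at, omega_at, s, rel_tol = 1e-10)
  states <- t(vapply(Rs, function(R) unclass(chart_from_rotation(R)), numeric(3)))
  momenta <- vertical_solution_s(h2_0, h3_0, params, pmin(s, smax))
  new_geodesic_path(s, states, momenta, params, "spherical_arclength_s")
}

#' Reparameterize spherical arclength to sub-Riemannian arclength
#'
#' Cumulative sub-Riemannian arclength
#' `t(s) = integral_0^s cost(sigma) sqrt(xi^2 + k_g^2(sigma)) dsigma`
#' along a path in spherical arclength, by trapezoidal quadrature. Along a
#' unit-speed geodesic this integrand equals `cost * xi^2 / h1`.
#'
#' @param path a `geodesic_path` with param kind `"spherical_arclength_s"`.
#' @param cost external cost values along the path (default uniform 1).
#' @return numeric vector of cumulative `t` values matching the path samples.
#' @export
t_of_s <- function(path, cost = 1) {
  stopifnot(inherits(path, "geodesic_path"),
            attr(path, "param_kind") == "spherical_arclength_s")
  xi <- attr(path, "xi")
  cost <- rep_len(cost, nrow(path))
  kg <- xi^2 * path$h2 / pmax(path$h1, 1e-12)
  integrand <- cost * sqrt(xi^2 + kg^2)
  s <- path$param
  c(0, cumsum(diff(s) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2))
}

#' Geodesic curvature of a sphere curve by finite differences
#'
#' Gauss-Bonnet formula `k_g(s) = n''(s) . (n(s) x n'(s))` for a unit-speed
#' curve on the unit sphere, evaluated with central differences. If the
#' supplied samples are not unit speed (within `1e-3`), the curve is first
#' resampled by cubic spline to uniform spherical arclength.
#'
#' @param n_mat matrix with rows of unit 3-vectors.
#' @param s_values parameter values of the samples.
#' @return numeric vector of curvature values (endpoints by one-sided copy).
#' @export
geodesic_curvature_gauss_bonnet <- function(n_mat, s_values) {
  n <- nrow(n_mat)
  if (n < 5) stop("need at least 5 samples for curvature estimation", call. = FALSE)
  speed <- sqrt(rowSums((diff(n_mat) / diff(s_values))^2))
  if (max(abs(speed - 1)) > 1e-3) {
    arc <- c(0, cumsum(sqrt(rowSums(diff(n_mat)^2))))
    ss <- seq(0, arc[n], length.out = n)
    n_mat <- vapply(1:3, function(j) stats::spline(arc, n_mat[, j], xout = ss)$y,
                    numeric(n))
    n_mat <- n_mat / sqrt(rowSums(n_mat^2))
    s_values <- ss
  }
  h <- diff(s_values)
  kg <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    h1 <- h[i - 1]; h2 <- h[i]
    d1 <- (n_mat[i + 1, ] - n_mat[i - 1, ]) / (h1 + h2)
    d2 <- 2 * (h1 * n_mat[i + 1, ] - (h1 + h2) * n_mat[i, ] + h2 * n_mat[i - 1, ]) /
      (h1 * h2 * (h1 + h2))
    kg[i] <- sum(d2 * pracma::cross(n_mat[i, ], d1))
  }
  kg[1] <- kg[2]; kg[n] <- kg[n - 1]
  kg
}

#' Geodesic wavefront: endpoints of all unit-speed geodesics of length T
#'
#' Samples initial momenta on the unit-speed cylinder `2H = 1`
#' (phase `beta in [0, 4pi)`, vertical momentum parameter `c` on a symmetric
#' grid) and maps each through the exponential map for time `T`.
#'
#' @param params a [model_params()].
#' @param T sub-Riemannian arclength radius, positive.
#' @param n_beta,n_c numbers of samples in `beta` and `c`.
#' @param c_cap half-range of the `c` grid.
#' @return tibble with columns `beta0`, `c0`, `x`, `y`, `theta` and the
#'   initial momenta; attribute `T`.
#' @export
wavefront <- function(params, T, n_beta = 64, n_c = 33, c_cap = 10) {
  stopifnot(T > 0)
  betas <- seq(0, 4 * pi, length.out = n_beta + 1)[-(n_beta + 1)]
  cs <- seq(-c_cap, c_cap, length.out = n_c)
  grid <- expand.grid(beta0 = betas, c0 = cs)
  ends <- t(mapply(function(b, cc) {
    h0 <- unit_momentum(b, params$xi * cc / 2, params)
    p <- exponential_map(h0, params, T, n_steps = 8)
    as.numeric(p[nrow(p), c("x", "y", "theta")])
  }, grid$beta0, grid$c0))
  out <- tibble::tibble(beta0 = grid$beta0, c0 = grid$c0,
                        x = ends[, 1], y = ends[, 2], theta = ends[, 3])
  attr(out, "T") <- T
  attr(out, "xi") <- params$xi
  out
}

# ---------------------------------------------------------------------------
# geodesic_path container

# states: matrix (x, y, theta); momenta: matrix (h1, h2, h3)
new_geodesic_path <- function(param, states, momenta, params, param_kind,
                              chart_exit = FALSE) {
  xi <- params$xi
  out <- tibble::tibble(
    param = as.numeric(param),
    x = states[, 1], y = states[, 2], theta = states[, 3],
    h1 = momenta[, 1], h2 = momenta[, 2], h3 = momenta[, 3],
    u1 = momenta[, 1] / xi^2, u2 = momenta[, 2],
    k_g = xi^2 * momenta[, 2] / pmax(abs(momenta[, 1]), 1e-12) * sign(momenta[, 1] + 1e-300)
  )
  attr(out, "param_kind") <- param_kind
  attr(out, "xi") <- xi
  attr(out, "chart_exit") <- chart_exit
  class(out) <- c("geodesic_path", class(out))
  out
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a geodesic path
#'
#' @param x a `geodesic_path`.
#' @param ... unused.
#' @return the underlying tibble of samples.
#' @export
tidy.geodesic_path <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "geodesic_path")
  attr(out, "param_kind") <- NULL
  out
}

#' One-row summary of a geodesic path
#'
#' @param x a `geodesic_path`.
#' @param ... unused.
#' @return tibble with parameter kind, endpoints, length and conservation
#'   diagnostics.
#' @export
glance.geodesic_path <- function(x, ...) {
  xi <- attr(x, "xi")
  H2 <- x$h1^2 / xi^2 + x$h2^2
  M2 <- x$h1^2 + x$h2^2 + x$h3^2
  tibble::tibble(
    param_kind = attr(x, "param_kind"),
    n = nrow(x),
    length = max(x$param),
    x_end = x$x[nrow(x)], y_end = x$y[nrow(x)], theta_end = x$theta[nrow(x)],
    max_dev_2H = max(abs(H2 - 1)),
    max_dev_M2 = max(abs(M2 - M2[1])),
    chart_exit = isTRUE(attr(x, "chart_exit"))
  )
}

#' Plot the spherical projection of a geodesic path
#'
#' @param object a `geodesic_path`.
#' @param ... unused.
#' @return a ggplot of the chart trace colored by curvature.
#' @export
autoplot.geodesic_path <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot", call. = FALSE)
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$y, y = .data$x,
                                             colour = .data$k_g)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude y (rad)", y = "latitude x (rad)",
                  colour = "k_g")
}

#' Autoplot generic for sphtrack result objects
#'
#' Dispatches to the `autoplot` method of the object (compatible with
#' ggplot2's generic when ggplot2 is attached).
#'
#' @param object an object with an `autoplot` method.
#' @param ... passed to methods.
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
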