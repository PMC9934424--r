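# ---------------------------------------------------------------------------
# Model definition: the continuum Peyrard-Bishop PDE for the hydrogen-bond
# stretching field R(x, t),
#
#   R_tt - (a1 + 3 a2 R_x^2) R_xx - 2 eta zeta e^{-eta R} (e^{-eta R} - 1) = 0,
#
# its travelling-wave reduction, the first integral, and the exponential
# substitution s = e^{-eta r} that turns the reduced equation into a
# polynomial ODE amenable to the unified method.
# ---------------------------------------------------------------------------

#' Model parameters of the continuum Peyrard-Bishop equation
#'
#' @param a1 harmonic inter-site coupling (coefficient of `R_xx`)
#' @param a2 anharmonic coupling (coefficient of `3 R_x^2 R_xx`)
#' @param eta inverse width of the Morse potential; must be nonzero
#' @param zeta strength of the Morse potential
#' @param C first-integral constant (recorded per branch by the solver;
#'   defaults to 0)
#' @return an object of class `pb_params`
#' @examples
#' pb_params(a1 = 1, a2 = 1, eta = 1, zeta = 1)
#' @export
pb_params <- function(a1, a2, eta, zeta, C = 0) {
  vals <- c(a1 = a1, a2 = a2, eta = eta, zeta = zeta, C = C)
  if (any(!is.finite(vals))) stop("all model parameters must be finite")
  if (eta == 0) stop("eta must be nonzero (Morse inverse width)")
  structure(as.list(vals), class = "pb_params")
}

#' @export
print.pb_params <- function(x, ...) {
  cat(sprintf("Peyrard-Bishop parameters: a1=%g a2=%g eta=%g zeta=%g C=%g\n",
              x$a1, x$a2, x$eta, x$zeta, x$C))
  invisible(x)
}

.param_env <- function(params, extra = list()) {
  c(list(a1 = params$a1, a2 = params$a2, eta = params$eta,
         zeta = params$zeta, C = params$C), extra)
}

# --- symbolic travelling-wave chain ----------------------------------------

#' Travelling-wave reduction of the model PDE
#'
#' Substituting \eqn{R(x,t) = r(\xi)}, \eqn{\xi = x - \omega t} reduces the
#' PDE to \eqn{(\omega^2 - a_1 - 3 a_2 r'^2) r'' - 2\eta\zeta u (u - 1) = 0}
#' with \eqn{u = e^{-\eta r}}.  The expression is returned as an exact
#' polynomial in the symbols `W` (\eqn{\omega^2}), `rp` (\eqn{r'}),
#' `rpp` (\eqn{r''}), `u`, and the model constants.
#'
#' @param params optional `pb_params`; when supplied, the numeric values are
#'   substituted for `a1`, `a2`, `eta`, `zeta`
#' @param omega optional wave speed; when supplied, `W` is replaced by
#'   `omega^2`
#' @return a `pbpoly`
#' @export
traveling_reduce <- function(params = NULL, omega = NULL) {
  W <- p_sym("W"); rp <- p_sym("rp"); rpp <- p_sym("rpp"); u <- p_sym("u")
  ode <- p_mul(p_sub(p_sub(W, p_sym("a1")),
                     p_scale(p_mul(p_sym("a2"), p_pow(rp, 2)), 3)),
               rpp)
  morse <- p_scale(p_mul(p_mul(p_sym("eta"), p_sym("zeta")),
                         p_mul(u, p_sub(u, p_const(1)))), -2)
  ode <- p_add(ode, morse)
  ode <- .subst_params(ode, params)
  if (!is.null(omega)) ode <- p_subs_rat(ode, "W", p_const_frac(omega^2), p_const(1))
  ode
}

# substitute rational numeric values for model constants where given
.subst_params <- function(poly, params) {
  if (is.null(params)) return(poly)
  for (sym in c("a1", "a2", "eta", "zeta")) {
    v <- p_const_frac(params[[sym]])
    poly <- p_subs_rat(poly, sym, v, p_const(1))
  }
  poly
}

# exact rational representation of a double (only used for user parameters,
# which are short decimals in practice)
p_const_frac <- function(x) {
  if (x == round(x)) return(p_const(round(x)))
  den <- 1
  while (abs(x * den - round(x * den)) > 1e-12 && den < 1e9) den <- den * 10
  p_const(round(x * den), den)
}

#' First integral of the travelling-wave ODE
#'
#' Multiplying the reduced ODE by \eqn{r'} and integrating once yields
#' \deqn{F = \frac{\omega^2 - a_1}{2} r'^2 - \frac{3}{4} a_2 r'^4
#'       + \zeta u (u - 2) + C,}
#' with \eqn{u = e^{-\eta r}}.  The fractions 1/2 and 3/4 are fixed by the
#' exact identity \eqn{dF/d\xi = r' \times} (reduced ODE), which
#' [xi_derivative()] lets you verify symbolically.
#'
#' @inheritParams traveling_reduce
#' @return a `pbpoly` in `W`, `rp`, `u`, `C` and the model constants
#' @export
first_integral <- function(params = NULL, omega = NULL) {
  W <- p_sym("W"); rp <- p_sym("rp"); u <- p_sym("u")
  F <- p_scale(p_mul(p_sub(W, p_sym("a1")), p_pow(rp, 2)), 1, 2)
  F <- p_sub(F, p_scale(p_mul(p_sym("a2"), p_pow(rp, 4)), 3, 4))
  F <- p_add(F, p_mul(p_sym("zeta"), p_mul(u, p_sub(u, p_const(2)))))
  F <- p_add(F, p_sym("C"))
  F <- .subst_params(F, params)
  if (!is.null(omega)) F <- p_subs_rat(F, "W", p_const_frac(omega^2), p_const(1))
  F
}

#' Derivative along the travelling-wave coordinate
#'
#' Applies \eqn{d/d\xi} in the differential ring generated by
#' \eqn{r', r'', u}: \eqn{(r')' = r''} and \eqn{u' = -\eta r' u}.  Second
#' derivatives of \eqn{r} are left as the symbol `rpp`; expressions of
#' higher differential order are rejected.
#'
#' @param poly a `pbpoly` in `rp`, `u` and parameters
#' @return a `pbpoly`
#' @export
xi_derivative <- function(poly) {
  if (p_deg(poly, "rpp") > 0L)
    stop("xi_derivative supports expressions of first differential order only")
  out <- p_zero()
  # d/dxi rp^a u^b = a rp^(a-1) rpp u^b + rp^a * b u^(b-1) * (-eta rp u)
  col_rp <- p_collect(poly, "rp")
  for (i in seq_along(col_rp$deg)) {
    a <- col_rp$deg[i]
    col_u <- p_collect(col_rp$coef[[i]], "u")
    for (j in seq_along(col_u$deg)) {
      b <- col_u$deg[j]
      base <- col_u$coef[[j]]
      if (a > 0) {
        t1 <- p_mul(base, p_scale(p_mul(p_pow(p_sym("rp"), a - 1), p_sym("rpp")), a))
        t1 <- p_mul(t1, p_pow(p_sym("u"), b))
        out <- p_add(out, t1)
      }
      if (b > 0) {
        t2 <- p_mul(base, p_pow(p_sym("rp"), a + 1))
        t2 <- p_mul(t2, p_scale(p_mul(p_sym("eta"), p_pow(p_sym("u"), b)), -b))
        out <- p_add(out, t2)
      }
    }
  }
  out
}

#' Exponential substitution to polynomial form
#'
#' Applies \eqn{s = e^{-\eta r}} to the first integral and clears
#' denominators; the result (scaled by \eqn{4\eta^4 s^4}) is
#' \deqn{2\eta^2(\omega^2 - a_1) s^2 s'^2 - 3 a_2 s'^4
#'       + 4\eta^4\zeta s^5 (s - 2) + 4\eta^4 C s^4 = 0,}
#' returned as an exact polynomial in the symbols `s` and `sp`
#' (\eqn{s'}).  Back-substituting \eqn{s = u}, \eqn{s' = -\eta r' u}
#' recovers \eqn{4\eta^4 u^4 F}; a unit test asserts this identity.
#'
#' @inheritParams traveling_reduce
#' @return a `pbpoly` in `s`, `sp`, `W`, `C` and the model constants
#' @export
exp_substitute <- function(params = NULL, omega = NULL) {
  s <- p_sym("s"); sp <- p_sym("sp")
  eta2 <- p_pow(p_sym("eta"), 2); eta4 <- p_pow(p_sym("eta"), 4)
  E <- p_scale(p_mul(p_mul(eta2, p_sub(p_sym("W"), p_sym("a1"))),
                     p_mul(p_pow(s, 2), p_pow(sp, 2))), 2)
  E <- p_sub(E, p_scale(p_mul(p_sym("a2"), p_pow(sp, 4)), 3))
  E <- p_add(E, p_scale(p_mul(p_mul(eta4, p_sym("zeta")), p_pow(s, 6)), 4))
  E <- p_sub(E, p_scale(p_mul(p_mul(eta4, p_sym("zeta")), p_pow(s, 5)), 8))
  E <- p_add(E, p_scale(p_mul(p_mul(eta4, p_sym("C")), p_pow(s, 4)), 4))
  E <- .subst_params(E, params)
  if (!is.null(omega)) E <- p_subs_rat(E, "W", p_const_frac(omega^2), p_const(1))
  E
}

# --- numeric field grids ----------------------------------------------------

#' Construct a space-time field grid
#'
#' @param x strictly increasing, uniformly spaced abscissae
#' @param t strictly increasing, uniformly spaced times
#' @param R numeric matrix `length(x)` by `length(t)` of field values
#' @param mask logical matrix of the same shape marking valid points
#' @return an object of class `field_grid`
#' @export
field_grid <- function(x, t, R, mask = NULL) {
  .check_uniform <- function(v, name) {
    if (length(v) < 2) stop(name, " needs at least 2 points")
    d <- diff(v)
    if (any(d <= 0)) stop(name, " must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-12 * max(abs(d[1]), 1))
      stop(name, " must be uniformly spaced")
  }
  .check_uniform(x, "x"); .check_uniform(t, "t")
  R <- as.matrix(R)
  if (!all(dim(R) == c(length(x), length(t))))
    stop("R must be length(x) x length(t)")
  if (is.null(mask)) mask <- matrix(TRUE, length(x), length(t))
  if (any(!is.finite(R[mask]))) stop("non-finite field values inside mask")
  structure(list(x = x, t = t, R = R, mask = mask), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: %d x-points on [%g, %g], %d t-points on [%g, %g], %d masked\n",
              length(x$x), min(x$x), max(x$x), length(x$t), min(x$t), max(x$t),
              sum(!x$mask)))
  invisible(x)
}

#' Finite-difference residual of the model PDE on a field grid
#'
#' Evaluates \eqn{R_{tt} - (a_1 + 3 a_2 R_x^2) R_{xx}
#' - 2\eta\zeta e^{-\eta R}(e^{-\eta R} - 1)} with second-order central
#' stencils at interior points; boundary points are masked out.  For exact
#' closed-form solutions use [residual_closed_form()], which differentiates
#' analytically and is not limited by the stencil truncation error.
#'
#' @param field a [field_grid()]
#' @param params a [pb_params()]
#' @return a `field_grid` holding the residual, with the boundary masked
#' @export
pde_residual <- function(field, params) {
  stopifnot(inherits(field, "field_grid"), inherits(params, "pb_params"))
  nx <- length(field$x); nt <- length(field$t)
  if (nx < 5 || nt < 5) stop("need at least 5 points in x and in t")
  dx <- field$x[2] - field$x[1]; dt <- field$t[2] - field$t[1]
  R <- field$R
  ii <- 2:(nx - 1); jj <- 2:(nt - 1)
  Rxx <- (R[ii + 1, jj] - 2 * R[ii, jj] + R[ii - 1, jj]) / dx^2
  Rx  <- (R[ii + 1, jj] - R[ii - 1, jj]) / (2 * dx)
  Rtt <- (R[ii, jj + 1] - 2 * R[ii, jj] + R[ii, jj - 1]) / dt^2
  ex <- exp(-params$eta * R[ii, jj])
  res <- matrix(NA_real_, nx, nt)
  res[ii, jj] <- Rtt - (params$a1 + 3 * params$a2 * Rx^2) * Rxx -
    2 * params$eta * params$zeta * ex * (ex - 1)
  mask <- matrix(FALSE, nx, nt)
  mask[ii, jj] <- field$mask[ii, jj] &
    field$mask[ii + 1, jj] & field$mask[ii - 1, jj] &
    field$mask[ii, jj + 1] & field$mask[ii, jj - 1]
  res[!mask] <- NA_real_
  res[mask & !is.finite(res)] <- NA_real_
  field_grid(field$x, field$t, ifelse(is.na(res), 0, res), mask)
}

#' Discrete energy of a simulation state
#'
#' Trapezoid (here: Riemann, uniform periodic grid) approximation of
#' \deqn{\int \tfrac12 R_t^2 + \tfrac12 a_1 R_x^2 + \tfrac14 a_2 R_x^4
#'       + \zeta (e^{-\eta R} - 1)^2 \, dx}
#' on a periodic domain.  This functional is conserved by the dynamics;
#' its drift is the simulator's primary diagnostic.
#'
#' @param state a [sim_state()] (periodic boundary)
#' @param params a [pb_params()]
#' @return numeric scalar
#' @export
field_energy <- function(state, params) {
  stopifnot(inherits(state, "sim_state"))
  R <- state$R; V <- state$V; dx <- state$dx
  Rx <- .periodic_dx(R, dx)
  ex <- exp(-params$eta * R)
  sum(0.5 * V^2 + 0.5 * params$a1 * Rx^2 + 0.25 * params$a2 * Rx^4 +
        params$zeta * (ex - 1)^2) * dx
}

.periodic_dx <- function(v, dx) {
  n <- length(v)
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * dx)
}

.periodic_dxx <- function(v, dx) {
  n <- length(v)
  (v[c(2:n, 1)] - 2 * v + v[c(n, 1:(n - 1))]) / dx^2
}
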