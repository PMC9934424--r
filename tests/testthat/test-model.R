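# travelling-wave reduction chain and finite-difference residual

p_sub <- pbwave:::p_sub; p_mul <- pbwave:::p_mul; p_is_zero <- pbwave:::p_is_zero
p_sym <- pbwave:::p_sym; p_subs_rat <- pbwave:::p_subs_rat
p_const <- pbwave:::p_const; p_pow <- pbwave:::p_pow
p_scale <- pbwave:::p_scale; p_neg <- pbwave:::p_neg; p_add <- pbwave:::p_add

test_that("reduction degenerates to the linear wave operator when a2 = zeta = 0", {
  ode <- traveling_reduce(pb_params(a1 = 2, a2 = 0, eta = 1, zeta = 0))
  # (W - 2) rpp exactly
  expected <- p_mul(p_sub(p_sym("W"), p_const(2)), p_sym("rpp"))
  expect_true(p_is_zero(p_sub(ode, expected)))
})

test_that("the first integral differentiates back to r' times the reduced ODE", {
  # this identity pins the 1/2 and 3/4 fractions of the printed first
  # integral, which are typographically collapsed in print
  F <- first_integral()
  ode <- traveling_reduce()
  dF <- xi_derivative(F)
  expect_true(p_is_zero(p_sub(dF, p_mul(p_sym("rp"), ode))))
})

test_that("a constant profile with matching C zeroes the first integral", {
  # r = const k, u = e^{-k}; C = -zeta u (u - 2)
  k <- 0.7; u <- exp(-k)
  Cv <- -1.3 * u * (u - 2)
  F <- first_integral(pb_params(a1 = 1, a2 = 2, eta = 1, zeta = 1.3, C = Cv))
  val <- pbwave:::p_eval(F, list(W = 4, rp = 0, u = u, C = Cv))
  expect_lt(Mod(val), 1e-14)
})

test_that("the exponential substitution reproduces the first integral", {
  # substituting s = u, s' = -eta rp u turns the polynomial form into
  # 4 eta^4 u^4 times the first integral -- an exact identity
  E <- exp_substitute()
  u <- p_sym("u"); rp <- p_sym("rp"); eta <- p_sym("eta")
  E_sub <- p_subs_rat(E, "s", u, p_const(1))
  E_sub <- p_subs_rat(E_sub, "sp", p_neg(p_mul(eta, p_mul(rp, u))), p_const(1))
  F <- first_integral()
  rhs <- p_mul(p_scale(p_mul(p_pow(eta, 4), p_pow(u, 4)), 4), F)
  expect_true(p_is_zero(p_sub(E_sub, rhs)))
})

test_that("the transformed ODE balances s'^4 against s^6 at the top degree", {
  sys <- derive_algebraic_system(build_ansatz("solitary"))
  expect_equal(max(sys$lam_degrees), 12L)  # both competing terms reach 12
})

test_that("finite-difference residual vanishes on exact constant solutions", {
  x <- seq(-1, 1, length.out = 21); tt <- seq(0, 1, length.out = 11)
  p <- pb_params(1, 1, 1, 1)
  z <- field_grid(x, tt, matrix(0, 21, 11))
  expect_equal(max(abs(pde_residual(z, p)$R)), 0)
  # R = log 2: Morse term is -2 * (1/2) * (1/2 - 1) = 1/2 at every point
  c2 <- field_grid(x, tt, matrix(log(2), 21, 11))
  r <- pde_residual(c2, p)
  expect_equal(unique(round(r$R[r$mask], 12)), 0.5)
})

test_that("finite-difference residual converges at second order on a smooth solution", {
  p <- pb_params(1, 1, 1, 1)
  # the second sign branch has s > 0 on this window
  sol <- assemble_solution(solve_branches("solitary")[[2]], p,
                           std_coeffs("solitary"), c1 = 0.3)
  res_at <- function(n) {
    x <- seq(-2, 2, length.out = n)
    tt <- seq(0, 0.5, length.out = n)
    fg <- eval_family(sol, x, tt)
    max(abs(pde_residual(fg, p)$R))
  }
  e1 <- res_at(41); e2 <- res_at(81)
  expect_gt(log2(e1 / e2), 1.6)
  expect_lt(log2(e1 / e2), 2.4)
})

test_that("field grids reject malformed input", {
  expect_error(field_grid(c(0, 1, 3), c(0, 1), matrix(0, 3, 2)), "uniform")
  expect_error(field_grid(c(0, 1), c(0, 1), matrix(c(0, Inf, 0, 0), 2, 2)),
               "non-finite")
  expect_error(pde_residual(field_grid(0:3, 0:5, matrix(0, 4, 6)),
                            std_params()), "at least 5")
})
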