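# closed-form lambda(xi) integration: symbolic certificates and numerics

aux_err <- function(l, co, prefactor = function(z) 1) {
  xi <- seq(-1.1, 1.3, length.out = 41)
  z <- l$lam(xi); d <- l$dlam(xi)
  P <- (if (is.null(co$B0)) 0 else co$B0) +
    (if (is.null(co$B1)) 0 else co$B1) * z +
    (if (is.null(co$B2)) 0 else co$B2) * z^2 +
    (if (is.null(co$B4)) 0 else co$B4) * z^4
  if (l$q == 1L) max(Mod(d - P)) else max(Mod(d^2 - prefactor(z) * P))
}

test_that("all discriminant cases of the first-power auxiliary equation verify", {
  cases <- list(
    list(co = list(B0 = 1, B1 = 0, B2 = 1), case = "tangent"),      # Delta < 0
    list(co = list(B0 = -1, B1 = 0, B2 = 1), case = "hyperbolic"),  # Delta > 0
    list(co = list(B0 = 1, B1 = 2, B2 = 1), case = "rational"),     # Delta = 0
    list(co = list(B0 = 0, B1 = 1, B2 = 0), case = "exponential"),
    list(co = list(B0 = 2, B1 = 0, B2 = 0), case = "linear"))
  for (cs in cases) {
    l <- integrate_auxiliary("solitary", cs$co, c1 = 0.4)
    expect_true(l$verified, info = cs$case)
    expect_match(l$case, cs$case)
    expect_lt(aux_err(l, cs$co), 1e-10)
  }
})

test_that("standard integrals come out in closed form", {
  # lambda' = 1 + lambda^2 integrates to tan(xi + c1)
  l <- integrate_auxiliary("solitary", list(B0 = 1, B1 = 0, B2 = 1), c1 = 0.3)
  xi <- seq(-0.9, 0.9, length.out = 21)
  expect_equal(Re(l$lam(xi)), tan(xi + 0.3), tolerance = 1e-12)
  # lambda' = lambda integrates to e^(xi + c1)
  l2 <- integrate_auxiliary("solitary", list(B0 = 0, B1 = 1, B2 = 0), c1 = 0.3)
  expect_equal(Re(l2$lam(xi)), exp(xi + 0.3), tolerance = 1e-12)
})

test_that("both exponential variants of the soliton auxiliary verify", {
  for (v in c("E1", "E2")) {
    l <- integrate_auxiliary("soliton", list(B1 = -1, B2 = 3), c1 = 1,
                             variant = v)
    expect_true(l$verified)
    co <- list(B0 = 1 / 12, B1 = -1, B2 = 3)
    expect_lt(aux_err(l, co, prefactor = function(z) z^2), 1e-10)
  }
})

test_that("the even quartic integrates through Jacobi sn with derived modulus", {
  # generic quartic: true doubly periodic sn
  co <- list(B0 = 0.15, B2 = -1, B4 = 1)
  l <- integrate_auxiliary("elliptic", co, c1 = 0)
  expect_true(l$verified)
  expect_match(l$case, "sn")
  expect_lt(aux_err(l, co), 1e-10)
  # on the solved-branch constraint B0 = B2^2/(4 B4) the modulus is 1 and
  # sn degenerates to tanh
  l2 <- integrate_auxiliary("elliptic", list(B2 = -2, B4 = 1), c1 = 0)
  expect_match(l2$case, "tanh")
  expect_lt(aux_err(l2, list(B0 = 1, B2 = -2, B4 = 1)), 1e-10)
})

test_that("circular and hyperbolic second-power cases verify", {
  l <- integrate_auxiliary("periodic_rational", list(B0 = 1, B2 = 2), c1 = 0.1)
  expect_true(l$verified)
  xi <- seq(-1, 1, length.out = 31)
  z <- l$lam(xi); d <- l$dlam(xi)
  expect_lt(max(Mod(d^2 - (1 - 4 * z^2))), 1e-12)  # B0^2 - B2^2 lambda^2
  l2 <- integrate_auxiliary("soliton_rational",
                            list(B0 = 0.3, B1 = -2.5, B2 = 2), c1 = 0)
  expect_true(l2$verified)
  expect_lt(aux_err(l2, list(B0 = 0.3, B1 = -2.5, B2 = 2)), 1e-10)
  # degenerate B2 = 0 case: parabolic profile
  l3 <- integrate_auxiliary("soliton_rational",
                            list(B0 = 0.4, B1 = 1.5, B2 = 0), c1 = 0.2)
  expect_true(l3$verified)
  expect_lt(aux_err(l3, list(B0 = 0.4, B1 = 1.5, B2 = 0)), 1e-12)
})
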