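# modulation-instability dispersion, stability and gain

test_that("dispersion relation matches closed-form spot values", {
  p <- pb_params(1, 1, 1, 1)
  k <- dispersion_kappa(0, p, 0)
  expect_equal(unname(k[1, "plus"]), complex(real = 0, imaginary = sqrt(2)),
               tolerance = 1e-14)
  expect_equal(unname(k[1, "plus"] + k[1, "minus"]), 0 + 0i)
  pneg <- pb_params(1, 1, 1, -1)
  k2 <- dispersion_kappa(1, pneg, 0)
  expect_equal(unname(sort(Re(k2[1, ]))), c(-1, 1), tolerance = 1e-14)
  expect_equal(unname(Im(k2[1, ])), c(0, 0))
})

test_that("kappa agrees with a quadratic-root oracle over a fine grid", {
  # independent oracle: roots of a1 k^2 + Omega^2 + 2 (1 + Z0) zeta eta^2
  p <- pb_params(2, 0, 2, 0.5)
  Z0 <- 1
  Om <- seq(-5, 5, length.out = 1000)
  k <- dispersion_kappa(Om, p, Z0)[, "plus"]
  for (i in seq(1, 1000, by = 37)) {
    roots <- polyroot(c(Om[i]^2 + 2 * (1 + Z0) * p$zeta * p$eta^2, 0, p$a1))
    expect_lt(min(Mod(k[i] - roots)), 1e-12)
  }
  # the advertised example: a1=2, eta=2, zeta=0.5, Z0=1, Omega=2 -> +- i sqrt(6)
  expect_equal(unname(dispersion_kappa(2, p, 1)[1, "plus"]),
               complex(real = 0, imaginary = sqrt(6)), tolerance = 1e-14)
})

test_that("stability classification follows the radicand sign", {
  p <- pb_params(1, 1, 1, 1)
  expect_true(all(classify_stability(seq(0, 10, 0.5), p, 0) == "unstable"))
  pneg <- pb_params(1, 1, 1, -1)
  expect_identical(classify_stability(2, pneg, 0), "unstable")  # radicand -2
  expect_identical(classify_stability(1, pneg, 0), "stable")    # radicand +1
  # an exactly representable marginal frequency: zeta = -2, eta = 1 -> Omega* = 2
  pm <- pb_params(1, 1, 1, -2)
  expect_identical(classify_stability(2, pm, 0), "marginal")
})

test_that("gain spectrum properties: value at zero, zero where stable, parity", {
  p <- pb_params(1, 1, 1, 1)
  sp <- gain_spectrum(seq(-3, 3, length.out = 121), p, 0)
  i0 <- which(sp$Omega == 0)
  expect_equal(sp$h[i0], 2 * sqrt(2), tolerance = 1e-14)
  expect_equal(sp$h, rev(sp$h), tolerance = 1e-13)            # even in Omega
  pneg <- pb_params(1, 1, 1, -1)
  spn <- gain_spectrum(seq(0, 3, length.out = 61), pneg, 0)
  expect_true(all(spn$h[spn$label == "stable"] == 0))
  # h nondecreasing in |Omega| when zeta (1 + Z0) > 0
  expect_true(all(diff(sp$h[sp$Omega >= 0]) >= -1e-12))
  # algebraic identity between the dispersion relation and the gain
  rad <- (-sp$Omega^2 - 2 * p$zeta * p$eta^2) / p$a1
  unst <- rad < 0
  expect_lt(max(abs(sp$h[unst]^2 * p$a1 / 4 + (-sp$Omega[unst]^2 -
                                                 2 * p$zeta * p$eta^2))), 1e-12)
})

test_that("gain grows pointwise with Z0 for positive zeta", {
  p <- pb_params(1, 0, 1, 1)
  om <- seq(0, 3, length.out = 31)
  h0 <- gain_spectrum(om, p, 0)$h
  h1 <- gain_spectrum(om, p, 0.5)$h
  expect_true(all(h1 > h0))
})

test_that("the printed linearisation leaves the steady state with a constant residual", {
  x <- seq(-1, 1, length.out = 21); tt <- seq(0, 1, length.out = 21)
  p <- pb_params(1, 1, 2, 0.5)
  zero <- field_grid(x, tt, matrix(0, 21, 21))
  r0 <- linearized_residual(zero, p, Z0 = 0)
  expect_equal(max(abs(r0$R)), 0)
  r1 <- linearized_residual(zero, p, Z0 = 0.3)
  # Gamma == 0 leaves exactly 2 eta^2 zeta Z0: the printed steady state is
  # not an exact solution of the printed linearisation (documented, kept)
  expect_equal(unique(round(r1$R[r1$mask], 12)), 2 * 2^2 * 0.5 * 0.3)
})

test_that("plane waves satisfy the linearisation with its own dispersion", {
  # a plane wave solves Gamma_tt + a1 Gamma_xx + 2 eta^2 zeta Gamma = 0 when
  # kappa^2 = (2 zeta eta^2 - Omega^2)/a1; note this differs in sign from
  # the printed dispersion relation with its (1 + Z0) factor -- the
  # documented inconsistency of the printed linearisation chain, which the
  # package keeps verbatim rather than reconciling
  p <- pb_params(1, 1, 1, 1)
  Om <- 1
  kap <- sqrt((2 * p$zeta * p$eta^2 - Om^2) / p$a1)
  res_at <- function(n) {
    x <- seq(0, 2 * pi / kap, length.out = n)
    tt <- seq(0, 2 * pi / Om, length.out = n)
    G <- outer(x, tt, function(xx, ttt) cos(kap * xx - Om * ttt))
    r <- linearized_residual(field_grid(x, tt, G), p, Z0 = 0)
    max(abs(r$R[r$mask]))
  }
  e1 <- res_at(41); e2 <- res_at(81)
  expect_gt(log2(e1 / e2), 1.7)  # second-order convergence to zero
  # with the printed Eq-(28)-style kappa the same substitution leaves a
  # finite residual 4 eta^2 |zeta|: the two printed relations are not
  # mutually consistent
  pneg <- pb_params(1, 1, 1, -1)
  kap28 <- Re(dispersion_kappa(1, pneg, 0)[1, "plus"])   # radicand (2-1)/1 = 1
  x <- seq(0, 2 * pi / kap28, length.out = 81)
  tt <- seq(0, pi, length.out = 81)
  G <- outer(x, tt, function(xx, ttt) cos(kap28 * xx - ttt))
  r <- linearized_residual(field_grid(x, tt, G), pneg, Z0 = 0)
  expect_gt(max(abs(r$R[r$mask])), 1)
})
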