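# assembled closed forms: residual master property, travelling-wave
# structure, masking, classification, figure fixtures

test_that("every assembled branch drives the PDE residual to rounding level", {
  p <- std_params()
  for (fam in PB_FAMILIES) {
    brs <- solve_branches(fam)
    expect_gte(length(brs), 2L)
    for (i in seq_along(brs)) {
      sol <- assemble_solution(brs[[i]], p, std_coeffs(fam), c1 = 0.3)
      r <- residual_closed_form(sol, std_window(fam), t = c(0, 0.4))
      expect_lt(r$max_rel, 1e-8)
    }
  }
})

test_that("solutions depend on (x, t) only through x - omega t", {
  p <- std_params()
  sol <- assemble_solution(solve_branches("solitary")[[1]], p,
                           std_coeffs("solitary"), c1 = 0)
  om <- Re(sol$omega)
  x <- seq(-2, 2, length.out = 50)
  delta <- 0.37
  a <- eval_family(sol, x, 0)$R[, 1]
  b <- eval_family(sol, x + om * delta, delta)$R[, 1]
  expect_equal(a, b, tolerance = 1e-11)
})

test_that("shifting c1 translates the profile exactly", {
  p <- std_params()
  brs <- solve_branches("solitary")
  delta <- 0.61
  s1 <- assemble_solution(brs[[1]], p, std_coeffs("solitary"), c1 = 0)
  s2 <- assemble_solution(brs[[1]], p, std_coeffs("solitary"), c1 = delta)
  x <- seq(-2, 2, length.out = 101)
  expect_equal(eval_family(s2, x, 0)$R[, 1],
               eval_family(s1, x + delta, 0)$R[, 1], tolerance = 1e-11)
})

test_that("log singularities of the cosine case are masked, not returned", {
  # tangent-case solitary profile: s proportional to sec^2 never vanishes,
  # but the rational Delta = 0 case pushes s through 0 at xi + c1 = 0
  p <- std_params()
  sol <- assemble_solution(solve_branches("solitary")[[1]], p,
                           list(B0 = 1, B1 = 2, B2 = 1), c1 = 0)
  fg <- eval_family(sol, seq(-0.5, 0.5, length.out = 101), 0)
  expect_true(any(!fg$mask))            # singular point masked
  expect_true(all(is.finite(fg$R)))     # and nothing non-finite leaks out
})

test_that("real evaluation of a complex branch fails with the violated condition", {
  prm <- pb_params(a1 = 3, a2 = 2.65, eta = 7.69, zeta = -0.001)
  sol <- assemble_solution(solve_branches("soliton")[[1]], prm,
                           list(B1 = -1, B2 = 3), c1 = 1)
  expect_true(sol$complex_valued)
  expect_error(eval_family(sol, seq(-1, 1, length.out = 10), 0),
               "a2 \\* zeta > 0")
})

test_that("profile classification recognises bright, dark and periodic shapes", {
  x <- seq(-10, 10, length.out = 401)
  expect_identical(classify_profile(1 / cosh(x)^2, x)$label, "bright")
  expect_identical(classify_profile(2 - 1 / cosh(x)^2, x)$label, "dark")
  expect_identical(classify_profile(sin(3 * x), x)$label, "periodic")
  expect_error(classify_profile(numeric(10)), "100")
})

test_that("figure fixtures resolve ambiguities explicitly and classify as printed", {
  fx <- list_fixtures()
  expect_named(fx, c("fig2", "fig3", "fig4"))
  expect_identical(fx$fig2$coeffs, list(B1 = -1, B2 = 3))
  expect_identical(fx$fig2$variant, "E1")
  expect_identical(fx$fig3$variant, "E2")
  expect_identical(fx$fig4$params_variants$etaB$zeta, -0.001)
  expect_true(all(c("etaA", "etaB") %in% names(fx$fig2$params_variants)))
  # figs 2-3: soliton branch with the caption parameters is complex-valued;
  # the modulus profile (what the figures plot) is finite and shows the
  # printed dark shape (the dip sits a few units off-centre because of c1
  # and the exponential rate, hence the wide window)
  for (nm in c("fig2", "fig3")) {
    f <- fx[[nm]]
    sol <- assemble_solution(solve_branches(f$family)[[1]],
                             f$params_variants$etaB, f$coeffs,
                             c1 = f$c1, variant = f$variant)
    expect_true(sol$complex_valued)
    # locate the dip on a coarse scan, then classify a window centred on it
    # (the dip is displaced from the origin by c1 and the exponential rate)
    scan <- eval_family(sol, seq(-25, 25, length.out = 501), 0,
                        output = "modulus")
    centre <- scan$x[which.min(scan$R[, 1])]
    fg <- eval_family(sol, seq(centre - 12, centre + 12, length.out = 801),
                      0, output = "modulus")
    expect_true(all(is.finite(fg$R[fg$mask])))
    expect_identical(classify_profile(fg)$label, "dark")
  }
  # fig 4: with the real-branch zeta variant, R dips below zero around the
  # core and |R| shows the printed bright bump on the window between the
  # zero crossings (the region the published panel displays)
  f <- fx$fig4
  sol <- assemble_solution(solve_branches(f$family)[[1]],
                           f$params_variants$etaB_zetapos, f$coeffs,
                           c1 = f$c1)
  expect_false(sol$complex_valued)
  fg <- eval_family(sol, seq(-0.62, 0.62, length.out = 401), 0,
                    output = "modulus")
  expect_identical(classify_profile(fg)$label, "bright")
})

test_that("the recorded first-integral constant is honoured along the profile", {
  # F(xi) with the branch's C must be constant (zero) along the solution
  p <- std_params()
  sol <- assemble_solution(solve_branches("solitary")[[1]], p,
                           std_coeffs("solitary"), c1 = 0.3)
  xi <- seq(-3, 3, length.out = 81)
  L <- sol$lambda$lam(xi); dL <- sol$lambda$dlam(xi)
  ch <- pbwave:::.s_chain(sol, L, dL)
  rp <- -ch$sp / (p$eta * ch$s)
  Fv <- (sol$W - p$a1) / 2 * rp^2 - 0.75 * p$a2 * rp^4 +
    p$zeta * ch$s * (ch$s - 2) + sol$C_implied
  expect_lt(max(Mod(Fv)), 1e-10)
})
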