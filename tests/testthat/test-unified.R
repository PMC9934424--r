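# balance, ansatz construction, system derivation, and branch structure

p_mul <- pbwave:::p_mul; p_sub <- pbwave:::p_sub; p_is_zero <- pbwave:::p_is_zero
p_sym <- pbwave:::p_sym; p_pow <- pbwave:::p_pow; p_scale <- pbwave:::p_scale
p_add <- pbwave:::p_add; p_deg <- pbwave:::p_deg; p_zero <- pbwave:::p_zero
p_const <- pbwave:::p_const

test_that("homogeneous balance returns n = 2 for p = 2, by construction", {
  expect_identical(balance_exponents("polynomial", 2), 2L)
  expect_identical(balance_exponents("rational", 1), 0L)
})

test_that("brute-force degree enumeration confirms only n = 2 balances at p = 2", {
  # independent oracle: raw lambda-degree bookkeeping without the package's
  # balance routine: deg s'^4 = 4 (n - 1 + p), deg s^6 = 6 n, realised by
  # explicit construction for each candidate n
  lam <- p_sym("lam")
  aux <- p_add(p_add(p_const(1), lam), p_pow(lam, 2))      # degree p = 2
  hits <- integer(0)
  for (n in 1:6) {
    s <- p_zero(); for (k in 0:n) s <- p_add(s, p_pow(lam, k))
    ds <- p_zero(); for (k in 1:n) ds <- p_add(ds, p_scale(p_pow(lam, k - 1), k))
    if (p_deg(p_pow(p_mul(ds, aux), 4), "lam") == p_deg(p_pow(s, 6), "lam"))
      hits <- c(hits, n)
  }
  expect_identical(hits, 2L)
})

test_that("ansatz templates differentiate back to their auxiliary relations", {
  for (fam in c("solitary", "soliton", "elliptic",
                "periodic_rational", "soliton_rational")) {
    an <- build_ansatz(fam)
    expect_true(p_deg(an$aux_sp2, "lam") >= 2L)
    # construction identity: the solitary (lambda')^2 template is the exact
    # square of its first-power polynomial
    if (fam == "solitary") {
      lp <- p_add(p_add(p_sym("B0"), p_mul(p_sym("B1"), p_sym("lam"))),
                  p_mul(p_sym("B2"), p_pow(p_sym("lam"), 2)))
      expect_true(p_is_zero(p_sub(an$aux_sp2, p_pow(lp, 2))))
    }
  }
  expect_error(build_ansatz("nope"))
})

test_that("the collected system has the degree predicted by balance", {
  sys <- derive_algebraic_system(build_ansatz("solitary"))
  expect_equal(max(sys$lam_degrees), 12L)
  sys2 <- derive_algebraic_system(build_ansatz("soliton_rational"))
  expect_equal(max(sys2$lam_degrees), 8L)
})

test_that("solitary branches reproduce the proportionality A0:A1:A2 = B0:B1:B2", {
  for (b in solve_branches("solitary")) {
    A2 <- b$sol$A2; A1 <- b$sol$A1; A0 <- b$sol$A0
    # A1 * den(A2) * B2 == A2 * den(A1) * B1 (cross-multiplied, exact)
    expect_true(p_is_zero(p_sub(
      p_mul(p_mul(A1$num, A2$den), p_sym("B2")),
      p_mul(p_mul(A2$num, A1$den), p_sym("B1")))))
    expect_true(p_is_zero(p_sub(
      p_mul(p_mul(A0$num, A2$den), p_sym("B2")),
      p_mul(p_mul(A2$num, A0$den), p_sym("B0")))))
  }
})

test_that("the soliton branch has A0 = 0 and B0 = B1^2/(4 B2), exactly", {
  brs <- solve_branches("soliton")
  expect_gte(length(brs), 2L)   # both signs
  for (b in brs) {
    expect_true(p_is_zero(b$sol$A0$num))
    B0 <- b$sol$B0
    expect_true(p_is_zero(p_sub(
      p_scale(p_mul(B0$num, p_sym("B2")), 4),
      p_mul(B0$den, p_pow(p_sym("B1"), 2)))))
  }
})

test_that("the elliptic branch has A1 = 0 and B0 = B2^2/(4 B4), exactly", {
  for (b in solve_branches("elliptic")) {
    expect_true(p_is_zero(b$sol$A1$num))
    B0 <- b$sol$B0
    expect_true(p_is_zero(p_sub(
      p_scale(p_mul(B0$num, p_sym("B4")), 4),
      p_mul(B0$den, p_pow(p_sym("B2"), 2)))))
  }
})

test_that("both rational families solve with A1 = 0 and constrained C0", {
  for (fam in c("periodic_rational", "soliton_rational")) {
    brs <- solve_branches(fam)
    expect_gte(length(brs), 2L)
    for (b in brs) {
      expect_true(p_is_zero(b$sol$A1$num))
      expect_false(is.null(b$sol$C0))
    }
  }
  # the soliton-rational C0 carries the sqrt(B1^2 - 4 B0 B2) radical
  b <- solve_branches("soliton_rational")[[1]]
  rads <- vapply(b$radicals, function(r) pbwave:::p_format(r$num), character(1))
  expect_true(any(grepl("B1\\^2", rads) & grepl("B0", rads)))
})

test_that("branch coefficients satisfy the system numerically, real and complex", {
  p_eval <- pbwave:::p_eval
  sys <- derive_algebraic_system(build_ansatz("solitary"))
  for (zeta in c(1, -1)) {
    prm <- pb_params(1, 1, 1, zeta)
    b <- solve_branches("solitary")[[1]]
    # B0 = -1 keeps omega^2 > 0 for zeta = +1, so the whole branch is real
    # there; zeta = -1 flips the amplitude radicand and the branch turns
    # complex (back-substitution still holds exactly over C)
    co <- branch_coefficients(b, prm, list(B0 = -1, B1 = 0, B2 = 1))
    env <- c(list(a1 = 1, a2 = 1, eta = 1, zeta = zeta, B0 = -1, B1 = 0, B2 = 1),
             co[c("A0", "A1", "A2", "W", "C")])
    errs <- vapply(sys$equations, function(e) Mod(p_eval(e, env)), numeric(1))
    expect_lt(max(errs), 1e-10)
    expect_identical(co$complex_valued, zeta < 0)
  }
})

test_that("degenerate constant-s branches are excluded by default", {
  brs <- solve_branches("soliton_rational", include_degenerate = TRUE)
  expect_true(any(vapply(brs, `[[`, logical(1), "degenerate")))
  brs2 <- solve_branches("soliton_rational")
  expect_false(any(vapply(brs2, `[[`, logical(1), "degenerate")))
})
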