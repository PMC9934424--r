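# ---------------------------------------------------------------------------
# The unified-method engine: homogeneous balance, ansatz templates, the
# algebraic system obtained by collecting powers of the auxiliary function
# lambda(xi), and branch solving.
#
# Family tags and their templates (q is the power of lambda' in the
# auxiliary equation):
#   solitary           s = A0 + A1 L + A2 L^2,  L'   = B0 + B1 L + B2 L^2
#   soliton            s = A0 + A1 L + A2 L^2,  L'   = L sqrt(B0 + B1 L + B2 L^2)
#   elliptic           s = A0 + A1 L + A2 L^2,  L'^2 = B0 + B2 L^2 + B4 L^4
#   periodic_rational  s = (A0 + A1 L)/(C0 + C1 L),  L'^2 = B0^2 - B2^2 L^2
#   soliton_rational   s = (A0 + A1 L)/(C0 + C1 L),  L'^2 = B0 + B1 L + B2 L^2
# ---------------------------------------------------------------------------

PB_FAMILIES <- c("solitary", "soliton", "elliptic",
                 "periodic_rational", "soliton_rational")

#' Homogeneous-balance degree for the transformed ODE
#'
#' For the polynomial ansatz the expansion degree `n` is found by actually
#' constructing a degree-`n` ansatz with an auxiliary equation of degree `p`
#' (for the first-power auxiliary form), forming the competing terms
#' \eqn{s'^4} and \eqn{s^6} of the transformed ODE, and comparing their
#' leading \eqn{\lambda}-degrees; the returned `n` is the one that
#' equalises them.  For the rational ansatz the same pole bookkeeping at
#' \eqn{\lambda \to \infty} yields the degree relation
#' \eqn{m - l = 2(n - 1)} between numerator and denominator data.
#'
#' @param form `"polynomial"` or `"rational"`
#' @param p_or_n auxiliary degree `p` (polynomial form) or numerator degree
#'   `n` (rational form)
#' @param n_max largest candidate expansion degree tried
#' @return for `"polynomial"`: the balanced degree `n` (error if no integer
#'   balance exists); for `"rational"`: `m - l`
#' @examples
#' balance_exponents("polynomial", 2)   # 2
#' balance_exponents("rational", 1)     # 0
#' @export
balance_exponents <- function(form = c("polynomial", "rational"), p_or_n,
                              n_max = 6L) {
  form <- match.arg(form)
  if (form == "polynomial") {
    p <- as.integer(p_or_n)
    lam <- p_sym("lam")
    # generic-looking ansatz: unit coefficients realise the generic degree
    aux <- p_zero()
    for (k in 0:p) aux <- p_add(aux, p_pow(lam, k))         # lambda' , degree p
    for (n in 1:n_max) {
      s <- p_zero()
      for (k in 0:n) s <- p_add(s, p_pow(lam, k))
      ds <- p_zero()
      for (k in 1:n) ds <- p_add(ds, p_scale(p_pow(lam, k - 1), k))
      sp <- p_mul(ds, aux)                                   # s' = ds/dL * L'
      d_sp4 <- p_deg(p_pow(sp, 4), "lam")
      d_s6 <- p_deg(p_pow(s, 6), "lam")
      if (d_sp4 == d_s6) return(n)
    }
    stop("no closed balance: no integer n in 1..", n_max,
         " equalises the lambda-degrees of s'^4 and s^6 for p = ", p)
  } else {
    n <- as.integer(p_or_n)
    if (n < 1) stop("rational balance needs n >= 1")
    2L * (n - 1L)
  }
}

#' Ansatz template for one solution family
#'
#' Returns the exact symbolic pieces of the family's ansatz: the expansion
#' `s(lambda)` (as numerator/denominator polynomials) and the auxiliary
#' relation, expressed through `sp2`, the polynomial equal to
#' \eqn{(\lambda')^2} (for first-power auxiliary equations this is the
#' square of the stated \eqn{\lambda'} polynomial, so no radical survives
#' in the transformed ODE, which only contains even powers of \eqn{s'}).
#'
#' @param family one of `r paste(PB_FAMILIES, collapse=", ")`
#' @return list with `family`, `q`, `s_num`, `s_den`, `aux_sp2`
#'   (\eqn{(\lambda')^2} as a `pbpoly` in `lam` and the B symbols),
#'   `unknowns`, `nonzero`
#' @export
build_ansatz <- function(family) {
  family <- match.arg(family, PB_FAMILIES)
  L <- p_sym("lam")
  poly2 <- function(c0, c1, c2)
    p_add(p_add(c0, p_mul(c1, L)), p_mul(c2, p_pow(L, 2)))
  if (family %in% c("solitary", "soliton", "elliptic")) {
    s_num <- poly2(p_sym("A0"), p_sym("A1"), p_sym("A2"))
    s_den <- p_const(1)
    if (family == "solitary") {
      lp <- poly2(p_sym("B0"), p_sym("B1"), p_sym("B2"))
      aux <- p_pow(lp, 2); q <- 1L
      unknowns <- c("A2", "A1", "A0", "W", "C")
    } else if (family == "soliton") {
      aux <- p_mul(p_pow(L, 2), poly2(p_sym("B0"), p_sym("B1"), p_sym("B2")))
      q <- 2L
      unknowns <- c("A2", "A1", "A0", "B0", "W", "C")
    } else {
      aux <- p_add(p_add(p_sym("B0"), p_mul(p_sym("B2"), p_pow(L, 2))),
                   p_mul(p_sym("B4"), p_pow(L, 4)))
      q <- 2L
      unknowns <- c("A2", "A1", "A0", "B0", "W", "C")
    }
    nonzero <- "A2"
  } else {
    s_num <- p_add(p_sym("A0"), p_mul(p_sym("A1"), L))
    s_den <- p_add(p_sym("C0"), p_mul(p_sym("C1"), L))
    if (family == "periodic_rational") {
      aux <- p_sub(p_pow(p_sym("B0"), 2), p_mul(p_pow(p_sym("B2"), 2), p_pow(L, 2)))
    } else {
      aux <- poly2(p_sym("B0"), p_sym("B1"), p_sym("B2"))
    }
    q <- 2L
    unknowns <- c("A1", "A0", "C0", "W", "C")
    nonzero <- character(0)
  }
  list(family = family, q = q, s_num = s_num, s_den = s_den, aux_sp2 = aux,
       unknowns = unknowns, nonzero = nonzero)
}

#' Algebraic system for one ansatz
#'
#' Substitutes the ansatz into the transformed ODE
#' \eqn{2\eta^2(W - a_1) s^2 s'^2 - 3 a_2 s'^4 + 4\eta^4\zeta s^5(s-2)
#' + 4\eta^4 C s^4 = 0}, clears denominators, and collects the
#' coefficients of each power of \eqn{\lambda} into one polynomial
#' equation.  Because only even powers of \eqn{s'} occur, the square root
#' in second-power auxiliary equations never appears explicitly.
#'
#' @param ansatz result of [build_ansatz()]
#' @return list with `equations` (list of `pbpoly`, ascending
#'   \eqn{\lambda}-power), `unknowns`, `nonzero`, `ansatz`
#' @export
derive_algebraic_system <- function(ansatz) {
  num <- ansatz$s_num; den <- ansatz$s_den
  L <- p_sym("lam")
  dnum <- .d_dlam(num); dden <- .d_dlam(den)
  # s' = w * lambda' / den^2 with Wronskian w = num' den - num den'
  w <- p_sub(p_mul(dnum, den), p_mul(num, dden))
  sp2n <- p_mul(p_pow(w, 2), ansatz$aux_sp2)       # s'^2 = sp2n / den^4
  eta2 <- p_pow(p_sym("eta"), 2); eta4 <- p_pow(p_sym("eta"), 4)
  # E * den^8
  E <- p_scale(p_mul(p_mul(eta2, p_sub(p_sym("W"), p_sym("a1"))),
                     p_mul(p_mul(p_pow(num, 2), p_pow(den, 2)), sp2n)), 2)
  E <- p_sub(E, p_scale(p_mul(p_sym("a2"), p_pow(sp2n, 2)), 3))
  E <- p_add(E, p_scale(p_mul(p_mul(eta4, p_sym("zeta")),
                              p_mul(p_pow(num, 6), p_pow(den, 2))), 4))
  E <- p_sub(E, p_scale(p_mul(p_mul(eta4, p_sym("zeta")),
                              p_mul(p_pow(num, 5), p_pow(den, 3))), 8))
  E <- p_add(E, p_scale(p_mul(p_mul(eta4, p_sym("C")),
                              p_mul(p_pow(num, 4), p_pow(den, 4))), 4))
  col <- p_collect(E, "lam")
  list(equations = col$coef, lam_degrees = col$deg,
       unknowns = ansatz$unknowns, nonzero = ansatz$nonzero, ansatz = ansatz)
}

.d_dlam <- function(poly) {
  col <- p_collect(poly, "lam")
  out <- p_zero()
  for (i in seq_along(col$deg)) {
    k <- col$deg[i]
    if (k > 0)
      out <- p_add(out, p_scale(p_mul(col$coef[[i]], p_pow(p_sym("lam"), k - 1L)), k))
  }
  out
}

.degenerate_test <- function(ansatz) {
  if (p_is_const(ansatz$s_den)) {
    function(br) {
      z <- function(u) !is.null(br$sol[[u]]) && p_is_zero(br$sol[[u]]$num)
      z("A1") && z("A2")
    }
  } else {
    function(br) {
      getv <- function(u) {
        v <- br$sol[[u]]
        if (is.null(v)) list(num = p_sym(u), den = p_const(1)) else v
      }
      a1v <- getv("A1"); a0v <- getv("A0"); c0v <- getv("C0")
      # Wronskian A1 C0 - A0 C1 over the common denominator
      w <- p_sub(p_mul(p_mul(a1v$num, c0v$num), a0v$den),
                 p_mul(p_mul(a0v$num, p_sym("C1")), p_mul(a1v$den, c0v$den)))
      p_is_zero(p_gred(w, br$radicals)$p)
    }
  }
}


# Evaluate all radicals and solved unknowns of a branch at numeric parameter
# values, resolving dependencies (radicands and values may refer to other
# solved unknowns).  Returns list(vals = radical values, out = unknown
# values) or the name of the blocking quantity; `check_dens` reports an
# indeterminate (0/0) representation via attribute.
.branch_eval_env <- function(br, env, check_dens = FALSE) {
  pmag <- function(p, ev) {
    q <- p; q$num <- abs(q$num)
    Mod(p_eval(q, lapply(ev, Mod))) + 1
  }
  vals <- list(); out <- list()
  pend_r <- seq_along(br$radicals)
  pend_u <- names(br$sol)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 20L) break
    prog <- FALSE
    for (i in pend_r) {
      r <- br$radicals[[i]]
      need <- union(p_syms(r$num), p_syms(r$den))
      ev <- c(env, vals, out)
      if (all(need %in% names(ev))) {
        dn <- p_eval(r$den, ev)
        if (check_dens && Mod(dn) < 1e-9 * pmag(r$den, ev))
          return(structure("indeterminate", quantity = r$sym))
        vals[[r$sym]] <- sqrt(p_eval(r$num, ev) / dn)
        pend_r <- setdiff(pend_r, i)
        prog <- TRUE
      }
    }
    for (u in pend_u) {
      v <- br$sol[[u]]
      need <- union(p_syms(v$num), p_syms(v$den))
      ev <- c(env, vals, out)
      if (all(need %in% names(ev))) {
        dn <- p_eval(v$den, ev)
        if (check_dens && Mod(dn) < 1e-9 * pmag(v$den, ev))
          return(structure("indeterminate", quantity = u))
        out[[u]] <- p_eval(v$num, ev) / dn
        pend_u <- setdiff(pend_u, u)
        prog <- TRUE
      }
    }
    if (!prog) break
  }
  if (length(pend_r) || length(pend_u))
    return(structure("unresolved",
                     quantity = paste(c(vapply(br$radicals[pend_r], `[[`,
                                               character(1), "sym"), pend_u),
                                      collapse = ", ")))
  list(vals = vals, out = out)
}

.branch_cache <- new.env(parent = emptyenv())

#' Solve the algebraic system of a family into branches
#'
#' Runs the exact elimination solver on the collected system and returns
#' every verified, non-degenerate branch (both choices of each radical
#' sign).  Each branch records the solved coefficients as exact rational
#' expressions in the free parameters, the radical definitions
#' (`g^2 = ...`), the solved first-integral constant `C`, and `W`
#' (\eqn{\omega^2}).
#'
#' @param family family tag, or a system from [derive_algebraic_system()]
#' @param time_budget seconds allowed for the search
#' @param include_degenerate also return degenerate (constant-`s`) branches
#' @return list of branch objects of class `pb_branch`
#' @export
solve_branches <- function(family, time_budget = 600, include_degenerate = FALSE) {
  if (is.character(family)) {
    fam <- match.arg(family, PB_FAMILIES)
    key <- fam
    if (!is.null(.branch_cache[[key]])) {
      res <- .branch_cache[[key]]
    } else {
      sys <- derive_algebraic_system(build_ansatz(fam))
      res <- .solve_system_obj(sys, time_budget)
      .branch_cache[[key]] <- res
    }
  } else {
    res <- .solve_system_obj(family, time_budget)
  }
  if (!include_degenerate)
    res <- Filter(function(b) !b$degenerate, res)
  res
}

.solve_system_obj <- function(sys, time_budget) {
  degtest <- .degenerate_test(sys$ansatz)
  raw <- solve_poly_system(sys$equations, sys$unknowns, sys$nonzero,
                           degtest, time_budget = time_budget)
  raw <- Filter(.branch_evaluable, raw)
  lapply(raw, function(br) {
    br$family <- sys$ansatz$family
    br$unknowns <- sys$unknowns
    class(br) <- "pb_branch"
    br
  })
}

# A solved value whose numerator and denominator both vanish at generic
# parameters is an indeterminate 0/0 parameterisation (its pivot vanishes
# identically on the branch); such representations are redundant -- the
# vanishing-pivot case split produces the well-defined form -- and are
# dropped here.  Generic irrational test values avoid accidental zeros.
.branch_evaluable <- function(br) {
  env <- list(a1 = pi, a2 = exp(1), eta = sqrt(2), zeta = sqrt(3),
              B0 = sqrt(5), B1 = sqrt(7), B2 = sqrt(11), B4 = sqrt(13),
              C1 = sqrt(17))
  res <- .branch_eval_env(br, env, check_dens = TRUE)
  !is.character(res)
}

#' @export
print.pb_branch <- function(x, ...) {
  cat("unified-method branch, family:", x$family,
      if (x$degenerate) "(degenerate)" else "", "\n")
  for (r in x$radicals)
    cat(sprintf("  %s^2 = (%s) / (%s)\n", r$sym, p_format(r$num), p_format(r$den)))
  for (u in x$unknowns) {
    v <- x$sol[[u]]
    if (is.null(v)) cat(sprintf("  %s : free\n", u))
    else cat(sprintf("  %s = (%s) / (%s)\n", u, p_format(v$num, 8), p_format(v$den, 8)))
  }
  invisible(x)
}

#' Numeric branch coefficients for given free parameters
#'
#' Evaluates every solved unknown and radical of a branch at numeric values
#' of the free coefficients and model parameters.  Radicals are evaluated as
#' principal square roots; a negative radicand yields an imaginary value,
#' which is reported in the `complex_valued` flag (downstream evaluators
#' refuse real evaluation in that case unless complex output is requested).
#'
#' @param branch a `pb_branch`
#' @param params a [pb_params()]
#' @param coeffs named list of free coefficient values (`B0`, `B1`, `B2`,
#'   `B4`, `C1` as the family requires)
#' @return named list with complex entries for every solved unknown plus
#'   the radical values, `omega` (= principal sqrt of `W`), and
#'   `complex_valued`
#' @export
branch_coefficients <- function(branch, params, coeffs) {
  env <- .param_env(params, coeffs)
  env$C <- NULL  # the first-integral constant is solved per branch, never an input
  res <- .branch_eval_env(branch, env)
  if (is.character(res))
    stop("branch values could not be evaluated (", res, ": ",
         attr(res, "quantity"), ")")
  out <- res$out
  for (u in branch$unknowns) {
    if (is.null(branch$sol[[u]]) && !is.null(env[[u]]))
      out[[u]] <- as.complex(env[[u]])
  }
  out$radicals <- res$vals
  W <- out$W
  out$omega <- sqrt(as.complex(W))
  tolz <- 1e-12
  cplx <- any(vapply(out[branch$unknowns[branch$unknowns %in% names(out)]],
                     function(z) abs(Im(z)) > tolz * (1 + abs(z)), logical(1)))
  out$complex_valued <- cplx || abs(Im(out$omega)) > tolz * (1 + abs(out$omega))
  out
}

#' Structural summary of solved branches
#'
#' Reports, for each non-degenerate branch of a family, which coefficients
#' vanish and which auxiliary constraints hold; used as the cross-check
#' against the printed solution structure.
#'
#' @param family family tag
#' @param ... passed to [solve_branches()]
#' @return data frame with one row per branch
#' @export
branch_structure <- function(family, ...) {
  brs <- solve_branches(family, ...)
  do.call(rbind, lapply(seq_along(brs), function(i) {
    b <- brs[[i]]
    z <- function(u) !is.null(b$sol[[u]]) && p_is_zero(b$sol[[u]]$num)
    data.frame(branch = i, family = b$family,
               A0_zero = z("A0"), A1_zero = z("A1"),
               B0_solved = !is.null(b$sol[["B0"]]),
               C0_solved = !is.null(b$sol[["C0"]]),
               n_radicals = length(b$radicals))
  }))
}
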