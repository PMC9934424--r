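# ---------------------------------------------------------------------------
# Triangular elimination solver for the unified-method algebraic systems.
#
# The system is a list of exact polynomials (each equated to zero) in a set
# of unknowns, with all remaining symbols treated as free parameters.  The
# strategy, in order, at every node of the search tree:
#
#   1. equations with a monomial factor already known to be zero are dropped;
#      common monomial factors in decided-nonzero symbols are stripped;
#   2. an equation divisible by an undecided unknown forces a case split
#      (u = 0, with that equation dropped, versus u != 0);
#   3. the structure coefficients A1, A0, C0 are decided zero/nonzero up
#      front (the printed branch families differ exactly in which of these
#      vanish);
#   4. equations linear in an unknown are solved (rational value); pure even
#      quadratics introduce a radical extension symbol g with g^2 = radicand
#      and both signs are explored; general quadratics are solved through a
#      discriminant radical, but only after pseudo-remainder reduction
#      between equations sharing an unknown has been tried;
#   5. whenever a pivot coefficient contains undecided unknowns, the
#      vanishing-pivot case is explored as well (Wu-style split).
#
# Junk cofactors introduced by substitution denominators and pseudo-remainder
# leading coefficients are tracked and cancelled by exact division.  Every
# completed branch is verified by back-substitution into the original
# system; only exactly verified branches are returned.
# ---------------------------------------------------------------------------

.solver_ctx <- function(node_budget, deadline, zero_first, degtest) {
  env <- new.env(parent = emptyenv())
  env$steps <- 0L
  env$node_budget <- node_budget
  env$deadline <- deadline
  env$zero_first <- zero_first
  env$degtest <- degtest
  env$out <- list()
  env$sigs <- character(0)
  env
}

.new_branch <- function() {
  list(sol = list(), radicals = list(), assume = character(0),
       zero = character(0), factors = list(), degenerate = FALSE,
       radcount = 1L)
}

.value_sig <- function(v) paste0("(", p_format(v$num), ")/(", p_format(v$den), ")")

.branch_sig <- function(br, unknowns) {
  parts <- vapply(unknowns, function(u) {
    if (is.null(br$sol[[u]])) "free" else .value_sig(br$sol[[u]])
  }, character(1))
  rads <- vapply(br$radicals, function(r)
    paste0(r$sym, "^2=(", p_format(r$num), ")/(", p_format(r$den), ")"), character(1))
  paste(c(parts, rads), collapse = " | ")
}

.fprep <- function(p) {
  if (p_is_zero(p) || p_is_const(p)) return(NULL)
  p <- p_mono_divide(p, p_mono_mins(p))
  p <- p_content_norm(p)
  if (p_is_const(p)) NULL else p
}

.addfactor <- function(factors, p) {
  p <- .fprep(p)
  if (is.null(p)) return(factors)
  for (f in factors) if (p_equal(f, p)) return(factors)
  c(factors, list(p))
}

.cleanup_eq <- function(e, factors, allowed_idx) {
  if (p_is_zero(e)) return(e)
  mins <- p_mono_mins(e)
  mins[!(PB_SYMS %in% allowed_idx)] <- 0L
  e <- p_mono_divide(e, mins)
  e <- p_content_norm(e)
  repeat {
    changed <- FALSE
    for (f in factors) {
      q <- p_divexact(e, f)
      while (!is.null(q) && !p_is_zero(q)) {
        e <- q
        changed <- TRUE
        q <- p_divexact(e, f)
      }
    }
    if (!changed) break
    mins <- p_mono_mins(e)
    mins[!(PB_SYMS %in% allowed_idx)] <- 0L
    e <- p_mono_divide(e, mins)
    e <- p_content_norm(e)
  }
  e
}

# reduce a rational value num/den modulo the radical relations, rationalise
# the denominator, strip common monomials in safe symbols, cancel tracked
# factors; NULL when the denominator degenerates to zero
.cleanup_pair <- function(num, den, factors, radicals, safe_syms) {
  pr <- tryCatch(.pk_pair_rationalize(num, den, .rad_cpp(radicals)),
                 error = function(e) NULL)
  if (is.null(pr)) return(NULL)
  num <- .mk_poly(pr$num); den <- .mk_poly(pr$den)
  if (p_is_zero(den)) return(NULL)
  if (p_is_zero(num)) return(list(num = p_zero(), den = p_const(1)))
  m1 <- p_mono_mins(num); m2 <- p_mono_mins(den)
  common <- pmin(m1, m2)
  common[!(PB_SYMS %in% safe_syms)] <- 0L
  if (any(common > 0L)) {
    num <- p_mono_divide(num, common)
    den <- p_mono_divide(den, common)
  }
  extra <- list()
  for (src in list(num, den)) {
    f <- .fprep(src)
    if (!is.null(f)) extra <- c(extra, list(f))
  }
  repeat {
    changed <- FALSE
    for (f in c(factors, extra)) {
      qn <- p_divexact(num, f)
      if (is.null(qn)) next
      qd <- p_divexact(den, f)
      if (is.null(qd)) next
      num <- qn; den <- qd
      changed <- TRUE
    }
    if (!changed) break
  }
  # numeric content: normalise so den is primitive with positive leading term
  dnorm <- p_content_norm(den)
  # den = c * dnorm for a rational c; recover c by matching one term
  if (p_nterms(den) > 0L) {
    c_num <- den$num[1] * dnorm$den[1]
    c_den <- den$den[1] * dnorm$num[1]
    num <- p_scale(num, c_den, c_num)
    den <- dnorm
  }
  list(num = num, den = den)
}

.zero_value <- function() list(num = p_zero(), den = p_const(1))

.sub_all_eqs <- function(eqs, sym, num, den) {
  v <- .sym_index(sym)
  out <- tryCatch(lapply(eqs, function(e) .mk_poly(.pk_subs_rat(e, v, num, den, TRUE))),
                  error = function(e) NULL)
  out
}

.accept_branch <- function(ctx, br, unknowns, safe_syms) {
  br <- .back_substitute(br, unknowns, safe_syms)
  br$degenerate <- ctx$degtest(br)
  sig <- .branch_sig(br, unknowns)
  if (!(sig %in% ctx$sigs)) {
    ctx$sigs <- c(ctx$sigs, sig)
    ctx$out <- c(ctx$out, list(br))
  }
  invisible(NULL)
}

.n_nondeg <- function(ctx) sum(!vapply(ctx$out, `[[`, logical(1), "degenerate"))

# every node is wrapped so that exact-arithmetic overflow prunes the branch
# instead of aborting the search (the kernel never returns inexact results)
.eliminate <- function(ctx, eqs, unknowns, nonzero, safe, br, depth) {
  tryCatch(.eliminate_impl(ctx, eqs, unknowns, nonzero, safe, br, depth),
           error = function(e) {
             if (grepl("overflow|stabilise", conditionMessage(e)))
               invisible(NULL)
             else stop(e)
           })
}

.trace <- function(depth, ...) {
  if (isTRUE(getOption("pbwave.trace")))
    cat(strrep(" ", depth), ..., "\n")
}

.eliminate_impl <- function(ctx, eqs, unknowns, nonzero, safe, br, depth) {
  if (is.null(eqs)) return(invisible(NULL))  # overflow in substitution: prune
  ctx$steps <- ctx$steps + 1L
  .trace(depth, "[node] solved:", paste(names(br$sol), collapse=","),
         "| neq:", length(eqs), "| steps:", ctx$steps)
  if (ctx$steps > ctx$node_budget || depth > 30L) return(invisible(NULL))
  if (!is.null(ctx$deadline) && Sys.time() > ctx$deadline) return(invisible(NULL))
  if (any(vapply(eqs, p_nterms, integer(1)) > 500L)) return(invisible(NULL))

  dyn_safe <- unique(c(safe, br$assume, nonzero,
                       vapply(br$radicals, `[[`, character(1), "sym")))
  neqs <- list(); others <- list()
  for (e in eqs) {
    e <- if (length(br$radicals) == 0L) e else
      .mk_poly(.pk_gred(e, .rad_cpp(br$radicals), TRUE)$p)
    mins <- p_mono_mins(e)
    oth <- mins[mins > 0L & !(PB_SYMS %in% dyn_safe)]
    if (any(names(oth) %in% br$zero)) next  # trivially satisfied
    if (!p_is_zero(e)) e <- .cleanup_eq(e, br$factors, dyn_safe)
    neqs <- c(neqs, list(e)); others <- c(others, list(oth))
  }

  zero_branch_eqs <- function(u) {
    keep <- !vapply(others, function(o) u %in% names(o), logical(1))
    .sub_all_eqs(neqs[keep], u, p_zero(), p_const(1))
  }

  # rule 2: divisibility case split
  for (i in seq_along(neqs)) {
    split <- intersect(names(others[[i]]),
                       setdiff(unknowns, c(nonzero, names(br$sol), br$assume)))
    if (length(split) && !p_is_zero(neqs[[i]])) {
      u <- split[[1]]
      .trace(depth, "split", u, "=0 / !=0")
      do_zero <- function() {
        b0 <- br; b0$sol[[u]] <- .zero_value(); b0$zero <- c(b0$zero, u)
        .eliminate(ctx, zero_branch_eqs(u), unknowns, nonzero, safe, b0, depth + 1L)
      }
      do_nonzero <- function() {
        b1 <- br; b1$assume <- c(b1$assume, u)
        .eliminate(ctx, neqs, unknowns, nonzero, safe, b1, depth + 1L)
      }
      n0 <- .n_nondeg(ctx)
      if (ctx$zero_first) do_zero() else do_nonzero()
      if (.n_nondeg(ctx) == n0) { if (ctx$zero_first) do_nonzero() else do_zero() }
      return(invisible(NULL))
    }
  }

  eqs <- Filter(Negate(p_is_zero), neqs)
  rem <- setdiff(unknowns, names(br$sol))
  if (length(eqs) == 0L) {
    .trace(depth, "ACCEPT")
    .accept_branch(ctx, br, unknowns, safe)
    return(invisible(NULL))
  }
  for (e in eqs) if (!length(intersect(p_syms(e), rem))) {
    .trace(depth, "inconsistent")
    return(invisible(NULL))
  }

  # rule 3: structure-coefficient decision
  for (u in intersect(c("A1", "A0", "C0"), rem)) {
    if (!(u %in% nonzero) && !(u %in% br$assume) && !(u %in% br$zero)) {
      .trace(depth, "decide", u)
      do_zero <- function() {
        b0 <- br; b0$sol[[u]] <- .zero_value(); b0$zero <- c(b0$zero, u)
        .eliminate(ctx, zero_branch_eqs(u), unknowns, nonzero, safe, b0, depth + 1L)
      }
      do_nonzero <- function() {
        b1 <- br; b1$assume <- c(b1$assume, u)
        .eliminate(ctx, eqs, unknowns, nonzero, safe, b1, depth + 1L)
      }
      n0 <- .n_nondeg(ctx)
      if (ctx$zero_first) do_zero() else do_nonzero()
      if (.n_nondeg(ctx) == n0) { if (ctx$zero_first) do_nonzero() else do_zero() }
      return(invisible(NULL))
    }
  }

  # candidate steps: (needs_pivot_split, nterms, kind_rank, unknown_rank)
  cands <- list()
  for (ei in seq_along(eqs)) {
    for (u in rem) {
      d <- p_deg(eqs[[ei]], u)
      if (d == 1L) {
        piv <- p_coef(eqs[[ei]], u, 1L)
        nsplit <- length(intersect(p_syms(piv), rem)) > 0L
        cands <- c(cands, list(list(nsplit = nsplit, n = p_nterms(eqs[[ei]]),
                                    rank = 0L, ui = match(u, unknowns),
                                    ei = ei, u = u, kind = "lin")))
      } else if (d == 2L) {
        col <- p_collect(eqs[[ei]], u)
        piv <- p_coef(eqs[[ei]], u, 2L)
        nsplit <- length(intersect(p_syms(piv), rem)) > 0L
        pure <- p_is_zero(p_coef(eqs[[ei]], u, 1L))
        cands <- c(cands, list(list(nsplit = nsplit, n = p_nterms(eqs[[ei]]),
                                    rank = if (pure) 1L else 2L,
                                    ui = match(u, unknowns),
                                    ei = ei, u = u,
                                    kind = if (pure) "quad" else "quadg")))
      }
    }
  }
  primary <- list(); quadg <- list()
  if (length(cands)) {
    ord <- order(vapply(cands, function(cc) cc$nsplit, logical(1)),
                 vapply(cands, `[[`, integer(1), "n"),
                 vapply(cands, `[[`, integer(1), "rank"),
                 vapply(cands, `[[`, integer(1), "ui"),
                 vapply(cands, `[[`, integer(1), "ei"))
    cands <- cands[ord]
    seen <- character(0)
    for (cc in cands) {
      key <- paste(cc$u, cc$kind)
      if (key %in% seen) next
      seen <- c(seen, key)
      if (cc$kind == "quadg") quadg <- c(quadg, list(cc)) else primary <- c(primary, list(cc))
    }
    primary <- primary[seq_len(min(3L, length(primary)))]
    quadg <- quadg[seq_len(min(2L, length(quadg)))]
  }

    run_step <- function(cc) {
      e <- eqs[[cc$ei]]; u <- cc$u
      n0 <- .n_nondeg(ctx)
      if (cc$kind == "lin") {
        num <- p_neg(p_coef(e, u, 0L)); den <- p_coef(e, u, 1L)
        v <- .cleanup_pair(num, den, br$factors, br$radicals, safe)
        if (!is.null(v) && p_nterms(v$num) + p_nterms(v$den) <= 60L) {
          .trace(depth, u, "=", p_format(v$num, 4), "/", p_format(v$den, 4))
          b <- br; b$sol[[u]] <- v
          b$factors <- .addfactor(b$factors, v$den)
          .eliminate(ctx, .sub_all_eqs(eqs, u, v$num, v$den),
                     unknowns, nonzero, safe, b, depth + 1L)
        }
      } else if (cc$kind == "quad") {
        v <- .cleanup_pair(p_neg(p_coef(e, u, 0L)), p_coef(e, u, 2L),
                           br$factors, br$radicals, safe)
        if (!is.null(v) && p_nterms(v$num) + p_nterms(v$den) <= 60L) {
          if (p_is_zero(v$num)) {
            .trace(depth, u, "^2 = 0")
            b <- br; b$sol[[u]] <- .zero_value(); b$zero <- c(b$zero, u)
            .eliminate(ctx, .sub_all_eqs(eqs, u, p_zero(), p_const(1)),
                       unknowns, nonzero, safe, b, depth + 1L)
          } else {
            gname <- paste0("g", br$radcount)
            .trace(depth, u, "^2 ->", gname, "=", p_format(v$num, 4), "/", p_format(v$den, 4))
            for (sgn in c(1, -1)) {
              b <- br
              b$radicals <- c(b$radicals, list(list(sym = gname, num = v$num, den = v$den)))
              b$factors <- .addfactor(.addfactor(b$factors, v$num), v$den)
              b$radcount <- br$radcount + 1L
              val <- list(num = p_scale(p_sym(gname), sgn), den = p_const(1))
              b$sol[[u]] <- val
              .eliminate(ctx, .sub_all_eqs(eqs, u, val$num, val$den),
                         unknowns, nonzero, safe, b, depth + 1L)
            }
          }
        }
      } else { # quadg
        c2 <- p_coef(e, u, 2L); c1 <- p_coef(e, u, 1L); c0 <- p_coef(e, u, 0L)
        disc <- p_gred(p_sub(p_mul(c1, c1), p_scale(p_mul(c2, c0), 4)), br$radicals)$p
        if (p_is_zero(disc)) {
          v <- .cleanup_pair(p_neg(c1), p_scale(c2, 2), br$factors, br$radicals, safe)
          if (!is.null(v)) {
            b <- br; b$sol[[u]] <- v
            b$factors <- .addfactor(b$factors, v$den)
            .eliminate(ctx, .sub_all_eqs(eqs, u, v$num, v$den),
                       unknowns, nonzero, safe, b, depth + 1L)
          }
        } else {
          dv <- .cleanup_pair(disc, p_const(1), br$factors, br$radicals, safe)
          if (!is.null(dv) && p_nterms(dv$num) + p_nterms(dv$den) <= 60L) {
            gname <- paste0("g", br$radcount)
            for (sgn in c(1, -1)) {
              b <- br
              b$radicals <- c(b$radicals, list(list(sym = gname, num = dv$num, den = dv$den)))
              b$factors <- .addfactor(.addfactor(b$factors, dv$num), dv$den)
              b$radcount <- br$radcount + 1L
              v <- .cleanup_pair(p_add(p_neg(c1), p_scale(p_sym(gname), sgn)),
                                 p_scale(c2, 2), b$factors, b$radicals, safe)
              if (is.null(v)) next
              b$sol[[u]] <- v
              b$factors <- .addfactor(b$factors, v$den)
              .eliminate(ctx, .sub_all_eqs(eqs, u, v$num, v$den),
                         unknowns, nonzero, safe, b, depth + 1L)
            }
          }
        }
      }
      # vanishing-pivot branch
      if (cc$nsplit) {
        .trace(depth, "pivot=0 split for", u)
        col <- p_collect(e, u)
        dtop <- if (cc$kind == "lin") 1L else 2L
        piv <- p_coef(e, u, dtop)
        rest <- eqs[-cc$ei]
        lower <- if (cc$kind == "lin") p_coef(e, u, 0L)
                 else p_add(p_mul(p_coef(e, u, 1L), p_sym(u)), p_coef(e, u, 0L))
        neweqs <- c(rest, list(piv), if (!p_is_zero(lower)) list(lower))
        .eliminate(ctx, neweqs, unknowns, nonzero, safe, br, depth + 1L)
      }
      .n_nondeg(ctx) > n0
    }

    for (cc in primary) if (run_step(cc)) return(invisible(NULL))
  # pseudo-remainder fallback (also when no linear/quadratic candidate exists)
  for (u in rem) {
    inv <- Filter(function(e) p_deg(e, u) >= 1L, eqs)
    if (length(inv) >= 2L) {
      degs <- vapply(inv, p_deg, integer(1), sym = u)
      ord2 <- order(degs, vapply(inv, p_nterms, integer(1)))
      gx <- inv[[ord2[1]]]; f <- inv[[ord2[2]]]
      r <- tryCatch(p_prem(f, gx, u), error = function(e) NULL)
      .trace(depth, "prem", u, if (is.null(r)) "too big" else paste(p_deg(f, u), "->", p_deg(r, u)))
      if (is.null(r)) return(invisible(NULL))
      b2 <- br
      lcg <- p_coef(gx, u, p_deg(gx, u))
      b2$factors <- .addfactor(b2$factors, lcg)
      drop_i <- which(vapply(eqs, function(e) identical(e, f), logical(1)))[1]
      neweqs <- c(eqs[-drop_i], if (!p_is_zero(r)) list(r))
      .eliminate(ctx, neweqs, unknowns, nonzero, safe, b2, depth + 1L)
      return(invisible(NULL))
    }
  }
  for (cc in quadg) if (run_step(cc)) return(invisible(NULL))
  invisible(NULL)
}

.back_substitute <- function(br, unknowns, safe_syms) {
  it <- 0L
  repeat {
    changed <- FALSE
    it <- it + 1L
    if (it > 12L) break
    for (u in unknowns) {
      v <- br$sol[[u]]
      if (is.null(v)) next
      for (w in unknowns) {
        if (w == u) next
        vw <- br$sol[[w]]
        if (is.null(vw)) next
        dn <- p_deg(v$num, w); dd <- p_deg(v$den, w)
        if (dn == 0L && dd == 0L) next
        ps <- tryCatch(.pk_pair_subs(v$num, v$den, .sym_index(w), vw$num, vw$den),
                       error = function(e) NULL)
        if (is.null(ps)) next
        nv <- .cleanup_pair(.mk_poly(ps$num), .mk_poly(ps$den),
                            br$factors, br$radicals, safe_syms)
        if (is.null(nv)) next
        v <- nv
        br$sol[[u]] <- v
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (u in unknowns) {
    v <- br$sol[[u]]
    if (is.null(v)) next
    nv <- .cleanup_pair(v$num, v$den, br$factors, br$radicals, safe_syms)
    if (!is.null(nv)) br$sol[[u]] <- nv
  }
  rads <- list()
  for (r in br$radicals) {
    for (w in unknowns) {
      vw <- br$sol[[w]]
      if (is.null(vw)) next
      dn <- p_deg(r$num, w); dd <- p_deg(r$den, w)
      if (dn == 0L && dd == 0L) next
      ps <- tryCatch(.pk_pair_subs(r$num, r$den, .sym_index(w), vw$num, vw$den),
                     error = function(e) NULL)
      if (is.null(ps)) next
      others <- Filter(function(x) !identical(x$sym, r$sym), br$radicals)
      nv <- .cleanup_pair(.mk_poly(ps$num), .mk_poly(ps$den),
                          br$factors, others, safe_syms)
      if (!is.null(nv)) { r$num <- nv$num; r$den <- nv$den }
    }
    rads <- c(rads, list(r))
  }
  br$radicals <- rads
  br
}

# exact verification: substitute the branch into every original equation and
# reduce modulo the radical relations; all must vanish identically
.verify_branch <- function(br, orig_eqs) {
  sols <- lapply(names(br$sol), function(u) {
    v <- br$sol[[u]]
    list(v = .sym_index(u), num = v$num, den = v$den)
  })
  .pk_verify_modp(orig_eqs, sols, .rad_cpp(br$radicals))
}

#' Solve a unified-method algebraic system
#'
#' Runs the staged elimination search (generic branch first, then the
#' zero-coefficient subfamilies) and returns all exactly verified solution
#' branches.
#'
#' @param eqs list of `pbpoly` equations (each equated to zero)
#' @param unknowns character vector of unknown symbols, in elimination
#'   preference order
#' @param nonzero unknowns that must not vanish (e.g. the top ansatz
#'   coefficient, whose vanishing would lower the ansatz degree)
#' @param degtest function(branch) -> logical marking degenerate branches
#'   (constant \eqn{s}, hence the trivial solution)
#' @param time_budget seconds allowed for the whole search
#' @return list of verified branch objects
#' @keywords internal
solve_poly_system <- function(eqs, unknowns, nonzero, degtest,
                              time_budget = 600) {
  safe <- c("a1", "a2", "eta", "zeta", "B0", "B1", "B2", "B4", "C1",
            "g1", "g2", "g3", "g4")
  stages <- list(list(zf = FALSE, budget = 2000L, frac = 0.25),
                 list(zf = TRUE, budget = 12000L, frac = 0.75))
  res <- list()
  for (st in stages) {
    ctx <- .solver_ctx(st$budget,
                       Sys.time() + time_budget * st$frac,
                       st$zf, degtest)
    .eliminate(ctx, eqs, unknowns, nonzero, safe, .new_branch(), 0L)
    res <- ctx$out
    if (sum(!vapply(res, `[[`, logical(1), "degenerate")) >= 2L) break
  }
  ok <- vapply(res, .verify_branch, logical(1), orig_eqs = eqs)
  res[ok]
}
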