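#' @useDynLib pbwave, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Exact multivariate polynomial layer.
#
# Every polynomial lives over one fixed symbol universe so that exponent
# matrices always align.  The universe covers the unified-method unknowns,
# the model constants, radical extension symbols g1..g4 introduced while
# solving, and the generators of the small verification rings used to check
# closed-form lambda(xi) candidates (tan/tanh T, sin S, cos Cs, Jacobi sn Sn
# with dn/cn eliminated, exponential X, plus auxiliary square roots r1, r2).
# ---------------------------------------------------------------------------

PB_SYMS <- c("lam", "A0", "A1", "A2", "C0", "C1", "B0", "B1", "B2", "B4",
             "W", "C", "a1", "a2", "eta", "zeta",
             "g1", "g2", "g3", "g4",
             "u", "rp", "rpp", "s", "sp",
             "T", "S", "Cs", "Sn", "X", "r1", "r2", "m2")

.sym_index <- function(sym) {
  i <- match(sym, PB_SYMS)
  if (is.na(i)) stop("unknown symbol: ", sym)
  i
}

.mk_poly <- function(x) {
  structure(x, class = "pbpoly")
}

#' Polynomial constructors
#'
#' `p_zero()`, `p_const()` and `p_sym()` build exact polynomials over the
#' package's fixed symbol universe; all arithmetic on them is exact rational
#' arithmetic (an error is raised on coefficient overflow, never a rounded
#' result).
#'
#' @param num,den integer numerator / denominator of a rational constant
#' @param sym symbol name (one of `PB_SYMS`)
#' @param pow integer power
#' @return an object of class `pbpoly`
#' @keywords internal
p_zero <- function() {
  k <- length(PB_SYMS)
  .mk_poly(list(E = matrix(0L, 0, k), num = numeric(0), den = numeric(0)))
}

p_const <- function(num, den = 1) {
  if (num == 0) return(p_zero())
  k <- length(PB_SYMS)
  .mk_poly(list(E = matrix(0L, 1, k), num = as.numeric(num), den = as.numeric(den)))
}

p_sym <- function(sym, pow = 1L) {
  k <- length(PB_SYMS)
  E <- matrix(0L, 1, k)
  E[1, .sym_index(sym)] <- as.integer(pow)
  .mk_poly(list(E = E, num = 1, den = 1))
}

p_add <- function(a, b) .mk_poly(.pk_add(a, b))
p_sub <- function(a, b) .mk_poly(.pk_add(a, .pk_neg(b)))
p_neg <- function(a) .mk_poly(.pk_neg(a))
p_mul <- function(a, b) .mk_poly(.pk_mul(a, b))
p_pow <- function(a, e) .mk_poly(.pk_pow(a, as.integer(e)))
p_scale <- function(a, num, den = 1) .mk_poly(.pk_scale(a, num, den))

p_is_zero <- function(a) nrow(a$E) == 0L
p_is_const <- function(a) nrow(a$E) == 0L || all(a$E == 0L)
p_nterms <- function(a) nrow(a$E)
p_deg <- function(a, sym) .pk_deg(a, .sym_index(sym))
p_equal <- function(a, b) p_is_zero(p_sub(a, b))

p_syms <- function(a) {
  if (nrow(a$E) == 0L) return(character(0))
  PB_SYMS[colSums(a$E) > 0L]
}

#' Collect a polynomial by powers of one symbol
#' @return list with `deg` (integer vector) and `coef` (list of pbpoly)
#' @keywords internal
p_collect <- function(a, sym) {
  res <- .pk_collect(a, .sym_index(sym))
  res$coef <- lapply(res$coef, .mk_poly)
  res
}

p_coef <- function(a, sym, deg) {
  col <- p_collect(a, sym)
  i <- match(deg, col$deg)
  if (is.na(i)) p_zero() else col$coef[[i]]
}

# substitute sym := num/den, homogenised by den^deg (equation use)
p_subs_rat <- function(a, sym, num, den) {
  .mk_poly(.pk_subs_rat(a, .sym_index(sym), num, den))
}

p_divexact <- function(a, f) {
  r <- .pk_divexact(a, f)
  if (is.null(r)) NULL else .mk_poly(r)
}

p_prem <- function(f, g, sym, max_terms = 3000L) {
  r <- .pk_prem(f, g, .sym_index(sym), as.integer(max_terms))
  if (is.null(r)) NULL else .mk_poly(r)
}

p_content_norm <- function(a) .mk_poly(.pk_content_norm(a))

p_mono_mins <- function(a) {
  m <- .pk_mono_mins(a)
  names(m) <- PB_SYMS
  m
}

p_mono_divide <- function(a, mins) .mk_poly(.pk_mono_divide(a, as.integer(mins)))

# radicals: list of list(sym=, num=, den=) meaning sym^2 == num/den
.rad_cpp <- function(radicals) {
  lapply(radicals, function(r) list(v = .sym_index(r$sym), num = r$num, den = r$den))
}

# reduce even radical powers; returns list(p=, mul=) with  p_in * mul == p_out
p_gred <- function(a, radicals) {
  if (length(radicals) == 0L) return(list(p = a, mul = p_const(1)))
  res <- .pk_gred(a, .rad_cpp(radicals))
  list(p = .mk_poly(res$p), mul = .mk_poly(res$mul))
}

#' Evaluate a polynomial numerically
#'
#' @param a pbpoly
#' @param env named list/vector of numeric or complex values; symbols absent
#'   from `env` must not occur in `a`
#' @return a complex scalar (take `Re()` when the imaginary part vanishes)
#' @keywords internal
p_eval <- function(a, env) {
  vals <- rep(as.complex(NA), length(PB_SYMS))
  names(vals) <- PB_SYMS
  present <- p_syms(a)
  missing <- setdiff(present, names(env))
  if (length(missing)) stop("no value for symbol(s): ", paste(missing, collapse = ", "))
  vals[names(env)] <- as.complex(unlist(env))
  vals[is.na(vals)] <- 0 + 0i
  .pk_eval(a, vals)
}

#' Canonical infix rendering of an exact polynomial
#' @keywords internal
p_format <- function(a, max_terms = Inf) {
  if (p_is_zero(a)) return("0")
  tot <- rowSums(a$E)
  key <- do.call(order, c(list(-tot), lapply(seq_len(ncol(a$E)), function(j) -a$E[, j])))
  parts <- character(0)
  for (i in key) {
    mono <- character(0)
    for (j in seq_along(PB_SYMS)) {
      e <- a$E[i, j]
      if (e == 1L) mono <- c(mono, PB_SYMS[j])
      else if (e > 1L) mono <- c(mono, paste0(PB_SYMS[j], "^", e))
    }
    co <- if (a$den[i] == 1) format(a$num[i]) else paste0(a$num[i], "/", a$den[i])
    term <- if (length(mono) == 0) co
            else if (a$num[i] == 1 && a$den[i] == 1) paste(mono, collapse = "*")
            else if (a$num[i] == -1 && a$den[i] == 1) paste0("-", paste(mono, collapse = "*"))
            else paste0(co, "*", paste(mono, collapse = "*"))
    parts <- c(parts, term)
  }
  extra <- ""
  if (length(parts) > max_terms) {
    extra <- paste0(" ... (", length(parts), " terms)")
    parts <- parts[seq_len(max_terms)]
  }
  out <- paste(parts, collapse = " + ")
  out <- gsub("+ -", "- ", out, fixed = TRUE)
  paste0(out, extra)
}

#' @export
print.pbpoly <- function(x, ...) {
  cat(p_format(x, max_terms = 24), "\n")
  invisible(x)
}

#' @export
format.pbpoly <- function(x, ...) p_format(x)
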