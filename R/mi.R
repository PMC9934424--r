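# ---------------------------------------------------------------------------
# Modulation-instability analysis: the dispersion relation of plane-wave
# perturbations about the steady state of amplitude Z0, the stability
# classification, and the gain spectrum, implemented exactly as the model's
# linearisation chain states them (the (1 + Z0) factor of the dispersion
# relation is kept verbatim; see linearized_residual() for the documented
# internal inconsistency of that chain).
# ---------------------------------------------------------------------------

#' Perturbation wavenumber of the modulation-instability analysis
#'
#' \deqn{\kappa = \pm\sqrt{\frac{-\Omega^2 - 2(1+Z_0)\zeta\eta^2}{a_1}}}
#' (principal square root; both signs reported, the root with
#' \eqn{\mathrm{Im}\,\kappa \ge 0} first).
#'
#' @param Omega real perturbation frequency (vectorised)
#' @param params a [pb_params()]; `a1` must be nonzero
#' @param Z0 incident power (steady-state amplitude)
#' @return complex matrix with columns `plus`, `minus`
#' @export
dispersion_kappa <- function(Omega, params, Z0) {
  stopifnot(inherits(params, "pb_params"))
  if (params$a1 == 0) stop("a1 must be nonzero in the dispersion relation")
  radicand <- (-Omega^2 - 2 * (1 + Z0) * params$zeta * params$eta^2) / params$a1
  k <- sqrt(as.complex(radicand))
  # principal branch: Im >= 0 root first
  flip <- Im(k) < 0
  k[flip] <- -k[flip]
  cbind(plus = k, minus = -k)
}

#' Linear stability of the steady state
#'
#' Stable where the dispersion radicand is positive (real \eqn{\kappa}),
#' unstable where it is negative (imaginary \eqn{\kappa}, exponential
#' growth), marginal exactly at zero.
#'
#' @inheritParams dispersion_kappa
#' @return character vector: `"stable"`, `"unstable"` or `"marginal"`
#' @export
classify_stability <- function(Omega, params, Z0) {
  if (params$a1 == 0) stop("a1 must be nonzero in the dispersion relation")
  radicand <- (-Omega^2 - 2 * (1 + Z0) * params$zeta * params$eta^2) / params$a1
  ifelse(radicand < 0, "unstable", ifelse(radicand > 0, "stable", "marginal"))
}

#' Modulation-instability gain spectrum
#'
#' \eqn{h(\Omega) = 2\,\mathrm{Im}\,\kappa(\Omega)}, equal to
#' \eqn{2\sqrt{(\Omega^2 + 2(1+Z_0)\zeta\eta^2)/a_1}} where that radicand
#' is positive and zero where \eqn{\kappa} is real.
#'
#' @param Omega real frequency grid
#' @inheritParams dispersion_kappa
#' @return object of class `mi_spectrum`: data frame with columns
#'   `Omega`, `re_kappa`, `im_kappa`, `h`, `label`
#' @export
gain_spectrum <- function(Omega, params, Z0) {
  k <- dispersion_kappa(Omega, params, Z0)[, "plus"]
  h <- 2 * abs(Im(k))
  structure(data.frame(Omega = Omega, re_kappa = Re(k), im_kappa = Im(k),
                       h = h, label = classify_stability(Omega, params, Z0),
                       stringsAsFactors = FALSE),
            class = c("mi_spectrum", "data.frame"),
            params = params, Z0 = Z0)
}

#' Finite-difference residual of the printed linearisation
#'
#' Evaluates \eqn{\Gamma_{tt} + a_1 \Gamma_{xx} + 2\eta^2\zeta(Z_0+\Gamma)}
#' with second-order central stencils.  This operator is the model's
#' printed linearisation about the steady state; note that the constant
#' forcing \eqn{2\eta^2\zeta Z_0} shows that the steady state itself is not
#' an exact solution of this operator (evaluate on \eqn{\Gamma \equiv 0} to
#' see the residual \eqn{2\eta^2\zeta Z_0}), and that the \eqn{(1+Z_0)}
#' factor of the dispersion relation does not follow from it; both printed
#' statements are implemented verbatim rather than reconciled.
#'
#' @param field a [field_grid()] holding \eqn{\Gamma(x,t)}
#' @param params a [pb_params()]
#' @param Z0 incident power
#' @return a `field_grid` with the residual (boundary masked)
#' @export
linearized_residual <- function(field, params, Z0) {
  stopifnot(inherits(field, "field_grid"))
  nx <- length(field$x); nt <- length(field$t)
  if (nx < 5 || nt < 5) stop("need at least 5 points in x and in t")
  dx <- field$x[2] - field$x[1]; dt <- field$t[2] - field$t[1]
  G <- field$R
  ii <- 2:(nx - 1); jj <- 2:(nt - 1)
  Gxx <- (G[ii + 1, jj] - 2 * G[ii, jj] + G[ii - 1, jj]) / dx^2
  Gtt <- (G[ii, jj + 1] - 2 * G[ii, jj] + G[ii, jj - 1]) / dt^2
  res <- matrix(0, nx, nt)
  res[ii, jj] <- Gtt + params$a1 * Gxx +
    2 * params$eta^2 * params$zeta * (Z0 + G[ii, jj])
  mask <- matrix(FALSE, nx, nt)
  mask[ii, jj] <- TRUE
  field_grid(field$x, field$t, res, mask)
}
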