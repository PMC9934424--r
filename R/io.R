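# ---------------------------------------------------------------------------
# Workbench I/O: CSV for fields and spectra, JSON for branches, fixtures
# and resolved run configurations, base-graphics panel plots, and a small
# command-line driver.
# ---------------------------------------------------------------------------

#' Write / read a field grid as CSV
#'
#' Long format with columns `x`, `t`, `R`, `mask`; numeric round trip is
#' exact to the 17 significant digits written.
#'
#' @param field a [field_grid()]
#' @param path file path
#' @return `read_field_csv` returns a `field_grid`
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "field_grid"))
  df <- data.frame(x = rep(field$x, times = length(field$t)),
                   t = rep(field$t, each = length(field$x)),
                   R = as.vector(field$R),
                   mask = as.integer(as.vector(field$mask)))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "t", "R", "mask")
  if (!all(need %in% names(df)))
    stop("malformed field CSV (expected columns x, t, R, mask): ", path)
  x <- sort(unique(df$x)); t <- sort(unique(df$t))
  R <- matrix(df$R[order(df$t, df$x)], length(x), length(t))
  m <- matrix(df$mask[order(df$t, df$x)] != 0, length(x), length(t))
  field_grid(x, t, R, m)
}

#' Write / read an MI gain spectrum as CSV
#'
#' Five fixed columns: `Omega`, `re_kappa`, `im_kappa`, `h`, `label`.
#'
#' @param spec an `mi_spectrum` from [gain_spectrum()]
#' @param path file path
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "mi_spectrum"))
  df <- as.data.frame(spec)[, c("Omega", "re_kappa", "im_kappa", "h", "label")]
  num <- vapply(df[1:4], function(col) format(col, digits = 17, trim = TRUE),
                character(nrow(df)))
  out <- data.frame(num, label = df$label, stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) != 5) stop("spectrum CSV must have exactly 5 columns: ", path)
  structure(df, class = c("mi_spectrum", "data.frame"))
}

#' Serialise a solved branch to JSON
#'
#' Coefficient expressions are written as canonical infix strings in the
#' free parameters; reading back re-parses nothing (the strings are for
#' human and cross-tool consumption) but all numeric evaluations of the
#' branch can be reproduced from the recorded family, zero-pattern and
#' radical definitions via [solve_branches()], whose output is
#' deterministic.
#'
#' @param branch a `pb_branch`
#' @param path file path
#' @export
write_branch_json <- function(branch, path) {
  stopifnot(inherits(branch, "pb_branch"))
  obj <- list(
    family = branch$family,
    degenerate = branch$degenerate,
    assume_nonzero = as.list(branch$assume),
    zero = as.list(branch$zero),
    radicals = lapply(branch$radicals, function(r)
      list(sym = r$sym, num = p_format(r$num), den = p_format(r$den))),
    coefficients = {
      cl <- list()
      for (u in branch$unknowns) {
        v <- branch$sol[[u]]
        cl[[u]] <- if (is.null(v)) "free"
                   else list(num = p_format(v$num), den = p_format(v$den))
      }
      cl
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_branch_json
#' @export
read_branch_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Render the four-panel figure layout for a field
#'
#' Mirrors the published figures: (a) surface (here: filled image),
#' (b) line in x at fixed t, (c) line in t at fixed x, (d) contour plot.
#'
#' @param field a [field_grid()]
#' @param prefix output path prefix; four PNG files
#'   `<prefix>_{surface,line_x,line_t,contour}.png` are produced
#' @param modulus label axes as |R| rather than R
#' @return character vector of the four file paths
#' @export
render_panels <- function(field, prefix, modulus = FALSE) {
  stopifnot(inherits(field, "field_grid"))
  if (!any(field$mask)) stop("all-masked field; nothing to plot")
  lab <- if (modulus) "|R(x,t)|" else "R(x,t)"
  Rp <- field$R; Rp[!field$mask] <- NA
  paths <- paste0(prefix, "_", c("surface", "line_x", "line_t", "contour"), ".png")
  grDevices::png(paths[1], width = 700, height = 550)
  graphics::image(field$x, field$t, Rp, xlab = "x", ylab = "t", main = lab,
                  col = grDevices::hcl.colors(64, "viridis"))
  grDevices::dev.off()
  grDevices::png(paths[2], width = 700, height = 550)
  graphics::plot(field$x, Rp[, 1], type = "l", xlab = "x", ylab = lab,
                 main = sprintf("%s at t = %.3g", lab, field$t[1]))
  grDevices::dev.off()
  grDevices::png(paths[3], width = 700, height = 550)
  imid <- ceiling(length(field$x) / 2)
  graphics::plot(field$t, Rp[imid, ], type = "l", xlab = "t", ylab = lab,
                 main = sprintf("%s at x = %.3g", lab, field$x[imid]))
  grDevices::dev.off()
  grDevices::png(paths[4], width = 700, height = 550)
  graphics::contour(field$x, field$t, Rp, xlab = "x", ylab = "t", main = lab)
  grDevices::dev.off()
  invisible(paths)
}

#' Plot an MI gain spectrum
#'
#' @param spec an `mi_spectrum` (or a list of them for several Z0 values)
#' @param path PNG output path
#' @export
render_gain <- function(spec, path) {
  if (inherits(spec, "mi_spectrum")) spec <- list(spec)
  grDevices::png(path, width = 700, height = 550)
  cols <- grDevices::hcl.colors(max(2L, length(spec)), "Dark 3")
  ylim <- range(unlist(lapply(spec, function(s) s$h)))
  graphics::plot(spec[[1]]$Omega, spec[[1]]$h, type = "l", col = cols[1],
                 xlab = expression(Omega), ylab = "h", ylim = ylim,
                 main = "modulation-instability gain spectrum")
  if (length(spec) > 1)
    for (i in 2:length(spec))
      graphics::lines(spec[[i]]$Omega, spec[[i]]$h, col = cols[i])
  graphics::legend("topleft", bty = "n",
                   legend = vapply(spec, function(s)
                     sprintf("Z0 = %g", attr(s, "Z0")), character(1)),
                   col = cols[seq_along(spec)], lty = 1)
  grDevices::dev.off()
  invisible(path)
}

#' Command-line driver
#'
#' A thin argv-level wrapper over the package functions, for use from the
#' `inst/scripts/pbwave` Rscript.  Subcommands: `derive` (solve a family
#' and emit branch JSON), `eval` (evaluate a family on a grid, emit field
#' CSV), `verify` (residual check of every branch of a family), `mi`
#' (gain spectrum CSV + PNG), `simulate` (propagate a branch, emit
#' diagnostics CSV), `report` (regenerate all fixture outputs).  Every run
#' writes a resolved-configuration JSON next to its outputs.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit code (0 on success)
#' @export
wb_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pbwave <derive|eval|verify|mi|simulate|report> [options]",
    "  common options: --family=F --a1= --a2= --eta= --zeta= --out=DIR",
    "  family coefficients: --B0= --B1= --B2= --B4= --C1= --c1= --variant=E1|E2",
    "  eval/simulate grid: --xmin= --xmax= --nx= --tmax= --nt=",
    "  mi: --Z0=z1,z2,... --omax= --nomega=", sep = "\n")
  if (length(argv) < 1) { message(usage); return(1L) }
  cmd <- argv[1]
  if (!cmd %in% c("derive", "eval", "verify", "mi", "simulate", "report")) {
    message("unknown command: ", cmd, "\n", usage)
    return(1L)
  }
  opts <- list(family = "solitary", a1 = 1, a2 = 1, eta = 1, zeta = 1,
               B0 = NA, B1 = NA, B2 = NA, B4 = NA, C1 = NA, c1 = 0,
               variant = "E1", out = ".", xmin = -10, xmax = 10, nx = 201,
               tmax = 1, nt = 11, Z0 = "0", omax = 3, nomega = 301)
  for (a in argv[-1]) {
    m <- regmatches(a, regexec("^--([A-Za-z0-9]+)=(.*)$", a))[[1]]
    if (length(m) != 3) { message("bad option: ", a, "\n", usage); return(1L) }
    key <- m[2]
    if (!key %in% names(opts)) { message("unknown option --", key, "\n", usage); return(1L) }
    opts[[key]] <- if (key %in% c("family", "variant", "out", "Z0")) m[3]
                   else as.numeric(m[3])
  }
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  params <- pb_params(opts$a1, opts$a2, opts$eta, opts$zeta)
  coeffs <- Filter(Negate(is.na), opts[c("B0", "B1", "B2", "B4", "C1")])
  resolved <- file.path(opts$out, paste0("pbwave_", cmd, "_config.json"))
  jsonlite::write_json(c(list(command = cmd), opts), resolved,
                       auto_unbox = TRUE, pretty = TRUE)
  res <- switch(cmd,
    derive = {
      brs <- solve_branches(opts$family)
      for (i in seq_along(brs))
        write_branch_json(brs[[i]],
                          file.path(opts$out, sprintf("%s_branch%d.json",
                                                      opts$family, i)))
      message(length(brs), " branch file(s) written to ", opts$out)
      0L
    },
    eval = {
      x <- seq(opts$xmin, opts$xmax, length.out = opts$nx)
      tt <- seq(0, opts$tmax, length.out = opts$nt)
      fg <- eval_family(opts$family, x, tt, params = params, coeffs = coeffs,
                        c1 = opts$c1, variant = opts$variant)
      write_field_csv(fg, file.path(opts$out, paste0(opts$family, "_field.csv")))
      message("field written; masked points: ", sum(!fg$mask))
      0L
    },
    verify = {
      brs <- solve_branches(opts$family)
      worst <- 0
      x <- seq(opts$xmin, opts$xmax, length.out = opts$nx)
      for (b in brs) {
        sol <- assemble_solution(b, params, coeffs, c1 = opts$c1,
                                 variant = opts$variant)
        r <- residual_closed_form(sol, x, t = c(0, opts$tmax))
        worst <- max(worst, r$max_abs)
      }
      message(sprintf("max residual over %d branch(es): %.3e  %s",
                      length(brs), worst,
                      if (worst < 1e-6) "PASS" else "FAIL"))
      if (worst < 1e-6) 0L else 2L
    },
    mi = {
      z0s <- as.numeric(strsplit(opts$Z0, ",")[[1]])
      om <- seq(0, opts$omax, length.out = opts$nomega)
      specs <- lapply(z0s, function(z) gain_spectrum(om, params, z))
      for (i in seq_along(z0s))
        write_spectrum_csv(specs[[i]],
                           file.path(opts$out, sprintf("mi_Z0_%g.csv", z0s[i])))
      render_gain(specs, file.path(opts$out, "mi_gain.png"))
      message("spectra written for Z0 = ", paste(z0s, collapse = ", "))
      0L
    },
    simulate = {
      brs <- solve_branches(opts$family)
      sol <- assemble_solution(brs[[1]], params, coeffs, c1 = opts$c1,
                               variant = opts$variant)
      x <- seq(opts$xmin, opts$xmax, length.out = opts$nx + 1)[seq_len(opts$nx)]
      tr <- sim_run(sim_init(sol, x), params, T = opts$tmax)
      utils::write.csv(tr$diagnostics,
                       file.path(opts$out, "simulate_diagnostics.csv"),
                       row.names = FALSE)
      message(sprintf("simulated to t = %.3g; energy drift %.3g",
                      max(tr$times),
                      max(abs(tr$diagnostics$energy - tr$diagnostics$energy[1])) /
                        abs(tr$diagnostics$energy[1])))
      0L
    },
    report = {
      fx <- list_fixtures()
      for (nm in names(fx)) {
        f <- fx[[nm]]
        sol <- assemble_solution(solve_branches(f$family)[[1]],
                                 f$params_variants$etaB, f$coeffs,
                                 c1 = f$c1, variant = f$variant)
        fg <- eval_family(sol, seq(-5, 5, length.out = 301),
                          seq(0, 1, length.out = 11), output = "modulus")
        write_field_csv(fg, file.path(opts$out, paste0(nm, "_modulus.csv")))
        render_panels(fg, file.path(opts$out, nm), modulus = TRUE)
      }
      message("fixture report written to ", opts$out)
      0L
    })
  res
}
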