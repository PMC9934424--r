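# ---------------------------------------------------------------------------
# Method-of-lines integration of the model PDE: second-order central
# periodic differences in space, classical fourth-order Runge-Kutta in
# time, CFL-limited step size, energy/shape diagnostics.
#
# The solved travelling-wave branches of this model all have a first
# integral constant different from the Morse equilibrium value, so their
# real profiles grow linearly in |xi| rather than decaying; the simulator's
# travelling-wave benchmark therefore uses an even (reflected) periodic
# extension of the exact profile on a domain large enough that the
# slope-discontinuity artefacts at the reflection points cannot reach the
# comparison window within the integration time (finite propagation
# speed).  Smooth periodic initial data are used for the conservation and
# time-reversal checks.
# ---------------------------------------------------------------------------

#' Construct a simulation state
#'
#' @param x uniform grid (periodic; the point at `x[n] + dx` is identified
#'   with `x[1]`)
#' @param R field values
#' @param V time derivative values
#' @param time current time
#' @param cfl CFL safety factor for the adaptive step bound
#' @return object of class `sim_state`
#' @export
sim_state <- function(x, R, V, time = 0, cfl = 0.4) {
  dx <- x[2] - x[1]
  if (max(abs(diff(x) - dx)) > 1e-12 * dx) stop("grid must be uniform")
  if (any(!is.finite(R)) || any(!is.finite(V))) stop("non-finite state")
  structure(list(x = x, R = as.numeric(R), V = as.numeric(V),
                 time = time, dx = dx, cfl = cfl),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: N = %d, dx = %.4g, t = %.4g, max|R| = %.4g\n",
              length(x$x), x$dx, x$time, max(abs(x$R))))
  invisible(x)
}

.charspeed <- function(state, params) {
  Rx <- .periodic_dx(state$R, state$dx)
  sqrt(max(params$a1 + 3 * params$a2 * Rx^2, 1e-12))
}

#' Initialise a simulation from a closed-form solution
#'
#' Samples \eqn{R(x, 0)} from the evaluator and sets the initial velocity
#' from the travelling frame, \eqn{V(x,0) = -\omega\, r'(\xi)}, using the
#' analytic derivative.  With `reflect = TRUE` the profile is evaluated on
#' the half-domain and extended evenly, which makes linearly growing
#' profiles periodic (kinks at the reflection points travel at the
#' characteristic speed and are excluded from interior comparisons).
#'
#' @param sol a `pb_solution` (must be real-valued on the grid)
#' @param x periodic grid; for profiles that are even about their core
#'   (the solved branches are), centring the domain on the core makes the
#'   periodic wrap continuous, with only a slope kink at the seam
#' @param cfl CFL factor
#' @return a [sim_state()]
#' @export
sim_init <- function(sol, x, cfl = 0.4) {
  stopifnot(inherits(sol, "pb_solution"))
  if (sol$complex_valued)
    stop("cannot simulate a complex-valued branch; violated: ",
         paste(sol$reality$violated, collapse = "; "))
  prof <- .exact_profile(sol, x, 0)
  if (any(!is.finite(prof$R)))
    stop("closed form is singular on the grid; shrink the domain")
  sim_state(x, prof$R, prof$V, time = 0, cfl = cfl)
}

# exact R and V = dR/dt = -omega r'(xi) at time t (real branches)
.exact_profile <- function(sol, x, t) {
  om <- Re(sol$omega)
  xi <- x - om * t
  L <- sol$lambda$lam(xi)
  dL <- sol$lambda$dlam(xi)
  ch <- .s_chain(sol, L, dL)
  rp <- -Re(ch$sp) / (sol$params$eta * Re(ch$s))
  list(R = -log(Re(ch$s)) / sol$params$eta, V = -om * rp)
}

.rhs <- function(R, V, params, dx) {
  Rx <- .periodic_dx(R, dx)
  Rxx <- .periodic_dxx(R, dx)
  ex <- exp(-params$eta * R)
  list(dR = V,
       dV = (params$a1 + 3 * params$a2 * Rx^2) * Rxx +
         2 * params$eta * params$zeta * ex * (ex - 1))
}

#' One RK4 step
#'
#' Advances the state by one classical fourth-order Runge-Kutta step of the
#' first-order system \eqn{\dot R = V}, \eqn{\dot V = (a_1 + 3 a_2 R_x^2)
#' R_{xx} + 2\eta\zeta e^{-\eta R}(e^{-\eta R} - 1)} with periodic
#' second-order central space differences.
#'
#' @param state a [sim_state()]
#' @param params a [pb_params()]
#' @param dt time step; defaults to the CFL bound
#'   `cfl * dx / c_max` with `c_max = sqrt(a1 + 3 a2 max R_x^2)`
#' @return the advanced `sim_state`
#' @export
sim_step <- function(state, params, dt = NULL) {
  cmax <- .charspeed(state, params)
  dt_cfl <- state$cfl * state$dx / cmax
  if (is.null(dt)) dt <- dt_cfl
  else if (dt > dt_cfl * (1 + 1e-9)) dt <- dt_cfl  # auto-shrink on CFL violation
  R <- state$R; V <- state$V; dx <- state$dx
  k1 <- .rhs(R, V, params, dx)
  k2 <- .rhs(R + dt / 2 * k1$dR, V + dt / 2 * k1$dV, params, dx)
  k3 <- .rhs(R + dt / 2 * k2$dR, V + dt / 2 * k2$dV, params, dx)
  k4 <- .rhs(R + dt * k3$dR, V + dt * k3$dV, params, dx)
  Rn <- R + dt / 6 * (k1$dR + 2 * k2$dR + 2 * k3$dR + k4$dR)
  Vn <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
  if (any(!is.finite(Rn)) || any(!is.finite(Vn)))
    stop("simulation blow-up at t = ", state$time, " (NaN in state)")
  sim_state(state$x, Rn, Vn, time = state$time + dt, cfl = state$cfl)
}

#' Run a simulation to a target time
#'
#' @param state initial [sim_state()]
#' @param params a [pb_params()]
#' @param T final time
#' @param record_every record a frame every this many steps
#' @param dt fixed step (default: CFL-bounded, slightly adjusted so that
#'   `T` is hit exactly)
#' @param track which extremum the core diagnostic follows: largest
#'   deviation from the median (default), the minimum, or the maximum
#' @return object of class `pb_trajectory`: list with `frames` (times and
#'   field snapshots) and `diagnostics` (per-frame energy, max |R|, core
#'   position)
#' @export
sim_run <- function(state, params, T, record_every = 10L, dt = NULL,
                    track = c("dev", "min", "max")) {
  track <- match.arg(track)
  if (is.null(dt)) dt <- state$cfl * state$dx / .charspeed(state, params)
  nsteps <- max(1L, ceiling(T / dt))
  dt <- T / nsteps
  times <- state$time
  frames <- list(state$R)
  diag <- data.frame(time = state$time,
                     energy = field_energy(state, params),
                     maxR = max(abs(state$R)),
                     core = .core_position(state$x, state$R, track))
  for (i in seq_len(nsteps)) {
    state <- sim_step(state, params, dt)
    if (i %% record_every == 0L || i == nsteps) {
      times <- c(times, state$time)
      frames <- c(frames, list(state$R))
      diag <- rbind(diag, data.frame(time = state$time,
                                     energy = field_energy(state, params),
                                     maxR = max(abs(state$R)),
                                     core = .core_position(state$x, state$R, track)))
    }
  }
  structure(list(times = times, frames = frames, diagnostics = diag,
                 state = state, dt = dt, x = state$x),
            class = "pb_trajectory")
}

#' @export
print.pb_trajectory <- function(x, ...) {
  d <- x$diagnostics
  drift <- abs(d$energy - d$energy[1]) / max(abs(d$energy[1]), 1e-300)
  cat(sprintf("pb_trajectory: %d frames to t = %.4g; relative energy drift %.3g\n",
              length(x$times), max(x$times), max(drift)))
  invisible(x)
}

# quadratically interpolated position of the profile extremum
.core_position <- function(x, R, track = "dev") {
  dev <- switch(track,
                min = -R,
                max = R,
                abs(R - stats::median(R)))
  i <- which.max(dev)
  n <- length(x)
  im <- if (i == 1) n else i - 1
  ip <- if (i == n) 1 else i + 1
  y1 <- dev[im]; y2 <- dev[i]; y3 <- dev[ip]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-14) 0.5 * (y1 - y3) / denom else 0
  dx <- x[2] - x[1]
  x[i] + delta * dx
}

#' Measure the propagation speed of a trajectory
#'
#' Least-squares slope of the (periodically unwrapped) core position over
#' time.
#'
#' @param traj a `pb_trajectory` (at least 3 frames with one tracked core)
#' @return numeric speed estimate
#' @export
measure_speed <- function(traj) {
  d <- traj$diagnostics
  if (nrow(d) < 3) stop("need at least 3 recorded frames")
  if (max(d$maxR) < 1e-12) stop("no identifiable core in a flat field")
  Lx <- diff(range(traj$x)) + (traj$x[2] - traj$x[1])
  core <- d$core
  # periodic unwrap
  for (i in 2:length(core)) {
    while (core[i] - core[i - 1] > Lx / 2) core[i] <- core[i] - Lx
    while (core[i] - core[i - 1] < -Lx / 2) core[i] <- core[i] + Lx
  }
  unname(stats::coef(stats::lm(core ~ d$time))[2])
}
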