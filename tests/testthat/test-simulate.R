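# method-of-lines integrator: fixed point, dispersion, reversal, speed

test_that("the zero state is a fixed point", {
  p <- std_params()
  x <- seq(-5, 5, length.out = 65)[1:64]
  st <- sim_state(x, numeric(64), numeric(64))
  st2 <- sim_step(st, p)
  expect_equal(max(abs(st2$R)), 0)
  expect_equal(max(abs(st2$V)), 0)
  tr <- sim_run(st, p, T = 1)
  expect_equal(max(abs(tr$state$R)), 0)
  expect_equal(tr$diagnostics$energy, rep(0, nrow(tr$diagnostics)))
})

test_that("linear plane waves advect at speed sqrt(a1)", {
  # a2 = 0, zeta = 0: pure wave equation; standing-wave closed form
  # R = eps sin(k x) cos(sqrt(a1) k t) and phase-speed check
  p <- pb_params(a1 = 2.25, a2 = 0, eta = 1, zeta = 0)
  k <- 2 * pi / 10
  N <- 64 * 10 %/% 10 * 10   # 64 points per wavelength on one wavelength
  N <- 640
  x <- seq(0, 10, length.out = N + 1)[1:N]
  eps <- 1e-3
  st <- sim_state(x, eps * sin(k * x), numeric(N))
  Tq <- 2 * pi / (sqrt(p$a1) * k) / 4            # quarter period
  tr <- sim_run(st, p, T = Tq, record_every = 1000, dt = Tq / 400)
  # at the quarter period the standing wave passes through zero
  expect_lt(max(abs(tr$state$R)) / eps, 0.005)
  # energy of the linear wave is constant within discretisation error
  en <- tr$diagnostics$energy
  expect_lt(max(abs(en - en[1])) / en[1], 1e-4)
})

test_that("a synthetically translated Gaussian measures its own speed", {
  x <- seq(-10, 10, length.out = 401)[1:400]
  mk <- function(t) exp(-((x - 0.7 * t)^2))
  traj <- structure(list(
    times = seq(0, 2, by = 0.25),
    frames = lapply(seq(0, 2, by = 0.25), mk),
    diagnostics = data.frame(
      time = seq(0, 2, by = 0.25),
      energy = 1, maxR = 1,
      core = vapply(seq(0, 2, by = 0.25), function(t)
        pbwave:::.core_position(x, mk(t), "max"), numeric(1))),
    x = x), class = "pb_trajectory")
  expect_equal(measure_speed(traj), 0.7, tolerance = 1e-3)
  # a stationary profile has speed 0
  traj$diagnostics$core <- rep(traj$diagnostics$core[1], 9)
  expect_equal(measure_speed(traj), 0, tolerance = 1e-12)
  # flat field has no core
  traj$diagnostics$maxR <- 0
  expect_error(measure_speed(traj), "core")
})

test_that("exact initial data from a branch set V to -omega r'", {
  p <- std_params()
  sol <- assemble_solution(solve_branches("elliptic")[[2]], p,
                           list(B2 = -0.5, B4 = 1), c1 = 0)
  x <- seq(-8, 8, length.out = 257)[1:256]
  st <- sim_init(sol, x)
  # centred finite-difference dR/dt of the evaluator at t = 0
  h <- 1e-5
  Rp <- pbwave:::.exact_profile(sol, x, h)$R
  Rm <- pbwave:::.exact_profile(sol, x, -h)$R
  expect_equal(st$V, (Rp - Rm) / (2 * h), tolerance = 1e-7)
  # characteristic speed matches its definition
  Rx <- pbwave:::.periodic_dx(st$R, st$dx)
  expect_equal(pbwave:::.charspeed(st, p),
               sqrt(p$a1 + 3 * p$a2 * max(Rx^2)), tolerance = 1e-12)
})

test_that("time reversal returns the initial state at fixed dt", {
  p <- std_params()
  N <- 256
  x <- seq(-10, 10, length.out = N + 1)[1:N]
  st <- sim_state(x, 0.3 * exp(-x^2 / 2), numeric(N))
  fw <- sim_run(st, p, T = 1, record_every = 1000, dt = 0.002)
  back <- fw$state; back$V <- -back$V
  bw <- sim_run(back, p, T = 1, record_every = 1000, dt = 0.002)
  expect_lt(max(abs(bw$state$R - st$R)), 1e-8)
})

test_that("travelling-wave initial data stays on the exact orbit (interior)", {
  p <- std_params()
  sol <- assemble_solution(solve_branches("elliptic")[[2]], p,
                           list(B2 = -0.5, B4 = 1), c1 = 0)
  N <- 1024
  x <- seq(-17, 17, length.out = N + 1)[1:N]
  tr <- sim_run(sim_init(sol, x), p, T = 2, record_every = 50, track = "min")
  ex <- pbwave:::.exact_profile(sol, x, max(tr$times))$R
  win <- abs(x) < 8   # seam artefacts propagate inward at finite speed
  expect_lt(max(abs(tr$state$R[win] - ex[win])), 1e-2)
})

test_that("blow-up is reported, not returned", {
  p <- pb_params(1, 1, 1, -50)   # inverted Morse well
  N <- 64
  x <- seq(-5, 5, length.out = N + 1)[1:N]
  st <- sim_state(x, 3 * sin(2 * pi * x / 10), numeric(N), cfl = 2.5)
  expect_error(suppressWarnings(sim_run(st, p, T = 50, dt = 1.2)),
               "blow-up|non-finite")
})
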