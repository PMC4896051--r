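test_that("passive equilibrium: dv/dt = 0 at the leak reversal", {
  m <- point_cell_model(gnabar = 0, gkbar = 0, el = -60, v_init = -60)
  d <- hh_derivatives(c(-60, 0.05, 0.6, 0.3), 0, m)
  expect_equal(d[1], 0)
})

test_that("resting potential agrees with an independent root-solve", {
  m <- point_cell_model()
  # steady-state total membrane current as a function of voltage
  i_ss <- function(v) {
    ss <- ephysopt:::hh_steady_state(v)
    m$gnabar * ss[["m"]]^3 * ss[["h"]] * (v - m$ena) +
      m$gkbar * ss[["n"]]^4 * (v - m$ek) + m$gl * (v - m$el)
  }
  v_rest <- uniroot(i_ss, c(-90, -40))$root
  tr <- run_sweep(m, square_pulse(0, 0, 0, 300))
  expect_lt(abs(tr$v[length(tr$v)] - v_rest), 1)
  # zero current: settles near rest and never exceeds v_init + 5 mV
  expect_true(all(abs(tr$v[tr$t > 50] - v_rest) < 1))
  expect_true(all(tr$v <= m$v_init + 5))
})

test_that("compiled integrator agrees with an R-side RK4 on hh_derivatives", {
  m <- point_cell_model()
  stim <- square_pulse(0.05, 2, 6, 10)
  dt <- 0.025
  s <- c(m$v_init, ephysopt:::hh_steady_state(m$v_init))
  vr <- numeric(0)
  for (k in 0:(10 / dt - 1)) {
    t <- k * dt
    # midpoint current held for the whole step (piecewise-constant input)
    ii <- if (t + dt / 2 >= 2 && t + dt / 2 < 8) 0.05 else 0
    k1 <- hh_derivatives(s, ii, m)
    k2 <- hh_derivatives(s + dt / 2 * k1, ii, m)
    k3 <- hh_derivatives(s + dt / 2 * k2, ii, m)
    k4 <- hh_derivatives(s + dt * k3, ii, m)
    s <- unname(s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    vr <- c(vr, s[1])
    # gating variables stay in [0,1] along the trajectory
    expect_true(all(s[2:4] >= 0 & s[2:4] <= 1))
  }
  tr <- run_sweep(m, stim, dt = dt)
  expect_equal(tr$v[-1], vr, tolerance = 1e-10)
})

test_that("halving dt changes the trace by < 0.1 mV (self-convergence)", {
  m <- point_cell_model(gnabar = 0.11, gkbar = 0.04)
  stim <- square_pulse(0.05, 100, 50, 200)
  tr1 <- run_sweep(m, stim, dt = 0.025, record_dt = 0.1)
  tr2 <- run_sweep(m, stim, dt = 0.0125, record_dt = 0.1)
  expect_equal(tr1$t, tr2$t)
  expect_lt(max(abs(tr1$v - tr2$v)), 0.1)
})

test_that("spike count is stable under dt refinement across the demo bounds", {
  stims <- list(square_pulse(0.01, 100, 50, 200),
                square_pulse(0.05, 100, 50, 200))
  for (gna in seq(0.05, 0.125, length.out = 10)) {
    for (gk in seq(0.01, 0.075, length.out = 10)) {
      m <- point_cell_model(gnabar = gna, gkbar = gk)
      for (stim in stims) {
        n1 <- compute_feature(run_sweep(m, stim, dt = 0.025), "Spikecount")
        n2 <- compute_feature(run_sweep(m, stim, dt = 0.0125,
                                        record_dt = 0.025), "Spikecount")
        expect_identical(n1, n2)
      }
    }
  }
})

test_that("distance scaler: parse-time validation and evaluation", {
  tmpl <- "(-0.8696 + 2.087*math.exp(({distance})*0.0031))*{value}"
  sc <- scaler_expression(tmpl)
  expect_equal(scale_by_distance(sc, 0, 500), 0)       # multiplicative in value
  expect_equal(scale_by_distance(sc, 8e-5, 0), (-0.8696 + 2.087) * 8e-5)
  # strictly increasing in distance for positive value
  d <- seq(0, 1000, by = 50)
  vals <- scale_by_distance(sc, 8e-5, d)
  expect_true(all(diff(vals) > 0))
  expect_error(scaler_expression("{distance} * ("), "malformed")
  expect_error(scaler_expression("system('ls') * {value}"), "disallowed")
})

test_that("SWC stub parsing: one-point soma only", {
  path <- system.file("extdata", "simple_soma.swc", package = "ephysopt")
  soma <- read_swc_soma(path)
  expect_equal(soma$radius, 5)
  expect_equal(soma$area_cm2, 4 * pi * 25 * 1e-8)
  m <- point_cell_model(morphology = path)
  expect_equal(m$area_cm2, pi * 10 * 10 * 1e-8)  # 10x10 um cylinder area
  multi <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 0 10 1 1"), multi)
  expect_error(read_swc_soma(multi), "unsupported")
})

test_that("trace text round trip preserves samples and stimulus window", {
  tr <- run_sweep(point_cell_model(), square_pulse(0.05, 100, 50, 200))
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$v, tr$v)
  expect_equal(tr2$stim_start, 100)
  expect_equal(tr2$stim_end, 150)
})
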