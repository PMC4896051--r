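test_that("calcium events: enumeration, counting, ordering", {
  p <- gb_params(c_pre = 1.5, c_post = 2, delay_d = 0)
  pr <- pairing_protocol("x", 0, n_post = 1)
  ev <- calcium_events(pr, p)
  expect_equal(nrow(ev), 2)                     # 1 + n_post
  expect_equal(ev$time, c(0, 0))                # simultaneous
  expect_setequal(ev$amplitude, c(1.5, 2))
  # delta_t +10 ms, delay 5 ms: pre transient at 5 ms, burst at 10/30/50 ms
  p2 <- gb_params(c_pre = 1.5, c_post = 2, delay_d = 0.005)
  pr2 <- pairing_protocol("y", 0.010, n_post = 3, post_freq = 50)
  ev2 <- calcium_events(pr2, p2)
  expect_equal(ev2$time, c(0.005, 0.010, 0.030, 0.050))
  expect_equal(ev2$amplitude, c(1.5, 2, 2, 2))
  # negative delta_t: burst precedes the presynaptic transient
  pr3 <- pairing_protocol("z", -0.050, n_post = 3, post_freq = 50)
  ev3 <- calcium_events(pr3, p2)
  expect_equal(ev3$time, c(-0.050, -0.030, -0.010, 0.005))
})

test_that("time above threshold: closed forms and grid oracle", {
  tau_ca <- 0.02
  # single event: tau_ca * log(c0 / theta)
  expect_equal(time_above_threshold(0, 3, 1, tau_ca), tau_ca * log(3))
  # sub-threshold events with no superposition
  expect_equal(time_above_threshold(c(0, 1), c(0.5, 0.9), 1, tau_ca), 0)
  expect_error(time_above_threshold(0, 1, -1, tau_ca), "theta")
  # 4-event fixture against dense-grid integration
  times <- c(0, 0.005, 0.013, 0.040); amps <- c(0.8, 0.7, 0.5, 1.2)
  dt_grid <- tau_ca / 5000
  expect_lt(abs(time_above_threshold(times, amps, 1, tau_ca) -
                  oracle_time_above(times, amps, 1, tau_ca, dt_grid)),
            2 * dt_grid)
  # property: random event sets
  set.seed(404)
  for (rep in 1:30) {
    ne <- sample(2:8, 1)
    times <- sort(runif(ne, 0, 0.15))
    amps <- runif(ne, 0.2, 2.5)
    tau <- runif(1, 0.005, 0.05)
    theta <- runif(1, 0.5, 1.5)
    dt_grid <- tau / 3000
    expect_lt(abs(time_above_threshold(times, amps, theta, tau) -
                    oracle_time_above(times, amps, theta, tau, dt_grid)),
              2 * dt_grid)
  }
  # analytic layer agrees with the exact superposition evaluator
  cc <- calcium_at(c(0.001, 0.02, 0.05), times = c(0, 0.01),
                   amps = c(1, 0.5), tau_ca = 0.02)
  expect_equal(cc[1], 1 * exp(-0.001 / 0.02))
  expect_equal(cc[2], exp(-1) + 0.5 * exp(-0.01 / 0.02))
})

test_that("effective dynamics: ratio identities and no-drive flag", {
  p <- gb_params()
  expect_equal(effective_dynamics(p, 0.01, 0)$rho_bar, 1)
  p_sym <- gb_params(gamma_p = 800, gamma_d = 800)
  expect_equal(effective_dynamics(p_sym, 0.004, 0.004)$rho_bar, 0.5)
  nd <- effective_dynamics(p, 0, 0)
  expect_true(nd$no_drive)
})

test_that("averaged-dynamics moments match an Euler-Maruyama oracle", {
  # the variance constant is frozen only because this oracle validates it
  p <- gb_params(gamma_p = 1133, gamma_d = 361.6, sigma = 4.557, tau = 1005)
  alpha_p <- 0.003; alpha_d <- 0.005
  eff <- effective_dynamics(p, alpha_p, alpha_d)
  t_end <- 2 * eff$tau_eff
  n <- 5e4; nstep <- 400; dt <- t_end / nstep
  noise_amp <- p$sigma * sqrt((alpha_p + alpha_d) / p$tau)
  set.seed(55)
  rho <- rep(0.2, n)
  for (s in seq_len(nstep)) {
    rho <- rho - (rho - eff$rho_bar) / eff$tau_eff * dt +
      noise_amp * sqrt(dt) * rnorm(n)
  }
  mean_th <- eff$rho_bar + (0.2 - eff$rho_bar) * exp(-t_end / eff$tau_eff)
  var_th <- eff$sigma_rho_sq * (1 - exp(-2 * t_end / eff$tau_eff))
  expect_lt(abs(mean(rho) - mean_th), 3 * sd(rho) / sqrt(n))
  expect_lt(abs(var(rho) - var_th), 3 * var(rho) * sqrt(2 / (n - 1)))
})

test_that("transition probabilities: no-drive, limits", {
  p <- gb_params()
  k <- gb_constants()
  expect_equal(transition_probabilities(p, k, 0, 0, 600), c(U = 0, D = 0))
  # overwhelming potentiation drive, long protocol, small noise
  p_strong <- gb_params(gamma_p = 2500, gamma_d = 5, sigma = 0.35, tau = 2.5)
  ud <- transition_probabilities(p_strong, k, 0.05, 0.05, 600)
  expect_gt(ud[["U"]], 0.999)
  expect_lt(ud[["D"]], 0.001)
})

test_that("analytic layer matches the full stochastic model (strong drive)", {
  fx <- strong_drive_fixture()
  a <- ephysopt:::alpha_fractions(fx$protocol, fx$params, fx$constants)
  t_total <- fx$protocol$n_reps / fx$protocol$rep_freq
  ud <- transition_probabilities(fx$params, fx$constants, a[["alpha_p"]],
                                 a[["alpha_d"]], t_total)
  n <- 2000
  set.seed(77)
  sim <- simulate_gb(fx$params, fx$constants, fx$protocol, n_trials = n)
  expect_lt(abs(ud[["U"]] - sim$U), 0.05)
  expect_lt(abs(ud[["D"]] - sim$D), 0.05)
  g_an <- protocol_outcome(fx$protocol, fx$params, fx$constants)
  se <- mc_gain_se(sim$U, sim$D, n, fx$params$b, fx$constants$beta)
  expect_lt(abs(g_an - sim$gain), 3 * se)
})

test_that("stochastic oracle basic behaviour", {
  k <- gb_constants()
  # calcium never crosses theta_d: rho stays at the fixed point 0
  p_low <- gb_params(c_pre = 0.3, c_post = 0.3, tau_ca = 0.009,
                     delay_d = 0, tau = 2500)
  pr <- pairing_protocol("low", 0, n_reps = 5, rep_freq = 1)
  set.seed(9)
  rho <- simulate_gb(p_low, k, pr, n_trials = 50, rho0 = 0)
  expect_true(all(rho == 0))
  expect_equal(protocol_outcome(pr, p_low, k), 1)  # U = D = 0 -> gain 1
  # strong pure-potentiation drive ends above rho_star from rho0 = 0
  p_pot <- gb_params(c_pre = 6, c_post = 6, tau_ca = 0.009, delay_d = 0,
                     gamma_p = 2500, gamma_d = 5, sigma = 0.35, tau = 10)
  set.seed(10)
  rho <- simulate_gb(p_pot, k, pairing_protocol("pot", 0, n_reps = 30,
                                                rep_freq = 1),
                     n_trials = 30, rho0 = 0)
  expect_true(all(rho > k$rho_star))
})

test_that("gain is monotone in the threshold time fractions", {
  p <- gb_params(sigma = 2)
  k <- gb_constants()
  gain_from <- function(ap, ad) {
    ud <- transition_probabilities(p, k, ap, ad, 600)
    after <- k$beta * (1 - ud[["D"]]) + (1 - k$beta) * ud[["U"]]
    (after * p$b + 1 - after) / (k$beta * p$b + 1 - k$beta)
  }
  ap_grid <- seq(0.0005, 0.004, length.out = 8)
  g_up <- vapply(ap_grid, gain_from, numeric(1), ad = 0.002)
  expect_true(all(diff(g_up) >= -1e-12))
  g_dn <- vapply(ap_grid, function(ad) gain_from(0.002, ad), numeric(1))
  expect_true(all(diff(g_dn) <= 1e-12))
})

test_that("dataset error vector: identities and alignment", {
  p <- gb_params()
  ds <- make_stdp_dataset(p, protocols = nevian_protocols(c(-50, 10)),
                          noise_sd = 0)
  err <- suppressWarnings(
    gb_evaluate(p, ds, dataset_protocols(ds)))
  expect_equal(unname(err), c(0, 0))
  # printed-arithmetic check: sg 1.5, gain 1.2, stderr 0.1 -> 3
  ds2 <- ds
  ds2$sg <- ds2$sg + 0.3
  ds2$stderr <- 0.1
  err2 <- suppressWarnings(gb_evaluate(p, ds2, dataset_protocols(ds2)))
  expect_equal(unname(err2), c(3, 3), tolerance = 1e-9)
  expect_error(gb_evaluate(p, ds, dataset_protocols(ds)[1]), "align")
})

test_that("plasticity dataset file round trip and validation", {
  ds <- make_stdp_dataset(gb_params(), noise_sd = 0.05, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_plasticity_dataset(ds, f)
  ds2 <- read_plasticity_dataset(f)
  expect_equal(ds2$sg, ds$sg)
  expect_equal(ds2$delta_t_ms, ds$delta_t_ms)
  bad <- ds; bad$stderr[2] <- 0
  expect_error(write_plasticity_dataset(bad, f), "stderr")
  g <- tempfile()
  writeLines(c("a\tb", "1\t2"), g)
  expect_error(read_plasticity_dataset(g), "missing column")
})

test_that("gb_params enforces the fitting bounds", {
  expect_error(gb_params(tau_ca = 0.5), "tau_ca")
  expect_error(gb_params(b = 0.5), "'b'")
  expect_s3_class(gb_params(), "gb_params")
})

test_that("packaged synthetic dataset reproduces the in-vitro curve shape", {
  path <- system.file("extdata", "synthetic_stdp_dataset.tsv",
                      package = "ephysopt")
  ds <- read_plasticity_dataset(path)
  expect_equal(nrow(ds), 8)
  g <- gain_curve(gb_params(), delta_t_ms = c(-50, 10),
                  template = dataset_protocols(ds)[[1]])
  expect_lt(g$gain[g$delta_t_ms == -50], 1)   # LTD side
  expect_gt(g$gain[g$delta_t_ms == 10], 1)    # LTP side
})
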