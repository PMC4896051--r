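# Independent oracles used by the unit and acceptance tests.
# These deliberately re-derive everything from first principles with
# naive double loops / dense grids, sharing no code with the package
# internals they check.

# brute-force IBEA fitness: explicit double loop over ordered pairs
oracle_ibea_fitness <- function(objs, kappa = 0.05) {
  n <- nrow(objs); m <- ncol(objs)
  lo <- apply(objs, 2, min); hi <- apply(objs, 2, max)
  norm <- objs
  for (j in seq_len(m)) {
    norm[, j] <- if (hi[j] > lo[j]) (objs[, j] - lo[j]) / (hi[j] - lo[j]) else 0
  }
  ind <- function(a, b) max(norm[a, ] - norm[b, ])
  c_abs <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
    c_abs <- max(c_abs, abs(ind(a, b)))
  if (c_abs <= 0) c_abs <- 1
  fit <- numeric(n)
  for (x in seq_len(n)) {
    s <- 0
    for (y in seq_len(n)) if (y != x) s <- s - exp(-ind(y, x) / (c_abs * kappa))
    fit[x] <- s
  }
  list(fitness = fit, c = c_abs, norm = norm)
}

# recompute-from-scratch environmental selection: at every removal step the
# fitness of the survivors is rebuilt by summation (normalization and c are
# fixed on the full starting population, as in the canonical algorithm)
oracle_environmental_selection <- function(objs, target_size, kappa = 0.05) {
  base <- oracle_ibea_fitness(objs, kappa)
  norm <- base$norm; c_abs <- base$c
  ind <- function(a, b) max(norm[a, ] - norm[b, ])
  alive <- seq_len(nrow(objs))
  while (length(alive) > target_size) {
    fit <- vapply(alive, function(x) {
      s <- 0
      for (y in setdiff(alive, x)) s <- s - exp(-ind(y, x) / (c_abs * kappa))
      s
    }, numeric(1))
    alive <- alive[-which.min(fit)]
  }
  alive
}

# dense-grid estimate of the time calcium spends above a threshold;
# cells straddling the threshold are split by linear interpolation so the
# estimate is well inside the 2-grid-step band even with many crossings
oracle_time_above <- function(times, amps, theta, tau_ca, dt_grid,
                              horizon = NULL) {
  if (is.null(horizon)) horizon <- max(times) + 20 * tau_ca
  tg <- seq(min(times), horizon, by = dt_grid)
  cg <- rep(0, length(tg))
  for (k in seq_along(times)) {
    on <- tg >= times[k]
    cg[on] <- cg[on] + amps[k] * exp(-(tg[on] - times[k]) / tau_ca)
  }
  c1 <- head(cg, -1); c2 <- tail(cg, -1)
  frac <- ifelse(c1 > theta & c2 > theta, 1,
          ifelse(c1 <= theta & c2 <= theta, 0,
                 abs(pmax(c1, c2) - theta) / abs(c2 - c1)))
  sum(frac) * dt_grid
}

# toy separable evaluator used by the optimiser tests: objective i is
# |x_i - 0.5| on [0, 1]^d
sphere_evaluator <- function(d = 2) {
  specs <- lapply(seq_len(d), function(i)
    parameter_spec(paste0("x", i), bounds = c(0, 1)))
  evaluator(specs, paste0("obj", seq_len(d)),
            function(g) abs(g - 0.5), name = "sphere")
}

# strong-drive fixture for the analytic-vs-SDE comparisons: chosen so the
# double-well cubic term is negligible (tau at its upper bound) while the
# protocol mixes both basins strongly (U, D both far from 0/1)
strong_drive_fixture <- function() {
  list(params = gb_params(tau_ca = 0.009, c_pre = 6, c_post = 6,
                          gamma_d = 2500, gamma_p = 2500, sigma = 11,
                          tau = 2500, delay_d = 0, b = 2),
       constants = gb_constants(),
       protocol = pairing_protocol("strong", 0, n_post = 3, post_freq = 50,
                                   n_reps = 30, rep_freq = 1))
}

# delta-method standard error of the Monte-Carlo gain estimate
mc_gain_se <- function(U, D, n, b, beta) {
  se_u <- sqrt(pmax(U * (1 - U), 0.25 / n) / n)
  se_d <- sqrt(pmax(D * (1 - D), 0.25 / n) / n)
  (b - 1) / (beta * b + 1 - beta) *
    sqrt(beta^2 * se_d^2 + (1 - beta)^2 * se_u^2)
}
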