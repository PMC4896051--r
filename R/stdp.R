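#' Graupner-Brunel model parameter box
#'
#' The nine optimised parameters of the calcium-based bistable synapse
#' model, with the bounds used for fitting. Units: seconds for time
#' constants and the NMDA delay; calcium amplitudes and the weight ratio
#' are dimensionless; `gamma_p`, `gamma_d` are rates (1/s).
#'
#' @return Named list of `c(lower, upper)` bounds, in genome order
#'   `tau_ca, c_pre, c_post, gamma_d, gamma_p, sigma, tau, delay_d, b`.
#' @export
gb_param_bounds <- function() {
  list(tau_ca = c(1e-3, 100e-3),
       c_pre = c(0.1, 20),
       c_post = c(0.1, 50),
       gamma_d = c(5, 5000),
       gamma_p = c(5, 2500),
       sigma = c(0.35, 70.7),
       tau = c(2.5, 2500),
       delay_d = c(0, 50e-3),
       b = c(1, 100))
}

#' Graupner-Brunel model parameters
#'
#' Calcium-based plasticity model of a bistable synapse: the efficacy
#' variable rho sits in a double-well potential with unstable point
#' `rho_star` (see [gb_constants()]), is pushed towards 1 at rate
#' `gamma_p` while calcium exceeds the potentiation threshold and
#' towards 0 at rate `gamma_d` while calcium exceeds the depression
#' threshold, with activity-dependent noise of amplitude `sigma`.
#' Calcium jumps by `c_pre` on a presynaptic spike (delayed by
#' `delay_d`, the slow NMDA activation) and by `c_post` on a
#' postsynaptic spike, decaying with time constant `tau_ca`.
#'
#' Defaults are the package's frozen ground-truth set for the synthetic
#' pre + postsynaptic-burst pairing fixture: calibrated once (before any
#' fitting) so that the analytic gain curve reproduces the qualitative
#' in-vitro shape of that protocol family -- depression peaking near
#' delta_t = -50 ms, potentiation peaking near +10 ms, little change far
#' from coincidence. See the methods vignette.
#'
#' @param tau_ca Calcium decay time constant (s).
#' @param c_pre,c_post Calcium transient amplitudes (unitless).
#' @param gamma_d,gamma_p Depression/potentiation rates (1/s).
#' @param sigma Noise amplitude.
#' @param tau Efficacy time constant (s).
#' @param delay_d NMDA delay of the presynaptic transient (s).
#' @param b Ratio of up-state to down-state synaptic weight.
#' @return An object of class `gb_params`.
#' @export
gb_params <- function(tau_ca = 0.098, c_pre = 0.623, c_post = 0.4649,
                      gamma_d = 361.6, gamma_p = 1133, sigma = 4.557,
                      tau = 1005, delay_d = 0.05, b = 2.854) {
  p <- list(tau_ca = tau_ca, c_pre = c_pre, c_post = c_post,
            gamma_d = gamma_d, gamma_p = gamma_p, sigma = sigma,
            tau = tau, delay_d = delay_d, b = b)
  bb <- gb_param_bounds()
  for (nm in names(bb)) {
    if (!is.finite(p[[nm]]) || p[[nm]] < bb[[nm]][1] || p[[nm]] > bb[[nm]][2])
      stop("gb_params: '", nm, "' = ", p[[nm]], " outside [",
           bb[[nm]][1], ", ", bb[[nm]][2], "]")
  }
  structure(p, class = "gb_params")
}

#' Fixed constants of the Graupner-Brunel model
#'
#' These are configuration, not fitted parameters: the calcium
#' thresholds for potentiation/depression, the basin boundary of the
#' double well, and the fraction of synapses initially in the up state.
#'
#' @param theta_d Depression threshold (> 0).
#' @param theta_p Potentiation threshold (> theta_d).
#' @param rho_star Unstable fixed point separating the basins, in (0,1).
#' @param beta Initial up-state fraction, in \[0,1\].
#' @return An object of class `gb_constants`.
#' @export
gb_constants <- function(theta_d = 1.0, theta_p = 1.3, rho_star = 0.5,
                         beta = 0.5) {
  stopifnot(theta_d > 0, theta_p > theta_d, rho_star > 0, rho_star < 1,
            beta >= 0, beta <= 1)
  structure(list(theta_d = theta_d, theta_p = theta_p,
                 rho_star = rho_star, beta = beta),
            class = "gb_constants")
}

#' Periodic pre + postsynaptic-burst pairing protocol
#'
#' One repetition pairs a single presynaptic spike (at time 0) with a
#' burst of `n_post` postsynaptic spikes at `post_freq` Hz starting at
#' `delta_t`; positive `delta_t` means pre before post (LTP side),
#' negative means the burst precedes the presynaptic spike (LTD side).
#' The pairing is repeated `n_reps` times at `rep_freq` Hz; repetitions
#' are treated as independent (the repetition period must greatly exceed
#' the calcium time constant).
#'
#' @param prot_id Protocol identifier.
#' @param delta_t Pre-to-burst offset (s).
#' @param n_post Burst size (>= 1).
#' @param post_freq Intra-burst frequency (Hz).
#' @param n_reps Number of repetitions.
#' @param rep_freq Repetition frequency (Hz).
#' @return An object of class `pairing_protocol`.
#' @export
pairing_protocol <- function(prot_id, delta_t, n_post = 3, post_freq = 50,
                             n_reps = 60, rep_freq = 0.1) {
  stopifnot(n_post >= 1, post_freq > 0, n_reps >= 1, rep_freq > 0)
  structure(list(prot_id = as.character(prot_id), delta_t = delta_t,
                 n_post = as.integer(n_post), post_freq = post_freq,
                 n_reps = as.integer(n_reps), rep_freq = rep_freq),
            class = "pairing_protocol")
}

#' Calcium events of one protocol repetition
#'
#' The presynaptic spike (at time 0) contributes a calcium event of
#' amplitude `c_pre` at `delay_d`; each postsynaptic spike of the burst
#' contributes amplitude `c_post` at `delta_t + k/post_freq`
#' (k = 0 .. n_post-1). Events are returned sorted by time (times may be
#' negative when the burst precedes the presynaptic spike).
#'
#' @param protocol A [pairing_protocol()].
#' @param params A [gb_params()].
#' @return Data frame with columns `time` (s) and `amplitude`.
#' @export
calcium_events <- function(protocol, params) {
  times <- c(params$delay_d,
             protocol$delta_t + (seq_len(protocol$n_post) - 1) /
               protocol$post_freq)
  amps <- c(params$c_pre, rep(params$c_post, protocol$n_post))
  ord <- order(times)
  data.frame(time = times[ord], amplitude = amps[ord])
}

#' Exact time calcium spends above a threshold
#'
#' Calcium starts at 0, jumps by each event amplitude and decays
#' exponentially with `tau_ca` in between, so within each inter-event
#' segment the trajectory is `c_k * exp(-(t - t_k)/tau_ca)` and the
#' downward crossing of `theta` (if `c_k > theta`) happens at
#' `t_k + tau_ca * log(c_k / theta)`. The total Lebesgue time above
#' `theta` is therefore available in closed form, exact to float
#' precision.
#'
#' @param times Event times (s), any origin; need not be sorted.
#' @param amps Event amplitudes, same length.
#' @param theta Threshold (> 0).
#' @param tau_ca Calcium decay time constant (s).
#' @param horizon Absolute end time; default `Inf` (full decay).
#' @return Time above threshold (s).
#' @export
time_above_threshold <- function(times, amps, theta, tau_ca,
                                 horizon = Inf) {
  if (theta <= 0) stop("theta must be > 0")
  stopifnot(length(times) == length(amps), tau_ca > 0)
  if (length(times) == 0L) return(0)
  ord <- order(times)
  times <- times[ord]; amps <- amps[ord]
  total <- 0
  c_cur <- 0
  for (k in seq_along(times)) {
    if (k > 1L) c_cur <- c_cur * exp(-(times[k] - times[k - 1L]) / tau_ca)
    c_cur <- c_cur + amps[k]
    seg_end <- if (k < length(times)) times[k + 1L] else horizon
    seg <- seg_end - times[k]
    if (c_cur > theta)
      total <- total + min(seg, tau_ca * log(c_cur / theta))
  }
  total
}

#' Calcium trajectory at given times
#'
#' Evaluates the exact event-superposition calcium trace (used for
#' plotting and as a cross-check of [time_above_threshold()]).
#'
#' @inheritParams time_above_threshold
#' @param t Times at which to evaluate (s).
#' @return Numeric vector `c(t)`.
#' @export
calcium_at <- function(t, times, amps, tau_ca) {
  vapply(t, function(tt) {
    past <- times <= tt
    if (!any(past)) return(0)
    sum(amps[past] * exp(-(tt - times[past]) / tau_ca))
  }, numeric(1))
}

# fractions of protocol time spent above the two calcium thresholds,
# assuming independent repetitions (calcium fully decays in between)
alpha_fractions <- function(protocol, params, constants) {
  if (protocol$rep_freq * params$tau_ca >= 0.01)
    warning("repetition period is not >> tau_ca (rep_freq * tau_ca = ",
            signif(protocol$rep_freq * params$tau_ca, 3),
            "); the independent-repetition approximation may be poor")
  ev <- calcium_events(protocol, params)
  horizon <- min(ev$time) + 1 / protocol$rep_freq
  t_p <- time_above_threshold(ev$time, ev$amplitude, constants$theta_p,
                              params$tau_ca, horizon)
  t_d <- time_above_threshold(ev$time, ev$amplitude, constants$theta_d,
                              params$tau_ca, horizon)
  c(alpha_p = t_p * protocol$rep_freq, alpha_d = t_d * protocol$rep_freq)
}

#' Time-averaged efficacy dynamics
#'
#' While the protocol runs, the threshold terms act for fractions
#' `alpha_p` and `alpha_d` of the time; averaging the efficacy equation
#' (and dropping the cubic double-well term, which is slow compared to
#' the driven linear terms) gives an Ornstein-Uhlenbeck process with
#' effective rates `Gamma_p = gamma_p * alpha_p`,
#' `Gamma_d = gamma_d * alpha_d`:
#' mean `rho_bar = Gamma_p / (Gamma_p + Gamma_d)`, relaxation time
#' `tau_eff = tau / (Gamma_p + Gamma_d)` and stationary variance
#' `sigma_rho_sq = sigma^2 (alpha_p + alpha_d) / (2 (Gamma_p + Gamma_d))`
#' (validated against the stochastic oracle in the test suite).
#'
#' @param params A [gb_params()].
#' @param alpha_p,alpha_d Fractions of protocol time above the
#'   potentiation/depression threshold, in \[0,1\].
#' @return List with `rho_bar`, `tau_eff`, `sigma_rho_sq` and `no_drive`
#'   (`TRUE` when `Gamma_p + Gamma_d = 0`, in which case the other
#'   entries are `NA` and downstream transition probabilities are 0).
#' @export
effective_dynamics <- function(params, alpha_p, alpha_d) {
  stopifnot(alpha_p >= 0, alpha_p <= 1, alpha_d >= 0, alpha_d <= 1)
  gp <- params$gamma_p * alpha_p
  gd <- params$gamma_d * alpha_d
  if (gp + gd <= 0)
    return(list(rho_bar = NA_real_, tau_eff = NA_real_,
                sigma_rho_sq = NA_real_, no_drive = TRUE))
  list(rho_bar = gp / (gp + gd),
       tau_eff = params$tau / (gp + gd),
       sigma_rho_sq = params$sigma^2 * (alpha_p + alpha_d) / (2 * (gp + gd)),
       no_drive = FALSE)
}

#' Up/down transition probabilities of a pairing protocol
#'
#' Gaussian endpoint approximation of the averaged dynamics: given the
#' initial state, the efficacy at the end of the protocol is normal with
#' mean `rho_bar + (rho0 - rho_bar) * exp(-T/tau_eff)` and variance
#' `sigma_rho_sq * (1 - exp(-2T/tau_eff))`. `U` is the probability that
#' a synapse starting in the down basin (rho0 = 0) ends above
#' `rho_star`; `D` the probability that one starting up (rho0 = 1) ends
#' below.
#'
#' @param params A [gb_params()].
#' @param constants A [gb_constants()].
#' @param alpha_p,alpha_d Threshold time fractions (see
#'   [effective_dynamics()]).
#' @param t_total Protocol duration `n_reps / rep_freq` (s).
#' @return Named numeric `c(U = , D = )`.
#' @export
transition_probabilities <- function(params, constants, alpha_p, alpha_d,
                                     t_total) {
  eff <- effective_dynamics(params, alpha_p, alpha_d)
  if (eff$no_drive) return(c(U = 0, D = 0))
  decay <- exp(-t_total / eff$tau_eff)
  sd_T <- sqrt(eff$sigma_rho_sq * (1 - exp(-2 * t_total / eff$tau_eff)))
  mean0 <- eff$rho_bar * (1 - decay)            # rho0 = 0
  mean1 <- eff$rho_bar + (1 - eff$rho_bar) * decay  # rho0 = 1
  if (sd_T <= 0) {
    return(c(U = as.numeric(mean0 > constants$rho_star),
             D = as.numeric(mean1 < constants$rho_star)))
  }
  c(U = stats::pnorm((mean0 - constants$rho_star) / sd_T),
    D = stats::pnorm((constants$rho_star - mean1) / sd_T))
}

#' Predicted synaptic gain of a pairing protocol
#'
#' Analytic protocol outcome: with initial up-state fraction `beta`, the
#' up fraction after the protocol is `beta (1 - D) + (1 - beta) U`, and
#' the synaptic gain (mean weight after / before, down-state weight 1,
#' up-state weight `b`) is
#' `(after * b + 1 - after) / (beta * b + 1 - beta)`.
#'
#' @param protocol A [pairing_protocol()].
#' @param params A [gb_params()].
#' @param constants A [gb_constants()].
#' @return Synaptic gain (> 0; 1 = no change).
#' @export
protocol_outcome <- function(protocol, params,
                             constants = gb_constants()) {
  a <- alpha_fractions(protocol, params, constants)
  t_total <- protocol$n_reps / protocol$rep_freq
  ud <- transition_probabilities(params, constants, a[["alpha_p"]],
                                 a[["alpha_d"]], t_total)
  after <- constants$beta * (1 - ud[["D"]]) +
    (1 - constants$beta) * ud[["U"]]
  (after * params$b + (1 - after)) /
    (constants$beta * params$b + (1 - constants$beta))
}

#' Error vector of a parameter set against a plasticity dataset
#'
#' One error per protocol: `|sg_i - gain_i| / stderr_i`, the distance of
#' the predicted gain from the measured synaptic gain in units of the
#' measurement standard error.
#'
#' @param params A [gb_params()].
#' @param dataset A plasticity dataset (see [read_plasticity_dataset()]):
#'   data frame with columns `prot_id`, `sg`, `stderr`.
#' @param protocols List of [pairing_protocol()], aligned with the
#'   dataset rows.
#' @param constants A [gb_constants()].
#' @return Non-negative error vector named by protocol id.
#' @export
gb_evaluate <- function(params, dataset, protocols,
                        constants = gb_constants()) {
  ids <- vapply(protocols, `[[`, character(1), "prot_id")
  if (nrow(dataset) != length(protocols) ||
      !identical(as.character(dataset$prot_id), ids))
    stop("dataset rows do not align with the protocol list")
  gains <- vapply(protocols, protocol_outcome, numeric(1),
                  params = params, constants = constants)
  stats::setNames(abs(dataset$sg - gains) / dataset$stderr, ids)
}

#' Fitting evaluator for the plasticity model
#'
#' Builds an [evaluator()] over the nine model parameters (bounds from
#' [gb_param_bounds()]) whose objective vector is [gb_evaluate()]: one
#' `|sg - gain|/stderr` error per protocol in the dataset.
#'
#' @param dataset Plasticity dataset data frame (columns `prot_id`,
#'   `delta_t_ms`, `n_post`, `post_freq_hz`, `n_reps`, `rep_freq_hz`,
#'   `sg`, `stdev`, `stderr`).
#' @param constants A [gb_constants()].
#' @return An [evaluator()] with attached `protocols` and `dataset`.
#' @export
gb_evaluator <- function(dataset, constants = gb_constants()) {
  protocols <- dataset_protocols(dataset)
  bb <- gb_param_bounds()
  specs <- lapply(names(bb), function(nm) parameter_spec(nm, bounds = bb[[nm]]))
  ids <- vapply(protocols, `[[`, character(1), "prot_id")
  eval_fn <- function(genome) {
    p <- do.call(gb_params, as.list(stats::setNames(genome, names(bb))))
    unname(gb_evaluate(p, dataset, protocols, constants))
  }
  ev <- evaluator(specs, ids, eval_fn, name = "gb_evaluator")
  ev$protocols <- protocols
  ev$dataset <- dataset
  ev$constants <- constants
  ev
}

#' Stochastic simulation of the plasticity model (oracle)
#'
#' Euler-Maruyama integration of the full double-well efficacy equation
#' driven by the exact calcium event superposition; noise is active only
#' while calcium exceeds at least one threshold (amplitude
#' `sigma * sqrt(tau) * sqrt(H[c - theta_p] + H[c - theta_d])` inside the
#' `tau`-scaled equation). Used to validate the analytic layer, never in
#' the fitting path. Reproducible via `set.seed()`.
#'
#' @param params A [gb_params()].
#' @param constants A [gb_constants()].
#' @param protocol A [pairing_protocol()].
#' @param n_trials Number of independent paths per initial condition.
#' @param rho0 Initial efficacy; if `NULL`, simulates from both basins
#'   (0 and 1) and also reports the empirical transition probabilities
#'   and gain.
#' @param dt Fine time step (s) while calcium is above the depression
#'   threshold; default `tau_ca / 100`.
#' @param dt_coarse Coarse step (s) for the silent deterministic
#'   stretches; default `tau / 500`.
#' @return If `rho0` is given, numeric vector of final efficacies.
#'   Otherwise a list with `rho_down`, `rho_up` (final samples), `U`,
#'   `D` (empirical crossing fractions) and `gain`.
#' @export
simulate_gb <- function(params, constants, protocol, n_trials = 1000,
                        rho0 = NULL, dt = NULL, dt_coarse = NULL) {
  if (is.null(dt)) dt <- params$tau_ca / 100
  if (is.null(dt_coarse)) dt_coarse <- params$tau / 500
  ev <- calcium_events(protocol, params)
  # lay the repetitions out in absolute time, shifted so all times >= 0
  shift <- max(0, -min(ev$time))
  rep_starts <- (seq_len(protocol$n_reps) - 1) / protocol$rep_freq
  times <- as.vector(outer(ev$time + shift, rep_starts, "+"))
  amps <- rep(ev$amplitude, times = protocol$n_reps)
  ord <- order(times)
  t_total <- protocol$n_reps / protocol$rep_freq + shift
  run <- function(r0) {
    .gb_simulate_cpp(times[ord], amps[ord], t_total, params$tau_ca,
                     params$tau, params$gamma_p, params$gamma_d,
                     params$sigma, constants$theta_p, constants$theta_d,
                     constants$rho_star, r0, as.integer(n_trials),
                     dt, dt_coarse)
  }
  if (!is.null(rho0)) return(run(rho0))
  rho_down <- run(0)
  rho_up <- run(1)
  U <- mean(rho_down > constants$rho_star)
  D <- mean(rho_up < constants$rho_star)
  after <- constants$beta * (1 - D) + (1 - constants$beta) * U
  gain <- (after * params$b + (1 - after)) /
    (constants$beta * params$b + (1 - constants$beta))
  list(rho_down = rho_down, rho_up = rho_up, U = U, D = D, gain = gain)
}

#' Plasticity dataset input/output
#'
#' A plasticity dataset is a data frame with one row per pairing
#' protocol: `prot_id`, `delta_t_ms`, `n_post`, `post_freq_hz`,
#' `n_reps`, `rep_freq_hz`, `sg` (measured synaptic gain), `stdev`,
#' `stderr` (> 0). Files are tab-separated with a header line.
#'
#' @param path File path.
#' @return `read_plasticity_dataset` returns the validated data frame.
#' @export
read_plasticity_dataset <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  validate_plasticity_dataset(df)
}

#' @rdname read_plasticity_dataset
#' @param dataset Dataset data frame.
#' @export
write_plasticity_dataset <- function(dataset, path) {
  validate_plasticity_dataset(dataset)
  utils::write.table(dataset, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

validate_plasticity_dataset <- function(df) {
  need <- c("prot_id", "delta_t_ms", "n_post", "post_freq_hz", "n_reps",
            "rep_freq_hz", "sg", "stdev", "stderr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plasticity dataset is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(df$stderr) | df$stderr <= 0))
    stop("plasticity dataset: stderr must be > 0 in every row")
  df
}

#' Protocol list of a plasticity dataset
#'
#' @param dataset Dataset data frame (see [read_plasticity_dataset()]).
#' @return List of [pairing_protocol()] objects, one per row
#'   (`delta_t_ms` converted to seconds).
#' @export
dataset_protocols <- function(dataset) {
  validate_plasticity_dataset(dataset)
  lapply(seq_len(nrow(dataset)), function(i)
    pairing_protocol(dataset$prot_id[i], dataset$delta_t_ms[i] / 1000,
                     n_post = dataset$n_post[i],
                     post_freq = dataset$post_freq_hz[i],
                     n_reps = dataset$n_reps[i],
                     rep_freq = dataset$rep_freq_hz[i]))
}

#' Predicted gain curve over a delta-t grid
#'
#' @param params A [gb_params()].
#' @param constants A [gb_constants()].
#' @param delta_t_ms Numeric grid of pre-to-burst offsets (ms).
#' @param template A [pairing_protocol()] providing the burst/repetition
#'   structure.
#' @return Data frame with columns `delta_t_ms` and `gain`.
#' @export
gain_curve <- function(params, constants = gb_constants(),
                       delta_t_ms = seq(-100, 50, by = 5),
                       template = pairing_protocol("grid", 0)) {
  gains <- vapply(delta_t_ms, function(dtm) {
    pr <- pairing_protocol(sprintf("dt%+g", dtm), dtm / 1000,
                           n_post = template$n_post,
                           post_freq = template$post_freq,
                           n_reps = template$n_reps,
                           rep_freq = template$rep_freq)
    protocol_outcome(pr, params, constants)
  }, numeric(1))
  data.frame(delta_t_ms = delta_t_ms, gain = gains)
}
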