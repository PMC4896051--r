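#' Synthetic spike-train voltage fixture
#'
#' Builds a piecewise-linear voltage trace at `base` mV with triangular
#' excursions to `peak` mV centred at the requested spike times, for
#' testing the feature extractors with known geometry:
#' [detect_spikes()] recovers the input times to within one sample.
#'
#' @param spike_times Spike apex times (ms); must be separated by more
#'   than `width`.
#' @param peak Apex voltage (mV).
#' @param base Baseline voltage (mV).
#' @param width Total triangle base width (ms).
#' @param dt Sampling step (ms).
#' @param stim_start,stim_end Stimulus window metadata (ms).
#' @param total Total trace duration (ms).
#' @return A [voltage_trace()].
#' @export
make_spike_fixture <- function(spike_times, peak = 20, base = -65,
                               width = 2, dt = 0.025, stim_start = 0,
                               stim_end = total, total = 200) {
  spike_times <- sort(spike_times)
  if (length(spike_times) >= 2 && any(diff(spike_times) <= width))
    stop("spike times must be separated by more than the spike width")
  if (length(spike_times) &&
      (min(spike_times) - width / 2 < 0 || max(spike_times) + width / 2 > total))
    stop("spike triangles must lie within [0, total]")
  t <- seq(0, total, by = dt)
  v <- rep(base, length(t))
  for (s in spike_times) {
    sel <- abs(t - s) <= width / 2
    v[sel] <- base + (peak - base) * (1 - abs(t[sel] - s) / (width / 2))
  }
  voltage_trace(t, v, stim_start, stim_end)
}

#' Generate a synthetic plasticity dataset
#'
#' Emulates a summary-plasticity table (one row per pairing protocol)
#' from known ground-truth model parameters: the measured synaptic gain
#' is the analytic [protocol_outcome()] plus Gaussian noise. Used for
#' parameter/gain-recovery benchmarking where the original in-vitro
#' values are not available.
#'
#' @param true_params A [gb_params()]: the ground truth.
#' @param constants A [gb_constants()].
#' @param protocols List of [pairing_protocol()] objects.
#' @param noise_sd Standard deviation of the additive Gaussian
#'   measurement noise (also written to the `stderr` column unless
#'   `stderr` is supplied).
#' @param seed Optional RNG seed for reproducibility.
#' @param stderr Optional per-row standard errors.
#' @return Plasticity dataset data frame (see
#'   [read_plasticity_dataset()]) with attribute `noise_free_gain`.
#' @export
make_stdp_dataset <- function(true_params, constants = gb_constants(),
                              protocols = nevian_protocols(),
                              noise_sd = 0.05, seed = NULL,
                              stderr = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  gains <- vapply(protocols, protocol_outcome, numeric(1),
                  params = true_params, constants = constants)
  sg <- gains + stats::rnorm(length(gains), 0, noise_sd)
  # a valid dataset needs stderr > 0; a noise-free table gets unit stderr
  if (is.null(stderr))
    stderr <- rep(if (noise_sd > 0) noise_sd else 1, length(gains))
  df <- data.frame(
    prot_id = vapply(protocols, `[[`, character(1), "prot_id"),
    delta_t_ms = vapply(protocols, `[[`, numeric(1), "delta_t") * 1000,
    n_post = vapply(protocols, `[[`, integer(1), "n_post"),
    post_freq_hz = vapply(protocols, `[[`, numeric(1), "post_freq"),
    n_reps = vapply(protocols, `[[`, integer(1), "n_reps"),
    rep_freq_hz = vapply(protocols, `[[`, numeric(1), "rep_freq"),
    sg = sg,
    stdev = rep(noise_sd, length(gains)),
    stderr = stderr,
    stringsAsFactors = FALSE)
  attr(df, "noise_free_gain") <- gains
  df
}

#' Standard pre + triple-post pairing protocol family
#'
#' The burst pairing structure used for the packaged synthetic dataset:
#' one presynaptic spike paired with a burst of 3 postsynaptic spikes at
#' 50 Hz, repeated 60 times at 0.1 Hz, over a grid of pre-to-burst
#' offsets.
#'
#' @param delta_t_ms Offsets (ms), positive = pre before post.
#' @param n_post,post_freq,n_reps,rep_freq Burst/repetition structure.
#' @return List of [pairing_protocol()] objects.
#' @export
nevian_protocols <- function(delta_t_ms = c(-100, -75, -50, -25, -10,
                                            10, 25, 50),
                             n_post = 3, post_freq = 50, n_reps = 60,
                             rep_freq = 0.1) {
  lapply(delta_t_ms, function(dtm)
    pairing_protocol(sprintf("dt%+03d", as.integer(dtm)), dtm / 1000,
                     n_post = n_post, post_freq = post_freq,
                     n_reps = n_reps, rep_freq = rep_freq))
}

#' The introductory two-conductance demo evaluator
#'
#' The canonical desk-scale optimisation problem: a single-compartment
#' HH cell whose sodium and potassium maximal conductances are free
#' (`gnabar` in \[0.05, 0.125\], `gkbar` in \[0.01, 0.075\] S cm-2) while
#' everything else is frozen; two square-pulse protocols (0.01 and
#' 0.05 nA, 100 ms delay, 50 ms duration, 200 ms total) with Spikecount
#' targets 1 and 5 and std = 0.05 * mean. A genome matching both spike
#' counts exactly scores (0, 0).
#'
#' @param area_cm2 Soma membrane area; default the 10 um x 10 um
#'   cylinder of the packaged SWC stub.
#' @param dt Integration step (ms).
#' @return A [cell_evaluator()].
#' @export
hh_demo_evaluator <- function(area_cm2 = 4 * pi * 5^2 * 1e-8, dt = 0.025) {
  model <- point_cell_model(area_cm2 = area_cm2)
  protocols <- list(
    step1 = square_pulse(amplitude = 0.01, delay = 100, duration = 50,
                         total_duration = 200),
    step2 = square_pulse(amplitude = 0.05, delay = 100, duration = 50,
                         total_duration = 200))
  means <- c(step1 = 1, step2 = 5)
  targets <- lapply(names(means), function(pn)
    feature_target(pn, "Spikecount", mean = means[[pn]],
                   std = 0.05 * means[[pn]]))
  param_specs <- list(
    parameter_spec("cm", value = 1.0, frozen = TRUE),
    parameter_spec("gnabar", bounds = c(0.05, 0.125)),
    parameter_spec("gkbar", bounds = c(0.01, 0.075)))
  cell_evaluator(model, protocols, targets, param_specs, dt = dt,
                 name = "hh_demo")
}

#' Read/write a run configuration (JSON)
#'
#' A run configuration has a `mode` (`hh_demo`, `stdp_fit` or
#' `features`), an `optimiser` block (fields of
#' [optimisation_config()]), an optional `evaluator` block (for
#' `hh_demo`, the [cell_evaluator_to_config()] schema) and optional
#' paths. The load -> dump -> load round trip is the identity.
#'
#' @param path JSON file.
#' @return `read_run_config` returns the config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("hh_demo", "stdp_fit", "features"))
    stop("run config ", path,
         ": 'mode' must be one of hh_demo, stdp_fit, features")
  if (cfg$mode %in% c("hh_demo", "stdp_fit") && is.null(cfg$optimiser))
    stop("run config ", path, ": mode '", cfg$mode,
         "' requires an 'optimiser' block")
  cfg
}

#' @rdname read_run_config
#' @param config Config list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

config_to_optimisation <- function(block, seed = NULL) {
  args <- block[intersect(names(block),
                          names(formals(optimisation_config)))]
  if (!is.null(seed)) args$seed <- seed
  do.call(optimisation_config, args)
}

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{hh-demo}{run the two-conductance demo optimisation; writes
#'     `hall_of_fame.csv`, `logbook.jsonl`, the best-individual traces
#'     and a reproducibility manifest.}
#'   \item{stdp-fit}{fit the plasticity model to a dataset
#'     (`--dataset FILE`); writes `hall_of_fame.csv`, `logbook.jsonl`,
#'     `gain_curve.csv` and the manifest.}
#'   \item{features}{extract the feature table from a trace file
#'     (`--trace FILE`) to `features.csv`.}
#' }
#' Common options: `--config FILE`, `--seed N`, `--offspring N`,
#' `--max-ngen N`, `--out DIR`, `--checkpoint FILE`, `--dataset FILE`,
#' `--trace FILE`.
#'
#' @param args Character vector of command-line arguments (default:
#'   the actual command line).
#' @return Exit code, invisibly (0 = success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    cli_main(args)
    0L
  }, error = function(e) {
    message("ephysopt error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_main <- function(args) {
  if (length(args) == 0L)
    stop("usage: ephysopt hh-demo|stdp-fit|features [options]")
  sub <- args[1]
  opts <- cli_parse_opts(args[-1])
  out_dir <- opts$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  switch(sub,
         "hh-demo" = cli_hh_demo(opts, out_dir),
         "stdp-fit" = cli_stdp_fit(opts, out_dir),
         "features" = cli_features(opts, out_dir),
         stop("unknown subcommand '", sub,
              "'; expected hh-demo, stdp-fit or features"))
  invisible(NULL)
}

cli_parse_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'")
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("option ", a, " requires a value")
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_config <- function(opts, default_mode) {
  if (!is.null(opts$config)) read_run_config(opts$config)
  else list(mode = default_mode, optimiser = list())
}

cli_opt_config <- function(cfg, opts) {
  block <- cfg$optimiser %||% list()
  if (!is.null(opts$seed)) block$seed <- as.integer(opts$seed)
  if (!is.null(opts$offspring)) block$offspring_size <- as.integer(opts$offspring)
  if (!is.null(opts$max_ngen)) block$max_ngen <- as.integer(opts$max_ngen)
  if (!is.null(opts$checkpoint)) {
    block$checkpoint_path <- opts$checkpoint
    block$checkpoint_period <- block$checkpoint_period %||% 1L
  }
  config_to_optimisation(block)
}

cli_manifest <- function(out_dir, cfg, opt_config, extra = list()) {
  manifest <- c(list(
    package = "ephysopt",
    version = as.character(utils::packageVersion("ephysopt")),
    r_version = R.version.string,
    mode = cfg$mode,
    seed = opt_config$seed,
    config_md5 = unname(cli_config_hash(cfg)),
    optimiser = unclass(opt_config)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

cli_config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

cli_hh_demo <- function(opts, out_dir) {
  cfg <- cli_config(opts, "hh_demo")
  if (is.null(cfg$optimiser) || length(cfg$optimiser) == 0L)
    cfg$optimiser <- list(offspring_size = 100L, max_ngen = 10L, seed = 1L)
  opt_config <- cli_opt_config(cfg, opts)
  ev <- if (!is.null(cfg$evaluator)) cell_evaluator_from_config(cfg$evaluator)
        else hh_demo_evaluator()
  res <- run_optimisation(ev, opt_config)
  write_hall_of_fame(res, file.path(out_dir, "hall_of_fame.csv"))
  write_logbook(res, file.path(out_dir, "logbook.jsonl"))
  best <- best_genome(res)
  for (pn in names(ev$protocols)) {
    m <- ev$model
    pv <- genome_to_params(ev$param_specs, best)
    for (nm in names(pv)) m[[nm]] <- pv[[nm]]
    tr <- run_sweep(m, ev$protocols[[pn]], dt = ev$dt)
    write_trace(tr, file.path(out_dir, paste0(pn, ".soma.v.tsv")))
  }
  cli_manifest(out_dir, cfg, opt_config,
               list(best_objective_sum = res$hall_of_fame$objective_sum[1]))
  message(sprintf("hh-demo: best objective sum %g (hall of fame written to %s)",
                  res$hall_of_fame$objective_sum[1], out_dir))
}

cli_stdp_fit <- function(opts, out_dir) {
  cfg <- cli_config(opts, "stdp_fit")
  if (is.null(opts$dataset) && is.null(cfg$dataset))
    stop("stdp-fit requires --dataset FILE (or a 'dataset' path in the config)")
  ds_path <- opts$dataset %||% cfg$dataset
  dataset <- read_plasticity_dataset(ds_path)
  if (is.null(cfg$optimiser) || length(cfg$optimiser) == 0L)
    cfg$optimiser <- list(offspring_size = 100L, max_ngen = 200L, seed = 1L)
  opt_config <- cli_opt_config(cfg, opts)
  ev <- gb_evaluator(dataset)
  res <- run_optimisation(ev, opt_config)
  write_hall_of_fame(res, file.path(out_dir, "hall_of_fame.csv"))
  write_logbook(res, file.path(out_dir, "logbook.jsonl"))
  best <- best_genome(res)
  fitted <- do.call(gb_params, as.list(best))
  curve <- gain_curve(fitted, template = ev$protocols[[1]])
  utils::write.csv(curve, file.path(out_dir, "gain_curve.csv"),
                   row.names = FALSE)
  cli_manifest(out_dir, cfg, opt_config,
               list(dataset = ds_path,
                    best_objective_sum = res$hall_of_fame$objective_sum[1]))
  message(sprintf("stdp-fit: best objective sum %g (results in %s)",
                  res$hall_of_fame$objective_sum[1], out_dir))
}

cli_features <- function(opts, out_dir) {
  if (is.null(opts$trace)) stop("features requires --trace FILE")
  tr <- read_trace(opts$trace)
  tab <- feature_table(tr)
  utils::write.csv(tab, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  message("features: table written to ", file.path(out_dir, "features.csv"))
}
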