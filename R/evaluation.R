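#' Construct an evaluator
#'
#' An evaluator is the bridge between the optimiser and a model: it holds
#' the ordered parameter specifications (the free ones define the genome
#' encoding), the objective names (fixed order and count for the whole
#' run) and an evaluation function mapping a genome to a vector of
#' non-negative objective scores.
#'
#' @param param_specs List of [parameter_spec()] objects, in genome order.
#' @param objective_names Character vector of objective names.
#' @param eval_fn Function `(genome) -> numeric` of length
#'   `length(objective_names)`; must be pure (same genome, same vector).
#' @param name Label used in printouts and manifests.
#' @return An object of class `evaluator`.
#' @export
evaluator <- function(param_specs, objective_names, eval_fn,
                      name = "evaluator") {
  stopifnot(is.list(param_specs), length(param_specs) >= 1,
            all(vapply(param_specs, inherits, logical(1), "parameter_spec")),
            is.character(objective_names), length(objective_names) >= 1,
            is.function(eval_fn))
  nm <- vapply(param_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated parameter names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(list(param_specs = param_specs,
                 objective_names = objective_names,
                 eval_fn = eval_fn, name = name),
            class = "evaluator")
}

#' @export
print.evaluator <- function(x, ...) {
  cat("<evaluator>", x$name, "\n")
  cat("  free parameters:",
      paste(free_param_names(x$param_specs), collapse = ", "), "\n")
  cat("  objectives:", paste(x$objective_names, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate one genome
#'
#' Checks the genome against the parameter bounds (no out-of-bounds
#' genome is ever evaluated) and applies the evaluator's evaluation
#' function.
#'
#' @param ev An [evaluator()].
#' @param genome Numeric vector, one entry per free parameter.
#' @return Numeric objective vector.
#' @export
evaluate_genome <- function(ev, genome) {
  check_genome_bounds(ev$param_specs, genome)
  ev$eval_fn(genome)
}

#' Objective specification
#'
#' Describes how one or more feature scores are reduced into a single
#' objective value: `singleton` passes the single score through, `max`
#' takes the maximum, `weighted_sum` a weighted sum (default weights 1).
#'
#' @param name Objective name.
#' @param reducer One of `"singleton"`, `"max"`, `"weighted_sum"`.
#' @param feature_refs Character vector of feature identifiers feeding
#'   this objective.
#' @param weights Optional numeric weights (weighted_sum only).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(name,
                           reducer = c("singleton", "max", "weighted_sum"),
                           feature_refs, weights = NULL) {
  reducer <- match.arg(reducer)
  if (reducer == "singleton" && length(feature_refs) != 1L)
    stop("singleton objective '", name, "' requires exactly one feature_ref")
  if (reducer == "weighted_sum") {
    if (is.null(weights)) weights <- rep(1, length(feature_refs))
    if (length(weights) != length(feature_refs))
      stop("weights length != feature_refs length for objective '", name, "'")
  }
  structure(list(name = name, reducer = reducer,
                 feature_refs = feature_refs, weights = weights),
            class = "objective_spec")
}

#' Reduce feature scores to one objective value
#'
#' @param spec An [objective_spec()].
#' @param feature_scores Numeric vector of finite, non-negative scores,
#'   aligned with `spec$feature_refs`.
#' @return Scalar objective value.
#' @export
reduce_objective <- function(spec, feature_scores) {
  if (length(feature_scores) != length(spec$feature_refs))
    stop("score vector length ", length(feature_scores),
         " != feature_refs length ", length(spec$feature_refs))
  switch(spec$reducer,
         singleton = feature_scores[[1]],
         max = max(feature_scores),
         weighted_sum = sum(spec$weights * feature_scores))
}

#' Cell evaluator for the built-in point-neuron model
#'
#' Builds an [evaluator()] that, per genome: instantiates the
#' point-neuron model with the frozen values plus the genome, runs every
#' sweep protocol in declaration order, extracts the target features from
#' the responses and scores them as `|mu_exp - f_model| / sigma_exp`
#' (one singleton objective per target, unless `objective_specs` groups
#' them otherwise).
#'
#' Only parameters named after fields of [point_cell_model()] (e.g.
#' `gnabar`, `gkbar`, `gl`, `cm`) can be free.
#'
#' @param model A [point_cell_model()] providing the non-optimised fields.
#' @param protocols Named list of [square_pulse()] stimuli; names are the
#'   protocol names referenced by the targets.
#' @param targets List of [feature_target()] objects.
#' @param param_specs List of [parameter_spec()] objects.
#' @param objective_specs Optional list of [objective_spec()]; default is
#'   one singleton objective per target, named `protocol.feature`.
#' @param dt Integration step (ms).
#' @param threshold Spike detection threshold (mV).
#' @param penalty Score substituted for features that cannot be computed.
#' @param name Evaluator label.
#' @return An [evaluator()].
#' @export
cell_evaluator <- function(model, protocols, targets, param_specs,
                           objective_specs = NULL, dt = 0.025,
                           threshold = -20, penalty = 250,
                           name = "cell_evaluator") {
  stopifnot(inherits(model, "point_cell_model"))
  target_names <- vapply(targets, function(tg)
    paste0(tg$protocol, ".", tg$feature), character(1))
  if (is.null(objective_specs)) {
    objective_specs <- lapply(seq_along(targets), function(i)
      objective_spec(target_names[i], "singleton", target_names[i]))
  }
  obj_names <- vapply(objective_specs, `[[`, character(1), "name")

  eval_fn <- function(genome) {
    pv <- genome_to_params(param_specs, genome)
    m <- model
    for (nm in names(pv)) m[[nm]] <- pv[[nm]]
    responses <- list()
    for (pn in names(protocols)) {
      tr <- run_sweep(m, protocols[[pn]], dt = dt)
      responses[[paste0(pn, ".", "soma.v")]] <- tr
    }
    scores <- calculate_objectives(responses, targets, penalty = penalty,
                                   threshold = threshold)
    names(scores) <- target_names
    vapply(objective_specs, function(os)
      reduce_objective(os, scores[os$feature_refs]), numeric(1))
  }

  ev <- evaluator(param_specs, obj_names, eval_fn, name = name)
  ev$model <- model
  ev$protocols <- protocols
  ev$targets <- targets
  ev$dt <- dt
  ev$threshold <- threshold
  ev$penalty <- penalty
  ev
}

#' Serialize a cell evaluator to a config list
#'
#' The config schema mirrors the run-configuration file: `parameters`
#' (name/bounds/value/frozen), `protocols` (square-pulse fields) and
#' `targets` (protocol/recording/feature/mean/std), plus the model
#' constants. [cell_evaluator_from_config()] rebuilds an identical
#' evaluator, so the round trip is lossless.
#'
#' @param ev A [cell_evaluator()].
#' @return A plain list serializable with `jsonlite`.
#' @export
cell_evaluator_to_config <- function(ev) {
  stopifnot(inherits(ev, "evaluator"), !is.null(ev$model))
  list(
    name = ev$name,
    model = unclass(ev$model),
    parameters = lapply(ev$param_specs, function(p)
      list(name = p$name, lower_bound = p$lower_bound,
           upper_bound = p$upper_bound, frozen = p$frozen,
           value = p$value)),
    protocols = lapply(ev$protocols, unclass),
    targets = lapply(ev$targets, unclass),
    dt = ev$dt, threshold = ev$threshold, penalty = ev$penalty
  )
}

#' @rdname cell_evaluator_to_config
#' @param config A list produced by [cell_evaluator_to_config()] (or read
#'   from JSON).
#' @export
cell_evaluator_from_config <- function(config) {
  model <- do.call(point_cell_model, config$model)
  protocols <- lapply(config$protocols, function(p)
    square_pulse(amplitude = p$amplitude, delay = p$delay,
                 duration = p$duration, total_duration = p$total_duration,
                 holding = p$holding))
  targets <- lapply(config$targets, function(tg)
    feature_target(protocol = tg$protocol, feature = tg$feature,
                   mean = tg$exp_mean, std = tg$exp_std,
                   recording = tg$recording))
  param_specs <- lapply(config$parameters, function(p) {
    if (isTRUE(p$frozen)) parameter_spec(p$name, value = p$value, frozen = TRUE)
    else parameter_spec(p$name, bounds = c(p$lower_bound, p$upper_bound))
  })
  cell_evaluator(model, protocols, targets, param_specs,
                 dt = config$dt, threshold = config$threshold,
                 penalty = config$penalty, name = config$name)
}
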