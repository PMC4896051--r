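#' Single-compartment Hodgkin-Huxley cell model
#'
#' The built-in simulator integrates the classic squid-axon
#' Hodgkin-Huxley equations in a single isopotential compartment, with
#' rate functions shifted so the resting potential sits near -65 mV (the
#' convention of the default `hh` mechanism in common simulators):
#' sodium (m^3 h), potassium (n^4) and leak currents. Units: mV, ms, nA,
#' uF cm-2, S cm-2.
#'
#' The membrane area defaults to that of a 10 um x 10 um cylindrical
#' soma (pi * 10 * 10 um^2 = 4 * pi * 5^2, i.e. the sphere-equivalent of
#' the one-point SWC stub shipped with the package); pass `morphology`
#' (a path to such a stub) or `area_cm2` to override.
#'
#' @param gnabar,gkbar Maximal Na+/K+ conductances (S cm-2).
#' @param gl Leak conductance (S cm-2).
#' @param cm Specific capacitance (uF cm-2).
#' @param ena,ek,el Reversal potentials (mV).
#' @param v_init Initial membrane potential (mV); gating variables start
#'   at their steady state for this voltage.
#' @param celsius Temperature; kinetics scale by `3^((celsius-6.3)/10)`.
#' @param area_cm2 Membrane area (cm^2).
#' @param morphology Optional path to a one-point SWC soma stub; its
#'   sphere area overrides `area_cm2`.
#' @return An object of class `point_cell_model`.
#' @export
point_cell_model <- function(gnabar = 0.12, gkbar = 0.036, gl = 3e-4,
                             cm = 1.0, ena = 50, ek = -77, el = -54.3,
                             v_init = -65, celsius = 6.3,
                             area_cm2 = NULL, morphology = NULL) {
  if (!is.null(morphology)) {
    soma <- read_swc_soma(morphology)
    area_cm2 <- soma$area_cm2
  }
  if (is.null(area_cm2)) area_cm2 <- 4 * pi * 5^2 * 1e-8  # 10x10 um cylinder
  stopifnot(gnabar >= 0, gkbar >= 0, gl >= 0, cm > 0, area_cm2 > 0)
  structure(list(gnabar = gnabar, gkbar = gkbar, gl = gl, cm = cm,
                 ena = ena, ek = ek, el = el, v_init = v_init,
                 celsius = celsius, area_cm2 = area_cm2),
            class = "point_cell_model")
}

#' @export
print.point_cell_model <- function(x, ...) {
  cat(sprintf(
    "<point_cell_model> gnabar=%g gkbar=%g gl=%g S/cm2, area=%.3g cm2\n",
    x$gnabar, x$gkbar, x$gl, x$area_cm2))
  invisible(x)
}

#' Read a one-point SWC soma stub
#'
#' Parses the minimal SWC subset used by the point-neuron model: a
#' single soma sample (type 1). Full morphologies are rejected; the
#' simulator has no cable model to put them on.
#'
#' @param path SWC file.
#' @return List with `x`, `y`, `z`, `radius` (um) and `area_cm2`
#'   (sphere area `4*pi*r^2` converted from um^2).
#' @export
read_swc_soma <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no samples in SWC file ", path)
  if (length(lines) > 1L)
    stop("unsupported SWC morphology in ", path,
         ": only a single-sample soma stub is supported")
  f <- as.numeric(strsplit(lines, "[[:space:]]+")[[1]])
  if (length(f) != 7L || any(!is.finite(f)))
    stop("malformed SWC sample line in ", path)
  if (f[2] != 1) stop("SWC sample is not a soma (type 1) in ", path)
  r <- f[6]
  if (r <= 0) stop("non-positive soma radius in ", path)
  list(x = f[3], y = f[4], z = f[5], radius = r,
       area_cm2 = 4 * pi * r^2 * 1e-8)
}

#' Square current pulse stimulus
#'
#' @param amplitude Step amplitude (nA).
#' @param delay Step onset (ms).
#' @param duration Step length (ms).
#' @param total_duration Total simulated time (ms).
#' @param holding Holding current applied for the whole sweep (nA).
#' @return An object of class `square_pulse`.
#' @export
square_pulse <- function(amplitude, delay, duration, total_duration,
                         holding = 0) {
  stopifnot(delay >= 0, duration >= 0, delay + duration <= total_duration,
            total_duration > 0)
  structure(list(amplitude = amplitude, delay = delay, duration = duration,
                 total_duration = total_duration, holding = holding),
            class = "square_pulse")
}

#' Voltage trace container
#'
#' Uniformly sampled membrane potential with the stimulus window
#' attached, so feature extraction knows where to look.
#'
#' @param t Time grid (ms), strictly increasing and uniform.
#' @param v Membrane potential samples (mV), same length as `t`.
#' @param stim_start,stim_end Stimulus window (ms).
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(t, v, stim_start, stim_end) {
  stopifnot(length(t) == length(v), length(t) >= 2,
            all(diff(t) > 0), stim_start >= 0, stim_end >= stim_start)
  structure(list(t = t, v = v, stim_start = stim_start,
                 stim_end = stim_end, dt = t[2] - t[1]),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %d samples, dt=%g ms, stim [%g, %g] ms, v in [%.1f, %.1f] mV\n",
    length(x$t), x$dt, x$stim_start, x$stim_end, min(x$v), max(x$v)))
  invisible(x)
}

#' Hodgkin-Huxley state derivatives (reference implementation)
#'
#' Pure-R right-hand side of the four-state HH system, used as the
#' independent reference for the compiled integrator. State order:
#' `c(v, m, h, n)`. See [point_cell_model()] for units; the factor 1000
#' converts (mA cm-2)/(uF cm-2) = V/s to mV/ms.
#'
#' @param state Numeric `c(v, m, h, n)`.
#' @param i_inj Injected current (nA).
#' @param model A [point_cell_model()].
#' @return Numeric length-4 derivative vector (per ms).
#' @export
hh_derivatives <- function(state, i_inj, model) {
  v <- state[1]; m <- state[2]; h <- state[3]; n <- state[4]
  q10 <- 3^((model$celsius - 6.3) / 10)
  ina <- model$gnabar * m^3 * h * (v - model$ena)
  ik <- model$gkbar * n^4 * (v - model$ek)
  il <- model$gl * (v - model$el)
  c(1000 * (-(ina + ik + il) + i_inj * 1e-6 / model$area_cm2) / model$cm,
    q10 * (hh_alpha("m", v) * (1 - m) - hh_beta("m", v) * m),
    q10 * (hh_alpha("h", v) * (1 - h) - hh_beta("h", v) * h),
    q10 * (hh_alpha("n", v) * (1 - n) - hh_beta("n", v) * n))
}

hh_alpha <- function(gate, v) {
  switch(gate,
         m = { x <- v + 40; ifelse(abs(x) < 1e-9, 1, 0.1 * x / (1 - exp(-x / 10))) },
         h = 0.07 * exp(-(v + 65) / 20),
         n = { x <- v + 55; ifelse(abs(x) < 1e-9, 0.1, 0.01 * x / (1 - exp(-x / 10))) })
}

hh_beta <- function(gate, v) {
  switch(gate,
         m = 4 * exp(-(v + 65) / 18),
         h = 1 / (1 + exp(-(v + 35) / 10)),
         n = 0.125 * exp(-(v + 65) / 80))
}

# steady-state gating values at voltage v
hh_steady_state <- function(v) {
  sapply(c("m", "h", "n"), function(g)
    hh_alpha(g, v) / (hh_alpha(g, v) + hh_beta(g, v)))
}

#' Run one sweep of the point-neuron model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the HH system from
#' `v_init` (gating at steady state for `v_init`), under a square current
#' pulse. Deterministic: identical inputs give bit-identical traces.
#'
#' @param model A [point_cell_model()].
#' @param stimulus A [square_pulse()].
#' @param dt Integration step (ms), default 0.025.
#' @param record_dt Recording step (ms); must be a multiple of `dt`.
#' @return A [voltage_trace()] with the stimulus window attached.
#' @export
run_sweep <- function(model, stimulus, dt = 0.025, record_dt = dt) {
  stopifnot(inherits(model, "point_cell_model"),
            inherits(stimulus, "square_pulse"), dt > 0, record_dt >= dt)
  res <- .hh_integrate_cpp(model$cm, model$area_cm2, model$gnabar,
                           model$gkbar, model$gl, model$ena, model$ek,
                           model$el, model$v_init, model$celsius,
                           stimulus$amplitude, stimulus$delay,
                           stimulus$duration, stimulus$total_duration,
                           stimulus$holding, dt, record_dt)
  voltage_trace(res$t, res$v, stimulus$delay,
                stimulus$delay + stimulus$duration)
}

#' Distance-dependent parameter scaler
#'
#' Parses a template expression with `{distance}` and `{value}`
#' placeholders into a pure arithmetic function, e.g. the exponential
#' scaler used to increase a dendritic channel density with path distance
#' from the soma:
#' `"(-0.8696 + 2.087*exp(({distance})*0.0031))*{value}"` (the Python
#' spelling `math.exp` is accepted too). Parsing and validation happen at
#' construction time; evaluation is side-effect free.
#'
#' @param template Template string.
#' @return An object of class `scaler_expression`.
#' @export
scaler_expression <- function(template) {
  stopifnot(is.character(template), length(template) == 1L)
  txt <- gsub("math.exp", "exp", template, fixed = TRUE)
  txt <- gsub("{distance}", "distance", txt, fixed = TRUE)
  txt <- gsub("{value}", "value", txt, fixed = TRUE)
  expr <- tryCatch(parse(text = txt)[[1]],
                   error = function(e) stop("malformed scaler template: ",
                                            conditionMessage(e)))
  allowed <- c("+", "-", "*", "/", "^", "(", "exp", "distance", "value")
  check <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.name(e) || is.function(e)) {
      if (!as.character(e) %in% allowed)
        stop("disallowed symbol in scaler template: ", as.character(e))
      return(invisible())
    }
    if (is.call(e)) {
      lapply(as.list(e), check)
      return(invisible())
    }
    stop("disallowed element in scaler template")
  }
  check(expr)
  structure(list(template = template, expr = expr),
            class = "scaler_expression")
}

#' @rdname scaler_expression
#' @param expr A `scaler_expression`.
#' @param value Base parameter value.
#' @param distance Distance from the origin location (um), >= 0.
#' @return Scaled parameter value.
#' @export
scale_by_distance <- function(expr, value, distance) {
  stopifnot(inherits(expr, "scaler_expression"), all(distance >= 0))
  eval(expr$expr, list(distance = distance, value = value,
                       exp = base::exp))
}

#' Write/read a voltage trace as two-column delimited text
#'
#' Columns `t_ms` and `v_mV`, tab-separated, with the stimulus window in
#' a `# stim_start= stim_end=` comment line so the round trip preserves
#' the feature-extraction window.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stim_start=%.17g stim_end=%.17g",
                     trace$stim_start, trace$stim_end), con)
  writeLines("t_ms\tv_mV", con)
  writeLines(sprintf("%.17g\t%.17g", trace$t, trace$v), con)
  invisible(path)
}

#' @rdname write_trace
#' @return `read_trace` returns a [voltage_trace()].
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  stim <- c(0, Inf)
  skip <- 0L
  if (startsWith(first, "#")) {
    stim <- as.numeric(c(
      sub(".*stim_start=([^[:space:]]+).*", "\\1", first),
      sub(".*stim_end=([^[:space:]]+).*", "\\1", first)))
    skip <- 1L
  }
  df <- utils::read.table(path, header = TRUE, skip = skip, sep = "\t")
  if (!is.finite(stim[2])) stim[2] <- max(df[[1]])
  voltage_trace(df[[1]], df[[2]], stim[1], stim[2])
}
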