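#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of `threshold` followed by a local
#' maximum before the next downward crossing; the spike time is the time
#' of that maximum and the onset time is the (interpolated) upward
#' crossing.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Detection threshold (mV), default -20.
#' @return An object of class `spike_train`: list with `peak_times`,
#'   `peak_values`, `onset_times`, `offset_times` (downward crossings)
#'   and `threshold`. Empty vectors when no spike is found.
#' @export
detect_spikes <- function(trace, threshold = -20) {
  v <- trace$v; t <- trace$t
  n <- length(v)
  above <- v >= threshold
  up <- which(!above[-n] & above[-1])     # index i: crossing in (i, i+1]
  down <- which(above[-n] & !above[-1])
  peak_times <- peak_values <- onset_times <- offset_times <- numeric(0)
  for (u in up) {
    d <- down[down > u]
    end <- if (length(d)) d[1] else n - 1L
    seg <- seq(u + 1L, end)
    pk <- seg[which.max(v[seg])]
    # linear interpolation of the threshold crossings
    on_t <- t[u] + (threshold - v[u]) / (v[u + 1L] - v[u]) * (t[u + 1L] - t[u])
    off_t <- if (length(d)) {
      dd <- d[1]
      t[dd] + (threshold - v[dd]) / (v[dd + 1L] - v[dd]) * (t[dd + 1L] - t[dd])
    } else NA_real_
    peak_times <- c(peak_times, t[pk])
    peak_values <- c(peak_values, v[pk])
    onset_times <- c(onset_times, on_t)
    offset_times <- c(offset_times, off_t)
  }
  structure(list(peak_times = peak_times, peak_values = peak_values,
                 onset_times = onset_times, offset_times = offset_times,
                 threshold = threshold),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes (threshold %g mV)\n",
              length(x$peak_times), x$threshold))
  invisible(x)
}

#' Feature target
#'
#' Binds one extracted feature on one protocol to an experimental
#' mean/std pair; the objective score of a model value `f` is
#' `|mean - f| / std`.
#'
#' @param protocol Protocol name (e.g. `"step1"`).
#' @param feature Feature name; must be in [efeature_names()].
#' @param mean,std Experimental mean and standard deviation; `std > 0`.
#' @param recording Recording name within the protocol (default
#'   `"soma.v"`).
#' @return An object of class `feature_target`.
#' @export
feature_target <- function(protocol, feature, mean, std,
                           recording = "soma.v") {
  if (!feature %in% efeature_names())
    stop("unknown feature '", feature, "'; supported: ",
         paste(efeature_names(), collapse = ", "))
  if (!is.finite(std) || std <= 0)
    stop("feature target ", protocol, ".", feature, ": std must be > 0")
  structure(list(protocol = protocol, feature = feature,
                 exp_mean = mean, exp_std = std, recording = recording),
            class = "feature_target")
}

#' Supported voltage-trace features
#'
#' @return Character vector of feature names accepted by
#'   [compute_feature()].
#' @export
efeature_names <- function() {
  c("Spikecount", "time_to_first_spike", "mean_frequency", "ISI_CV",
    "doublet_ISI", "adaptation_index2", "AP_height",
    "AP_amplitude_from_voltagebase", "AHP_depth_abs",
    "AHP_depth_abs_slow", "AHP_slow_time", "AP_width")
}

#' Compute a voltage-trace feature
#'
#' All spike-based features consider only spikes whose peak lies inside
#' the stimulus window `[stim_start, stim_end]`; the voltage base is the
#' mean potential on `[0, stim_start)`. Returns `NA` ("missing") when a
#' feature's prerequisites are unmet (e.g. too few spikes), which the
#' scoring layer converts into the configured penalty.
#'
#' Definitions:
#' \describe{
#'   \item{Spikecount}{number of spikes in the window (0 allowed).}
#'   \item{time_to_first_spike}{first peak time - stim_start (>= 1 spike).}
#'   \item{mean_frequency}{`1000 * N / (last peak - stim_start)` in Hz.}
#'   \item{ISI_CV}{sample sd / mean of inter-peak intervals (>= 3 spikes).}
#'   \item{doublet_ISI}{second peak - first peak (>= 2 spikes).}
#'   \item{adaptation_index2}{mean over i >= 2 of
#'     `(ISI[i+1]-ISI[i])/(ISI[i+1]+ISI[i])` (>= 4 spikes).}
#'   \item{AP_height}{mean peak voltage.}
#'   \item{AP_amplitude_from_voltagebase}{mean(peak - voltage base).}
#'   \item{AHP_depth_abs}{mean of the minima between consecutive peaks.}
#'   \item{AHP_depth_abs_slow}{mean of the minima on
#'     `[peak + 5 ms, next onset]`.}
#'   \item{AHP_slow_time}{mean of (slow-AHP time - peak time)/ISI.}
#'   \item{AP_width}{mean spike width at the detection-threshold level.}
#' }
#'
#' @param trace A [voltage_trace()].
#' @param name Feature name (see [efeature_names()]).
#' @param threshold Spike detection threshold (mV).
#' @return Scalar feature value, or `NA_real_` when missing.
#' @export
compute_feature <- function(trace, name, threshold = -20) {
  if (!name %in% efeature_names())
    stop("unknown feature '", name, "'; supported: ",
         paste(efeature_names(), collapse = ", "))
  st <- detect_spikes(trace, threshold)
  win <- st$peak_times >= trace$stim_start & st$peak_times <= trace$stim_end
  pt <- st$peak_times[win]; pv <- st$peak_values[win]
  on <- st$onset_times[win]; off <- st$offset_times[win]
  nsp <- length(pt)
  isis <- if (nsp >= 2) diff(pt) else numeric(0)
  vbase <- if (any(trace$t < trace$stim_start))
    mean(trace$v[trace$t < trace$stim_start]) else NA_real_

  switch(name,
    Spikecount = as.numeric(nsp),
    time_to_first_spike = if (nsp >= 1) pt[1] - trace$stim_start else NA_real_,
    mean_frequency = {
      if (nsp >= 1 && pt[nsp] > trace$stim_start)
        1000 * nsp / (pt[nsp] - trace$stim_start) else NA_real_
    },
    ISI_CV = if (nsp >= 3) stats::sd(isis) / mean(isis) else NA_real_,
    doublet_ISI = if (nsp >= 2) pt[2] - pt[1] else NA_real_,
    adaptation_index2 = {
      if (length(isis) >= 3) {
        i <- 2:(length(isis) - 1)
        mean((isis[i + 1] - isis[i]) / (isis[i + 1] + isis[i]))
      } else NA_real_
    },
    AP_height = if (nsp >= 1) mean(pv) else NA_real_,
    AP_amplitude_from_voltagebase =
      if (nsp >= 1 && is.finite(vbase)) mean(pv - vbase) else NA_real_,
    AHP_depth_abs = {
      if (nsp >= 2) {
        mins <- vapply(seq_len(nsp - 1), function(i) {
          sel <- trace$t > pt[i] & trace$t < pt[i + 1]
          if (any(sel)) min(trace$v[sel]) else NA_real_
        }, numeric(1))
        if (all(is.na(mins))) NA_real_ else mean(mins, na.rm = TRUE)
      } else NA_real_
    },
    AHP_depth_abs_slow = {
      w <- slow_ahp(trace, pt, on, nsp)
      if (is.null(w)) NA_real_ else mean(w$v)
    },
    AHP_slow_time = {
      w <- slow_ahp(trace, pt, on, nsp)
      if (is.null(w)) NA_real_
      else mean((w$t - pt[w$i]) / isis[w$i])
    },
    AP_width = {
      ok <- is.finite(on) & is.finite(off)
      if (nsp >= 1 && any(ok)) mean(off[ok] - on[ok]) else NA_real_
    })
}

# minima of the slow-AHP windows [peak_i + 5 ms, onset_{i+1}];
# returns NULL when no valid window exists
slow_ahp <- function(trace, pt, on, nsp) {
  if (nsp < 2) return(NULL)
  out_t <- out_v <- numeric(0); out_i <- integer(0)
  for (i in seq_len(nsp - 1)) {
    lo <- pt[i] + 5
    hi <- on[i + 1]
    sel <- trace$t >= lo & trace$t <= hi
    if (!any(sel)) next
    j <- which(sel)[which.min(trace$v[sel])]
    out_t <- c(out_t, trace$t[j]); out_v <- c(out_v, trace$v[j])
    out_i <- c(out_i, i)
  }
  if (length(out_t) == 0L) NULL else list(t = out_t, v = out_v, i = out_i)
}

#' Score one feature against its target
#'
#' The normalized objective score `|mu_exp - f_model| / sigma_exp`:
#' 0 means a perfect match, k means k experimental standard deviations
#' away. A missing feature value (`NA`) scores the penalty.
#'
#' @param f_model Model feature value or `NA`.
#' @param target A [feature_target()].
#' @param penalty Non-negative score for missing features (default 250).
#' @return Non-negative score.
#' @export
feature_score <- function(f_model, target, penalty = 250) {
  stopifnot(penalty >= 0)
  if (is.na(f_model)) return(penalty)
  abs(target$exp_mean - f_model) / target$exp_std
}

#' Score a set of responses against feature targets
#'
#' @param responses Named list of [voltage_trace()] objects; names are
#'   `"<protocol>.<recording>"`.
#' @param targets List of [feature_target()] objects.
#' @param penalty Score for missing features.
#' @param threshold Spike detection threshold (mV).
#' @return Numeric score vector aligned with `targets`.
#' @export
calculate_objectives <- function(responses, targets, penalty = 250,
                                 threshold = -20) {
  vapply(targets, function(tg) {
    key <- paste0(tg$protocol, ".", tg$recording)
    if (is.null(responses[[key]]))
      stop("missing recording '", key, "' in responses")
    f <- compute_feature(responses[[key]], tg$feature, threshold = threshold)
    feature_score(f, tg, penalty = penalty)
  }, numeric(1))
}

#' Feature table for a trace
#'
#' Convenience wrapper computing every supported feature on one trace.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Spike detection threshold (mV).
#' @return Data frame with columns `feature` and `value`.
#' @export
feature_table <- function(trace, threshold = -20) {
  data.frame(feature = efeature_names(),
             value = vapply(efeature_names(), function(nm)
               compute_feature(trace, nm, threshold = threshold),
               numeric(1)),
             row.names = NULL)
}
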