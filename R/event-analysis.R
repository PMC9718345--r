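# Lick onset detection and event-triggered averaging, used to test whether
# the temperature signal is distorted by orofacial licking movements.

#' Detect lick onsets from a vibration channel
#'
#' The trace is baseline-subtracted (median), rectified, and smoothed into a
#' short envelope; the threshold is either a manual value or
#' `median + k_mad * mad` of the envelope (replacing the manually adjusted
#' daily threshold used in bench practice with a robust automatic default).
#' Onsets are upward threshold crossings, with a refractory period
#' suppressing re-triggers within one lick.
#'
#' @param vibration A [sampled_trace()] from the spout vibration sensor.
#' @param k_mad Robust threshold multiplier (default 5).
#' @param refractory Minimum spacing between onsets in seconds (default 0.1,
#'   below the ~250 ms lick period).
#' @param manual_threshold Optional absolute threshold in envelope units,
#'   overriding the automatic rule.
#' @param envelope_window Rectified-envelope smoothing window in seconds.
#' @return A `lick_events` list: `onsets` (s), `threshold_used`, `n`.
#' @export
detect_lick_onsets <- function(vibration, k_mad = 5, refractory = 0.1,
                               manual_threshold = NULL,
                               envelope_window = 0.01) {
  stopifnot(inherits(vibration, "sampled_trace"),
            length(vibration$values) > 0L)
  env <- abs(vibration$values - stats::median(vibration$values))
  env <- runmean(env, envelope_window * vibration$fs)
  thr <- manual_threshold %||%
    (stats::median(env) + k_mad * stats::mad(env))
  above <- env > thr
  if (!any(above)) {
    warning("threshold above the global maximum; no licks detected",
            call. = FALSE)
    return(structure(list(onsets = numeric(0), threshold_used = thr, n = 0L),
                     class = "lick_events"))
  }
  cross <- which(above & !c(FALSE, above[-length(above)]))
  times <- vibration$t0 + (cross - 1L) / vibration$fs
  onsets <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      onsets <- c(onsets, tt)
      last <- tt
    }
  }
  structure(list(onsets = onsets, threshold_used = thr, n = length(onsets)),
            class = "lick_events")
}

#' @export
print.lick_events <- function(x, ...) {
  cat(sprintf("<lick_events> %d onsets (threshold %.4g)\n", x$n,
              x$threshold_used))
  invisible(x)
}

#' Event-triggered average of a trace
#'
#' Trace segments around each event are interpolated onto a common lag grid,
#' baseline-subtracted by their pre-event mean, and averaged across events.
#' The modulation index is the largest absolute post-event mean deviation
#' divided by the robust respiratory amplitude of the whole trace (90th
#' minus 10th percentile); it is near zero when the events are independent
#' of the signal and grows when an event-locked artifact is present.
#'
#' @param trace A [sampled_trace()] (typically the temperature channel).
#' @param events Event times in seconds.
#' @param window Numeric pair `(pre, post)` of window extents in seconds
#'   (default `c(2, 2)`, i.e. lags -2..+2 s). Events whose window leaves the
#'   trace are dropped.
#' @return A `triggered_average` list: `lags`, `mean`, `sd`, `n_events`,
#'   `modulation_index`.
#' @export
triggered_average <- function(trace, events, window = c(2, 2)) {
  stopifnot(inherits(trace, "sampled_trace"), length(window) == 2L,
            all(window > 0))
  tt <- trace_times(trace)
  lags <- seq(-window[1], window[2], by = 1 / trace$fs)
  usable <- events[events - window[1] >= tt[1] &
                   events + window[2] <= tt[length(tt)]]
  if (!length(usable)) stop("no events with a full window inside the trace",
                            call. = FALSE)
  segs <- vapply(usable, function(ev) {
    s <- stats::approx(tt, trace$values, xout = ev + lags)$y
    s - mean(s[lags < 0])
  }, numeric(length(lags)))
  segs <- matrix(segs, nrow = length(lags))
  mu <- rowMeans(segs)
  sdv <- apply(segs, 1L, stats::sd)
  q <- stats::quantile(trace$values, c(0.1, 0.9), names = FALSE)
  amp <- q[2] - q[1]
  mi <- if (amp > 0) max(abs(mu[lags > 0])) / amp else 0
  structure(list(lags = lags, mean = mu, sd = sdv,
                 n_events = length(usable), modulation_index = mi),
            class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered_average> %d events, lags %.2f..%.2f s, modulation index %.3f\n",
              x$n_events, min(x$lags), max(x$lags), x$modulation_index))
  invisible(x)
}

#' Write a triggered average as CSV
#'
#' Columns `lag_s`, `mean`, `sd`.
#'
#' @param ta A `triggered_average`.
#' @param path Output file.
#' @export
write_triggered_average_csv <- function(ta, path) {
  stopifnot(inherits(ta, "triggered_average"))
  utils::write.csv(data.frame(lag_s = ta$lags, mean = ta$mean, sd = ta$sd),
                   path, row.names = FALSE)
  invisible(path)
}
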