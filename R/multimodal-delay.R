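# Timing offset between thermosensor-derived and chest-band-derived
# respiratory events, and its dependence on probe position and body weight.

#' Match respiratory events across two modalities
#'
#' Greedy nearest-neighbour matching of two sorted event lists: candidate
#' pairs within `tolerance` are taken in order of increasing absolute time
#' difference (ties broken toward the earlier chest event, then the earlier
#' thermosensor event), each event used at most once. On realistically
#' structured event trains -- one event per breath, tolerance below half a
#' breath period -- this equals the minimum-cost assignment.
#'
#' @param thermo_events Sorted times (s) of thermosensor events.
#' @param chest_events Sorted times (s) of chest-band events of the same
#'   physiological phase.
#' @param tolerance Maximum |thermo - chest| for a pair, in seconds. The
#'   conventional choice is 0.45 times the median IPI, which forbids
#'   cross-cycle pairing.
#' @return A `peak_match` list: `pairs` (data frame `thermo_time`,
#'   `chest_time`, `delay`), `delays`, `mean_delay` (thermo minus chest;
#'   positive means the thermosensor lags), `n_unmatched`.
#' @export
match_events <- function(thermo_events, chest_events, tolerance) {
  stopifnot(!is.unsorted(thermo_events), !is.unsorted(chest_events),
            tolerance > 0)
  if (!length(thermo_events) || !length(chest_events)) {
    warning("empty event list; returning empty match", call. = FALSE)
    return(empty_match(length(thermo_events) + length(chest_events)))
  }
  cand <- expand.grid(ti = seq_along(thermo_events),
                      ci = seq_along(chest_events))
  cand$delay <- thermo_events[cand$ti] - chest_events[cand$ci]
  cand <- cand[abs(cand$delay) <= tolerance, , drop = FALSE]
  if (!nrow(cand)) return(empty_match(length(thermo_events) + length(chest_events)))
  cand <- cand[order(abs(cand$delay), chest_events[cand$ci],
                     thermo_events[cand$ti]), , drop = FALSE]
  used_t <- logical(length(thermo_events))
  used_c <- logical(length(chest_events))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ti <- cand$ti[r]; ci <- cand$ci[r]
    if (!used_t[ti] && !used_c[ci]) {
      keep[r] <- TRUE
      used_t[ti] <- TRUE
      used_c[ci] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  m <- m[order(m$ti), , drop = FALSE]
  pairs <- data.frame(thermo_time = thermo_events[m$ti],
                      chest_time = chest_events[m$ci],
                      delay = m$delay)
  structure(list(pairs = pairs, delays = pairs$delay,
                 mean_delay = mean(pairs$delay),
                 n_unmatched = sum(!used_t) + sum(!used_c),
                 tolerance = tolerance),
            class = "peak_match")
}

empty_match <- function(n_unmatched) {
  structure(list(pairs = data.frame(thermo_time = numeric(0),
                                    chest_time = numeric(0),
                                    delay = numeric(0)),
                 delays = numeric(0), mean_delay = NA_real_,
                 n_unmatched = n_unmatched, tolerance = NA_real_),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("<peak_match> %d pairs (mean delay %s ms), %d unmatched\n",
              nrow(x$pairs),
              if (is.na(x$mean_delay)) "NA" else sprintf("%.1f", 1000 * x$mean_delay),
              x$n_unmatched))
  invisible(x)
}

#' Thermosensor-vs-chest delay for one session
#'
#' Extracts respiratory events from the temperature trace and the chest
#' diameter (integrating the movement channel first when needed) and matches
#' them. By default temperature peaks (expiration ends) are matched to chest
#' diameter troughs -- the same physiological transition -- so the delay is a
#' pure measurement lag. `mode = "peak-peak"` instead matches peaks of both
#' waveforms, the convention used when both channels are simply treated as
#' "respiration signals" with marked peaks; those events sit on different
#' phase transitions, so this mode mixes the measurement lag with the
#' inspiration duration.
#'
#' @param temperature A [sampled_trace()] of nasal temperature.
#' @param chest A [sampled_trace()] of chest movement (integrated
#'   automatically when labelled `chest_movement`) or chest diameter.
#' @param mode `"physiological"` (default) or `"peak-peak"`.
#' @param tolerance_frac Matching tolerance as a fraction of the median IPI.
#' @param ... Detection settings passed to [detect_extrema()].
#' @return A `peak_match` (see [match_events()]).
#' @export
session_delay <- function(temperature, chest, mode = c("physiological", "peak-peak"),
                          tolerance_frac = 0.45, ...) {
  mode <- match.arg(mode)
  if (identical(chest$label, "chest_movement")) {
    chest <- integrate_chest_movement(chest)
  }
  ex_t <- detect_extrema(temperature, ...)
  ex_c <- detect_extrema(chest, ...)
  thermo <- ex_t$time[ex_t$kind == "peak"]
  chest_kind <- if (mode == "physiological") "trough" else "peak"
  chest_ev <- ex_c$time[ex_c$kind == chest_kind]
  tol <- tolerance_frac * stats::median(diff(thermo))
  match_events(thermo, chest_ev, tol)
}

#' Regress per-session delays on a covariate
#'
#' Ordinary least squares of mean session delay on a covariate such as probe
#' position (mm) or body weight (kg), with Pearson correlation and its
#' two-sided p-value (from the in-package statistical routines).
#'
#' @param data Data frame with one row per session.
#' @param covariate_col,delay_col Column names (defaults `"covariate"`,
#'   `"mean_delay"`).
#' @return List with `table` (the input points) and `regression` (a
#'   `regress_result`, see [pearson_r()]).
#' @export
delay_by_condition <- function(data, covariate_col = "covariate",
                               delay_col = "mean_delay") {
  stopifnot(is.data.frame(data),
            all(c(covariate_col, delay_col) %in% names(data)))
  x <- data[[covariate_col]]
  y <- data[[delay_col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct covariate values for a regression",
         call. = FALSE)
  }
  if (stats::var(x) == 0) stop("degenerate covariate: zero variance", call. = FALSE)
  list(table = data.frame(covariate = x, mean_delay = y),
       regression = pearson_r(x, y))
}
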