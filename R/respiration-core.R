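# Respiratory cycle extraction from a temperature or chest-diameter trace.
#
# The nasal air temperature rises during expiration (warm expired air) and
# falls during inspiration (ambient air), so temperature peaks mark
# expiration ends and troughs mark inspiration ends. The chest diameter has
# the opposite convention: it rises during inspiration. Both conventions are
# handled by segment_cycles().

# Strict local maxima of `s` with their topographic prominence: for each
# maximum, extend left and right until a strictly higher sample (or the
# edge); prominence = peak - max(lowest point on left stretch, lowest on
# right stretch).
local_maxima_prominence <- function(s) {
  n <- length(s)
  if (n < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  prom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    peak <- s[i]
    lo_l <- peak
    j <- i - 1L
    while (j >= 1L && s[j] <= peak) {
      if (s[j] < lo_l) lo_l <- s[j]
      j <- j - 1L
    }
    lo_r <- peak
    j <- i + 1L
    while (j <= n && s[j] <= peak) {
      if (s[j] < lo_r) lo_r <- s[j]
      j <- j + 1L
    }
    prom[k] <- peak - max(lo_l, lo_r)
  }
  data.frame(index = idx, prominence = prom)
}

# Keep candidates (ordered by decreasing prominence, ties to the earlier
# sample) whose index is at least `min_sep` samples from every already-kept
# candidate.
enforce_refractory <- function(cand, min_sep) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(-cand$prominence, cand$index)
  kept <- integer(0)
  for (r in ord) {
    if (!length(kept) || all(abs(cand$index[kept] - cand$index[r]) >= min_sep)) {
      kept <- c(kept, r)
    }
  }
  cand[sort(kept), , drop = FALSE]
}

#' Detect respiratory extrema
#'
#' Smooths the trace with a centered moving average, finds strict local
#' maxima and minima whose topographic prominence is at least
#' `min_prominence_frac` times the robust amplitude (90th minus 10th
#' percentile of the smoothed trace), enforces a refractory spacing within
#' each kind, and then enforces peak/trough alternation by discarding the
#' lower-prominence of any two consecutive same-kind extrema. Returned times
#' are sub-sample estimates from a parabolic fit through the extremum and its
#' two neighbours.
#'
#' @param trace A [sampled_trace()].
#' @param smooth_window Moving-average width in seconds (default 0.15).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   robust amplitude (default 0.3).
#' @param refractory Minimum spacing between same-kind extrema in seconds
#'   (default 0.6, well below any plausible breath period).
#' @return A `resp_extrema` data frame with columns `time`, `kind`
#'   (`"peak"`/`"trough"`), `index` (sample index), `prominence`; kinds
#'   strictly alternate and times strictly increase.
#' @seealso [segment_cycles()]
#' @export
detect_extrema <- function(trace, smooth_window = 0.15,
                           min_prominence_frac = 0.3, refractory = 0.6) {
  stopifnot(inherits(trace, "sampled_trace"))
  fs <- trace$fs
  if (length(trace$values) / fs <= 3 * refractory) {
    stop("trace shorter than 3 refractory periods; nothing to detect",
         call. = FALSE)
  }
  s <- runmean(trace$values, smooth_window * fs)
  q <- stats::quantile(s, c(0.1, 0.9), names = FALSE)
  thr <- min_prominence_frac * (q[2] - q[1])
  min_sep <- refractory * fs

  pk <- local_maxima_prominence(s)
  tr <- local_maxima_prominence(-s)
  pk <- pk[pk$prominence >= thr & thr > 0, , drop = FALSE]
  tr <- tr[tr$prominence >= thr & thr > 0, , drop = FALSE]
  pk <- enforce_refractory(pk, min_sep)
  tr <- enforce_refractory(tr, min_sep)

  ev <- rbind(
    if (nrow(pk)) data.frame(index = pk$index, kind = "peak", prominence = pk$prominence),
    if (nrow(tr)) data.frame(index = tr$index, kind = "trough", prominence = tr$prominence)
  )
  if (is.null(ev) || nrow(ev) < 2L) {
    stop(no_respiration_error(trace$label))
  }
  ev <- ev[order(ev$index), , drop = FALSE]
  ev <- enforce_alternation(ev)
  if (nrow(ev) < 2L) stop(no_respiration_error(trace$label))

  off <- vapply(ev$index, function(i) {
    if (i <= 1L || i >= length(s)) 0 else parabolic_offset(s[i - 1], s[i], s[i + 1])
  }, 0)
  ev$time <- trace$t0 + (ev$index - 1L + off) / fs
  out <- ev[, c("time", "kind", "index", "prominence")]
  rownames(out) <- NULL
  structure(out, class = c("resp_extrema", "data.frame"), fs = fs)
}

# Drop the lower-prominence of any two consecutive same-kind events (ties:
# drop the later one), repeating until kinds strictly alternate.
enforce_alternation <- function(ev) {
  repeat {
    same <- which(ev$kind[-1] == ev$kind[-nrow(ev)])
    if (!length(same)) return(ev)
    i <- same[1]
    drop <- if (ev$prominence[i] < ev$prominence[i + 1]) i else i + 1L
    ev <- ev[-drop, , drop = FALSE]
    if (nrow(ev) < 2L) return(ev)
  }
}

no_respiration_error <- function(label) {
  structure(
    class = c("thermoresp_no_respiration", "error", "condition"),
    list(message = paste0("no respiration detected",
                          if (nzchar(label)) paste0(" in channel '", label, "'"),
                          ": fewer than 2 extrema survive the prominence and ",
                          "refractory rules"),
         call = NULL)
  )
}

#' Segment alternating extrema into respiratory cycles
#'
#' For a temperature trace, inspiration is the cooling peak-to-trough stretch
#' and expiration the warming trough-to-peak stretch; for a chest-diameter
#' trace the chest expands during inspiration, so the labels are swapped.
#' Partial cycles at the edges are dropped.
#'
#' @param extrema A `resp_extrema` from [detect_extrema()] (>= 3 alternating
#'   events).
#' @param signal_kind `"temperature"` or `"chest_diameter"`.
#' @return A `resp_cycles` data frame with columns `insp_start`, `exp_start`,
#'   `insp_duration`, `exp_duration` (seconds), carrying `signal_kind` as an
#'   attribute.
#' @export
segment_cycles <- function(extrema, signal_kind = c("temperature", "chest_diameter")) {
  signal_kind <- match.arg(signal_kind)
  stopifnot(inherits(extrema, "resp_extrema"))
  if (nrow(extrema) < 3L) {
    stop("need at least 3 alternating extrema to form a cycle", call. = FALSE)
  }
  # the extremum kind that marks an inspiration start
  start_kind <- if (signal_kind == "temperature") "peak" else "trough"
  k <- extrema$kind
  t <- extrema$time
  first <- which(k == start_kind)[1]
  if (is.na(first)) stop("no inspiration-start extrema present", call. = FALSE)
  insp_start <- exp_start <- insp_end <- numeric(0)
  i <- first
  while (i + 2L <= nrow(extrema)) {
    insp_start <- c(insp_start, t[i])
    exp_start <- c(exp_start, t[i + 1L])
    insp_end <- c(insp_end, t[i + 2L])
    i <- i + 2L
  }
  if (!length(insp_start)) {
    stop("not enough extrema for one full cycle", call. = FALSE)
  }
  out <- data.frame(insp_start = insp_start, exp_start = exp_start,
                    insp_duration = exp_start - insp_start,
                    exp_duration = insp_end - exp_start)
  structure(out, class = c("resp_cycles", "data.frame"),
            signal_kind = signal_kind)
}

#' Summarize respiratory cycles
#'
#' Computes the inter-peak interval (IPI) series as successive differences of
#' the chosen anchor events and the inspiration/expiration time ratio as the
#' mean of per-cycle duration ratios (matching how a per-cycle SD of the
#' ratio is reported).
#'
#' @param cycles A `resp_cycles` from [segment_cycles()], at least 2 cycles.
#' @param ipi_anchor `"peak"` (default; for temperature these are the
#'   expiration-end maxima usually marked on respiration traces) or
#'   `"trough"`.
#' @return A `resp_summary` list: `ipi_series`, `anchor_times`, `mean_ipi`,
#'   `sd_ipi`, `ie_ratio`, `n_cycles`.
#' @export
summarize_cycles <- function(cycles, ipi_anchor = c("peak", "trough")) {
  ipi_anchor <- match.arg(ipi_anchor)
  stopifnot(inherits(cycles, "resp_cycles"))
  if (nrow(cycles) < 2L) stop("need at least 2 cycles to form an IPI series",
                              call. = FALSE)
  signal_kind <- attr(cycles, "signal_kind")
  # which cycle boundary carries the requested extremum kind
  peak_col <- if (signal_kind == "temperature") "insp_start" else "exp_start"
  trough_col <- setdiff(c("insp_start", "exp_start"), peak_col)
  anchors <- cycles[[if (ipi_anchor == "peak") peak_col else trough_col]]
  ipi <- diff(anchors)
  structure(list(ipi_series = ipi, anchor_times = anchors,
                 mean_ipi = mean(ipi), sd_ipi = stats::sd(ipi),
                 ie_ratio = mean(cycles$insp_duration / cycles$exp_duration),
                 n_cycles = nrow(cycles)),
            class = "resp_summary")
}

#' @export
print.resp_summary <- function(x, ...) {
  cat(sprintf("<resp_summary> %d cycles: IPI %.3f +/- %.3f s, I/E ratio %.3f\n",
              x$n_cycles, x$mean_ipi, x$sd_ipi, x$ie_ratio))
  invisible(x)
}

#' Integrate the chest movement channel into a chest diameter
#'
#' Chest-band movement sensors output the time-derivative of the chest
#' diameter; cumulative trapezoidal integration recovers the diameter, and a
#' running-mean baseline (default 30 s) is subtracted to suppress the slow
#' drift that integrating sensor offset/noise produces. Set
#' `detrend_window = 0` to skip detrending.
#'
#' @param movement A [sampled_trace()] of chest movement.
#' @param detrend_window Running-mean window in seconds (0 = off).
#' @return A [sampled_trace()] labelled `"chest_diameter"`.
#' @export
integrate_chest_movement <- function(movement, detrend_window = 30) {
  stopifnot(inherits(movement, "sampled_trace"))
  d <- as.numeric(pracma::cumtrapz(movement$values)) / movement$fs
  if (detrend_window > 0) {
    d <- d - runmean(d, detrend_window * movement$fs)
  }
  units <- if (grepl("/s$", movement$units)) {
    sub("/s$", "", movement$units)
  } else if (nzchar(movement$units)) {
    paste0(movement$units, "*s")
  } else ""
  sampled_trace(d, movement$fs, t0 = movement$t0, units = units,
                label = "chest_diameter")
}

#' Write a cycle table as CSV
#'
#' @param cycles A `resp_cycles` from [segment_cycles()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  stopifnot(inherits(cycles, "resp_cycles"))
  df <- as.data.frame(cycles)
  df$ipi <- c(diff(df$insp_start), NA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
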