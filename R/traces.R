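#' Uniformly sampled single-channel trace
#'
#' The basic container for all recorded and simulated signals: a numeric
#' vector sampled at a fixed rate, with the time of sample \eqn{i} defined as
#' \eqn{t_0 + (i-1)/f_s}.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units Physical units of the samples (e.g. `"degC"`, `"au"`).
#' @param label Channel name (e.g. `"temperature"`, `"chest_movement"`).
#' @return An object of class `sampled_trace`.
#' @examples
#' tr <- sampled_trace(sin(2 * pi * 0.5 * seq(0, 10, by = 0.01)), fs = 100,
#'                     units = "degC", label = "temperature")
#' tr
#' @export
sampled_trace <- function(values, fs, t0 = 0, units = "", label = "") {
  values <- as.numeric(values)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("trace values must be finite", call. = FALSE)
  }
  structure(
    list(values = values, fs = fs, t0 = as.numeric(t0),
         units = as.character(units), label = as.character(label)),
    class = "sampled_trace"
  )
}

#' @export
print.sampled_trace <- function(x, ...) {
  dur <- length(x$values) / x$fs
  cat(sprintf("<sampled_trace> %s: %d samples @ %g Hz (%.1f s)%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs, dur,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [sampled_trace()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' Exact discrete first-order (RC) lag filter
#'
#' Applies the first-order low-pass \eqn{\tau \dot y + y = x} using the exact
#' zero-order-hold discretization \eqn{y_k = \alpha y_{k-1} + (1-\alpha) x_k}
#' with \eqn{\alpha = e^{-1/(f_s \tau)}}. This models the thermal response of
#' a thermosensor with time constant `tau`; for a sinusoidal drive at
#' frequency \eqn{f} the output peaks lag the input by
#' \eqn{\arctan(2\pi f\tau)/(2\pi f)}.
#'
#' @param x Numeric vector (or [sampled_trace()]) to filter.
#' @param fs Sampling rate in Hz; ignored when `x` is a trace.
#' @param tau Time constant in seconds; `tau = 0` returns `x` unchanged.
#' @return Same type as `x`.
#' @export
first_order_lag <- function(x, fs = NULL, tau) {
  if (inherits(x, "sampled_trace")) {
    out <- x
    out$values <- first_order_lag(x$values, x$fs, tau)
    return(out)
  }
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0)
  if (tau == 0 || length(x) == 0L) return(x)
  if (is.null(fs)) stop("`fs` required when filtering a plain vector", call. = FALSE)
  a <- exp(-1 / (fs * tau))
  y <- stats::filter((1 - a) * x, filter = a, method = "recursive", init = x[1])
  as.numeric(y)
}

#' Write / read a channel CSV
#'
#' One channel per file: a comment header
#' `# fs_hz=<float>, units=<str>, t0=<float>` followed by a single `value`
#' column. This is the on-disk dialect used by session bundles and accepted
#' for real two-column recordings exported to a single value column.
#'
#' @param trace A [sampled_trace()].
#' @param path File path.
#' @return `write_channel_csv` returns `path` invisibly; `read_channel_csv`
#'   returns a [sampled_trace()].
#' @export
write_channel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sampled_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.17g, units=%s, t0=%.17g",
                     trace$fs, trace$units, trace$t0), con)
  writeLines("value", con)
  writeLines(sprintf("%.17g", trace$values), con)
  invisible(path)
}

#' @rdname write_channel_csv
#' @param label Channel label to attach on read (defaults to the file name).
#' @export
read_channel_csv <- function(path, label = NULL) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec(
    "^#\\s*fs_hz=([0-9.eE+-]+),\\s*units=([^,]*),\\s*t0=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 4L) {
    stop("not a channel CSV (missing '# fs_hz=..., units=..., t0=...' header): ",
         path, call. = FALSE)
  }
  vals <- utils::read.csv(path, comment.char = "#")$value
  sampled_trace(vals, fs = as.numeric(m[2]), t0 = as.numeric(m[4]),
                units = trimws(m[3]),
                label = label %||% sub("\\.csv$", "", basename(path)))
}
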