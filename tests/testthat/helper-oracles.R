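# Independent brute-force oracles used to cross-check the optimized
# implementations. These re-apply the same documented rules with naive
# exhaustive loops and share no code with the package internals.

# --- extrema detection oracle -------------------------------------------

oracle_runmean <- function(x, w) {
  w <- max(1L, as.integer(round(w)))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

oracle_prominence <- function(s, i) {
  n <- length(s)
  peak <- s[i]
  lo_l <- peak
  j <- i - 1L
  while (j >= 1L && s[j] <= peak) {
    lo_l <- min(lo_l, s[j])
    j <- j - 1L
  }
  lo_r <- peak
  j <- i + 1L
  while (j <= n && s[j] <= peak) {
    lo_r <- min(lo_r, s[j])
    j <- j + 1L
  }
  peak - max(lo_l, lo_r)
}

# Exhaustive scan applying the documented smoothing / prominence /
# refractory / alternation / parabolic-interpolation rules sample by sample.
oracle_extrema <- function(trace, smooth_window = 0.15,
                           min_prominence_frac = 0.3, refractory = 0.6) {
  fs <- trace$fs
  s <- oracle_runmean(trace$values, smooth_window * fs)
  n <- length(s)
  q <- stats::quantile(s, c(0.1, 0.9), names = FALSE)
  thr <- min_prominence_frac * (q[2] - q[1])
  if (thr <= 0) return(NULL)
  min_sep <- refractory * fs

  find_kind <- function(sig) {
    cand <- list()
    for (i in 2:(n - 1)) {
      if (sig[i] > sig[i - 1] && sig[i] > sig[i + 1]) {
        p <- oracle_prominence(sig, i)
        if (p >= thr) cand[[length(cand) + 1L]] <- c(index = i, prominence = p)
      }
    }
    if (!length(cand)) return(data.frame(index = integer(0), prominence = numeric(0)))
    cand <- as.data.frame(do.call(rbind, cand))
    # refractory: decreasing prominence, ties earlier index
    ord <- order(-cand$prominence, cand$index)
    kept <- integer(0)
    for (r in ord) {
      clash <- FALSE
      for (k in kept) {
        if (abs(cand$index[k] - cand$index[r]) < min_sep) clash <- TRUE
      }
      if (!clash) kept <- c(kept, r)
    }
    cand[sort(kept), , drop = FALSE]
  }

  pk <- find_kind(s)
  tr <- find_kind(-s)
  ev <- rbind(
    if (nrow(pk)) data.frame(index = pk$index, kind = "peak", prominence = pk$prominence),
    if (nrow(tr)) data.frame(index = tr$index, kind = "trough", prominence = tr$prominence)
  )
  if (is.null(ev) || nrow(ev) < 2L) return(NULL)
  ev <- ev[order(ev$index), , drop = FALSE]
  # alternation: drop lower-prominence of first adjacent same-kind pair
  repeat {
    same <- which(ev$kind[-1] == ev$kind[-nrow(ev)])
    if (!length(same)) break
    i <- same[1]
    drop <- if (ev$prominence[i] < ev$prominence[i + 1]) i else i + 1L
    ev <- ev[-drop, , drop = FALSE]
    if (nrow(ev) < 2L) return(NULL)
  }
  ev$time <- vapply(seq_len(nrow(ev)), function(r) {
    i <- ev$index[r]
    if (i <= 1L || i >= n) return(trace$t0 + (i - 1) / fs)
    y1 <- s[i - 1]; y2 <- s[i]; y3 <- s[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) < 1e-300) 0 else max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
    trace$t0 + (i - 1 + off) / fs
  }, 0)
  ev
}

# --- event matching oracle ----------------------------------------------

# Exhaustive assignment: maximize the number of matched pairs within
# tolerance, break ties by minimal total |delay|. Recursion over thermo
# events; feasible for the small instances used in tests.
oracle_match <- function(thermo, chest, tol) {
  nt <- length(thermo)
  best <- new.env()
  best$count <- -1L
  best$cost <- Inf
  best$assign <- rep(NA_integer_, nt)
  assign_now <- rep(NA_integer_, nt)
  rec <- function(ti, used_c, count, cost) {
    if (ti > nt) {
      if (count > best$count || (count == best$count && cost < best$cost)) {
        best$count <- count
        best$cost <- cost
        best$assign <- assign_now
      }
      return(invisible())
    }
    # skip this thermo event
    assign_now[ti] <<- NA_integer_
    rec(ti + 1L, used_c, count, cost)
    for (ci in seq_along(chest)) {
      d <- thermo[ti] - chest[ci]
      if (!used_c[ci] && abs(d) <= tol) {
        used_c[ci] <- TRUE
        assign_now[ti] <<- ci
        rec(ti + 1L, used_c, count + 1L, cost + abs(d))
        used_c[ci] <- FALSE
        assign_now[ti] <<- NA_integer_
      }
    }
  }
  rec(1L, logical(length(chest)), 0L, 0)
  ti <- which(!is.na(best$assign))
  data.frame(thermo_time = thermo[ti], chest_time = chest[best$assign[ti]],
             delay = thermo[ti] - chest[best$assign[ti]])
}

# --- shared fixtures -----------------------------------------------------

# A single-block schedule (one noise block) for fast event-analysis
# sessions; rewards at roughly the protocol rate of one per 30 s so the
# >= 10 s spacing constraint stays feasible for short blocks.
short_schedule <- function(seed = 1, duration = 180,
                           n_rewards = max(2L, round(duration / 30))) {
  set.seed(seed)
  rw <- numeric(0)
  repeat {
    rw <- sort(stats::runif(n_rewards, 2, duration - 5))
    if (n_rewards < 2 || all(diff(rw) >= 10)) break
  }
  session_schedule(list(stimulus_block("noise", 0, 40, 0, duration)), rw)
}

make_noise_trace <- function(n, fs = 100, sd = 1, seed = 1) {
  set.seed(seed)
  sampled_trace(stats::rnorm(n, sd = sd), fs = fs, label = "test")
}

# random short traces for the extrema oracle sweep: sinusoid + noise
# mixtures, occasionally pure noise
random_trace <- function(seed) {
  set.seed(seed)
  n <- sample(300:700, 1)
  fs <- 100
  t <- (0:(n - 1)) / fs
  kind <- sample(3, 1)
  v <- switch(kind,
    sin(2 * pi * stats::runif(1, 0.3, 1.2) * t) * stats::runif(1, 0.5, 2) +
      stats::rnorm(n, sd = 0.2),
    sin(2 * pi * stats::runif(1, 0.3, 0.8) * t) +
      0.4 * sin(2 * pi * stats::runif(1, 1, 2) * t) + stats::rnorm(n, sd = 0.1),
    stats::rnorm(n)
  )
  sampled_trace(v, fs = fs, label = sprintf("rand%d", seed))
}
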