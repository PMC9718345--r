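# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation helpers never clobber user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with shrinking windows at the edges; `w` in samples,
# forced odd so the window is symmetric.
runmean <- function(x, w) {
  w <- max(1L, as.integer(round(w)))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  if (w == 1L || n < 2L) return(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sub-sample offset (in samples, within [-0.5, 0.5]) of the vertex of the
# parabola through (-1, y1), (0, y2), (1, y3). Needed because timing targets
# downstream are of order one sample at 100 Hz.
parabolic_offset <- function(y1, y2, y3) {
  den <- y1 - 2 * y2 + y3
  if (!is.finite(den) || abs(den) < .Machine$double.eps * max(abs(c(y1, y2, y3, 1)))) {
    return(0)
  }
  off <- 0.5 * (y1 - y3) / den
  max(-0.5, min(0.5, off))
}

# FNV-1a hash of a character scalar, as hex; used to fingerprint configs in
# report provenance without an external digest dependency.
fnv1a_hex <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
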