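# Statistical comparisons implemented from formulas (Student/Welch t tests,
# one-way ANOVA, Pearson regression), so the pipeline's core contrasts carry
# no opaque statistical dependency. p-values come from the regularized
# incomplete beta function evaluated by a Lentz continued fraction
# (absolute accuracy well below 1e-8).

# Continued-fraction helper for the incomplete beta function.
betacf <- function(a, b, x) {
  maxit <- 300L
  eps <- 3e-14
  fpmin <- 1e-300
  qab <- a + b
  qap <- a + 1
  qam <- a - 1
  c_ <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < fpmin) d <- fpmin
  d <- 1 / d
  h <- d
  for (m in seq_len(maxit)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d
    if (abs(d) < fpmin) d <- fpmin
    c_ <- 1 + aa / c_
    if (abs(c_) < fpmin) c_ <- fpmin
    d <- 1 / d
    h <- h * d * c_
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d
    if (abs(d) < fpmin) d <- fpmin
    c_ <- 1 + aa / c_
    if (abs(c_) < fpmin) c_ <- fpmin
    d <- 1 / d
    del <- d * c_
    h <- h * del
    if (abs(del - 1) < eps) break
  }
  h
}

# Regularized incomplete beta I_x(a, b).
ibeta <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  lbt <- lgamma(a + b) - lgamma(a) - lgamma(b) + a * log(x) + b * log1p(-x)
  if (x < (a + 1) / (a + b + 2)) {
    exp(lbt) * betacf(a, b, x) / a
  } else {
    1 - exp(lbt) * betacf(b, a, 1 - x) / b
  }
}

# Two-sided p-value of a t statistic with df degrees of freedom:
# P(|T| >= |t|) = I_{df/(df+t^2)}(df/2, 1/2).
p_from_t <- function(t, df) {
  if (!is.finite(t)) return(0)
  ibeta(df / (df + t^2), df / 2, 0.5)
}

# Upper-tail p-value of an F statistic: P(F' >= F) = I_{d2/(d2+d1 F)}(d2/2, d1/2).
p_from_f <- function(f, df1, df2) {
  if (!is.finite(f)) return(0)
  if (f <= 0) return(1)
  ibeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

#' Unpaired two-sample t test
#'
#' Classical pooled-variance Student t by default; `variant = "welch"` uses
#' the Welch statistic with Satterthwaite degrees of freedom. If both samples
#' have zero variance and equal means, `t = 0` and `p = 1` by convention;
#' zero variance with unequal means falls back to the Welch form with the
#' degrees of freedom clamped at 1 and is flagged degenerate.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `ttest_result` list: `t`, `df`, `p` (two-sided), `mean_diff`
#'   (mean of `x` minus mean of `y`), `degenerate`.
#' @export
ttest_unpaired <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- mx - my
  if (vx == 0 && vy == 0) {
    if (diff == 0) {
      return(ttest_result(0, nx + ny - 2, 1, diff, degenerate = TRUE))
    }
    return(ttest_result(sign(diff) * Inf, 1, 0, diff, degenerate = TRUE))
  }
  if (variant == "pooled" && (vx == 0 || vy == 0)) variant <- "welch"
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- diff / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    t <- diff / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    df <- max(df, 1)
  }
  ttest_result(t, df, p_from_t(t, df), diff)
}

ttest_result <- function(t, df, p, mean_diff, degenerate = FALSE) {
  structure(list(t = t, df = df, p = p, mean_diff = mean_diff,
                 degenerate = degenerate),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g (mean diff %.4g)%s\n",
              x$t, x$df, x$p, x$mean_diff,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Paired t test
#'
#' One-sample Student t on the element-wise differences `x - y`. A zero
#' variance of the differences with a nonzero mean difference yields `p = 0`
#' with a degenerate-variance flag; all-zero differences yield `t = 0`,
#' `p = 1`.
#'
#' @param x,y Numeric samples of equal length >= 2.
#' @return A `ttest_result` (see [ttest_unpaired()]); `df = n - 1`.
#' @export
ttest_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length",
                                   call. = FALSE)
  stopifnot(length(x) >= 2L)
  d <- x - y
  n <- length(d)
  vd <- stats::var(d)
  md <- mean(d)
  if (vd == 0) {
    if (md == 0) return(ttest_result(0, n - 1, 1, 0, degenerate = TRUE))
    return(ttest_result(sign(md) * Inf, n - 1, 0, md, degenerate = TRUE))
  }
  t <- md / sqrt(vd / n)
  ttest_result(t, n - 1, p_from_t(t, n - 1), md)
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition; the p-value is the
#' upper tail of the F distribution. All groups constant and equal gives
#' `F = 0`, `p = 1` by convention.
#'
#' @param groups List of numeric samples, >= 2 groups, each of length >= 2.
#' @return An `anova_result` list: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- k - 1L
  df_w <- N - k
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
  }
  structure(list(F = f, df_between = df_b, df_within = df_w,
                 p = if (is.finite(f)) p_from_f(f, df_b, df_w) else 0),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Pearson correlation with OLS line
#'
#' Pearson r, the least-squares slope and intercept, and the two-sided
#' p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}}. Perfect collinearity is
#' reported as `p = 0` with a degenerate flag.
#'
#' @param x,y Numeric samples, length >= 3, both with nonzero variance.
#' @return A `regress_result` list: `slope`, `intercept`, `r`, `p`, `n`,
#'   `degenerate`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("zero variance in x or y", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  slope <- sxy / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  if (abs(r) >= 1) {
    return(structure(list(slope = slope, intercept = intercept, r = r,
                          p = 0, n = n, degenerate = TRUE),
                     class = "regress_result"))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(slope = slope, intercept = intercept, r = r,
                 p = p_from_t(t, n - 2), n = n, degenerate = FALSE),
            class = "regress_result")
}

#' @export
print.regress_result <- function(x, ...) {
  cat(sprintf("r = %.4f, p = %.4g (slope %.4g, intercept %.4g, n = %d)%s\n",
              x$r, x$p, x$slope, x$intercept, x$n,
              if (x$degenerate) " [collinear]" else ""))
  invisible(x)
}
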