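# Statistical toolkit: median/IQR, Pearson chi-squared on 2x2 tables,
# relative risk with log-normal CI, and the two-sample Wilcoxon rank-sum
# test with a tie-corrected normal approximation.

#' Construct a 2x2 contingency table
#'
#' @param a exposed with outcome.
#' @param b exposed without outcome.
#' @param c unexposed with outcome.
#' @param d unexposed without outcome.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome", "no outcome")))
  print(m)
  invisible(x)
}

.stat_result <- function(method, statistic, p_value = NA_real_,
                         effect = NA_real_, conf_int = c(NA_real_, NA_real_),
                         note = NULL) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 effect = effect, conf_int = conf_int, note = note),
            class = "carepath_stat")
}

#' @export
print.carepath_stat <- function(x, ...) {
  switch(x$method,
    chi_squared = cat(sprintf("Pearson chi-squared (df = 1): X2 = %.4g, p = %.3g\n",
                              x$statistic, x$p_value)),
    relative_risk = cat(sprintf("Relative risk: RR = %.4g (95%% CI %.4g to %.4g)\n",
                                x$effect, x$conf_int[1L], x$conf_int[2L])),
    rank_sum = cat(sprintf(
      "Wilcoxon rank-sum (normal approximation): |z| = %.4g (%s), p = %.3g\n",
      abs(x$statistic),
      if (x$statistic >= 0) "first sample ranks higher"
      else "second sample ranks higher",
      x$p_value))
  )
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values non-empty numeric vector; `NA`s are dropped.
#' @return list with `median`, `q1`, `q3`, `n`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q1 = q[1L], q3 = q[3L], n = length(values))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one degree of freedom.
#' Yates' continuity correction is available behind `correct = TRUE` but is
#' off by default.
#'
#' @param t a `two_by_two` table.
#' @param correct apply Yates' continuity correction.
#' @return a `carepath_stat` with the statistic and two-sided p-value.
#' @export
chi_squared_2x2 <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (n <= 0 || any(margins == 0)) {
    stop("degenerate table: zero margin", call. = FALSE)
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  .stat_result("chi_squared", statistic = stat,
               p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Relative risk from a 2x2 table
#'
#' `RR = (a/(a+b)) / (c/(c+d))`, with a 95% confidence interval from the
#' log-normal approximation.
#'
#' @param t a `two_by_two` table.
#' @return a `carepath_stat` with `effect` (the RR) and `conf_int`.
#' @export
relative_risk <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (a + b == 0 || c + d == 0) {
    stop("degenerate table: empty exposure group", call. = FALSE)
  }
  if (c == 0) stop("undefined RR: no outcomes among the unexposed",
                   call. = FALSE)
  rr <- (a / (a + b)) / (c / (c + d))
  ci <- c(NA_real_, NA_real_)
  if (a > 0) {
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
    ci <- exp(log(rr) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  .stat_result("relative_risk", statistic = rr, effect = rr, conf_int = ci)
}

#' Two-sample Wilcoxon rank-sum test (normal approximation)
#'
#' Mid-ranks are used for ties; the z statistic is the standardized rank
#' sum of `x` with tie-corrected variance, and the p-value is two-sided
#' from the normal distribution. A positive z means `x` tends to rank
#' higher than `y`.
#'
#' @param x,y numeric samples (each non-empty; `NA`s dropped).
#' @return a `carepath_stat` with `statistic` (signed z) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts)
  v <- n1 * n2 / 12 * ((N + 1) - if (N > 1) tie_term / (N * (N - 1)) else 0)
  if (v <= 0) stop("zero variance: all pooled values identical", call. = FALSE)
  z <- (W - mu) / sqrt(v)
  .stat_result("rank_sum", statistic = z,
               p_value = 2 * stats::pnorm(-abs(z)))
}
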