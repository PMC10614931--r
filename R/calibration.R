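#' Sample variance of Z-scores
#'
#' The inflation statistic is the average squared Z-score (variance about
#' 0): under a calibrated null it approaches 1. The mean-centered sample
#' variance is available as an option.
#'
#' @param z Numeric vector of Z-scores, length >= 2.
#' @param center Center at the sample mean instead of 0 (default `FALSE`).
#' @return The sample variance.
#' @export
z_sample_variance <- function(z, center = FALSE) {
  z <- as.numeric(z)
  if (length(z) < 2L) stop("need at least 2 Z-scores")
  if (center) stats::var(z) else mean(z^2)
}

#' Null reference interval for a mean of squared Z-scores
#'
#' Central interval of the distribution of a mean of `n` i.i.d.
#' chi-square(1) variables: the reference against which an observed average
#' Z-squared is judged. The normal approximation is mean 1, sd
#' `sqrt(2/n)`; the exact gamma option uses the fact that the sum is
#' chi-square with `n` degrees of freedom.
#'
#' @param n Number of averaged squared Z-scores (`n >= 2`).
#' @param level Coverage in `(0, 1)` (default 0.95).
#' @param method `"normal"` (default) or `"gamma"` (exact).
#' @return Length-2 numeric `(lo, hi)`.
#' @examples
#' null_variance_interval(1000, 0.95)  # about (0.912, 1.088)
#' @export
null_variance_interval <- function(n, level = 0.95,
                                   method = c("normal", "gamma")) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  a <- (1 - level) / 2
  if (method == "normal") {
    q <- stats::qnorm(1 - a) * sqrt(2 / n)
    c(1 - q, 1 + q)
  } else {
    # mean of n chi-square(1) = Gamma(shape n/2, rate n/2)
    stats::qgamma(c(a, 1 - a), shape = n / 2, rate = n / 2)
  }
}

#' Kolmogorov-Smirnov uniformity test for p-values
#'
#' One-sample KS test of the p-values against Uniform(0, 1); the package's
#' operational proxy for the visual QQ-alignment judgement of calibration.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return List with `ks_stat` and `ks_p`.
#' @export
uniformity_test <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' QQ-plot coordinates on the -log10 scale
#'
#' Observed order statistics of the p-values against expected uniform
#' quantiles `i/(n+1)`, both -log10-transformed, thinned to at most
#' `n_points` points (extremes always kept).
#'
#' @param p Numeric vector of p-values.
#' @param n_points Maximum number of points returned (default 1000).
#' @return A `data.frame` with columns `expected` and `observed`, sorted by
#'   `expected`.
#' @export
qq_points <- function(p, n_points = 1000) {
  p <- as.numeric(p)
  n <- length(p)
  if (n < 1L) stop("empty p-value vector")
  obs <- sort(p)
  expd <- seq_len(n) / (n + 1)
  if (n_points < n) {
    keep <- unique(round(seq(1, n, length.out = n_points)))
  } else {
    keep <- seq_len(n)
  }
  out <- data.frame(expected = -log10(expd[keep]),
                    observed = -log10(obs[keep]))
  out[order(out$expected), , drop = FALSE]
}

#' Assemble a calibration report
#'
#' Bundles the diagnostics the package uses to judge calibration of a set
#' of TWAS statistics: the Z-score sample variance with its null reference
#' interval, the KS uniformity test of the p-values, and QQ coordinates.
#'
#' @param z Numeric vector of Z-scores.
#' @param p Optional p-values (default: two-sided normal from `z`).
#' @param level Coverage of the null variance interval (default 0.95).
#' @param n_qq Maximum number of QQ points (default 1000).
#' @return A `calibration_report` list: `n_tests`, `z_sample_variance`,
#'   `z_var_null_interval`, `ks_stat`, `ks_p`, `qq_points`.
#' @export
calibration_report <- function(z, p = NULL, level = 0.95, n_qq = 1000) {
  z <- as.numeric(z)
  if (length(z) < 2L) stop("need at least 2 Z-scores")
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  ks <- uniformity_test(p)
  structure(
    list(n_tests = length(z),
         z_sample_variance = z_sample_variance(z),
         z_var_null_interval = null_variance_interval(length(z), level),
         ks_stat = ks$ks_stat, ks_p = ks$ks_p,
         qq_points = qq_points(p, n_qq)),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  iv <- x$z_var_null_interval
  cat("calibration_report over", x$n_tests, "tests\n")
  cat("  sample variance of Z:", signif(x$z_sample_variance, 4),
      sprintf("(null %d%% interval: %.4f - %.4f)",
              round(100 * attr(iv, "level") %||% 95), iv[1], iv[2]), "\n")
  cat("  KS uniformity: stat =", signif(x$ks_stat, 4),
      ", p =", signif(x$ks_p, 4), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
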