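#' Mann-Kendall S statistic and tie-corrected variance
#'
#' `S = sum_(i<j) sign(x_j - x_i)` over all pairs, and
#' `varS = [n(n-1)(2n+5) - sum_g t_g(t_g-1)(2t_g+5)] / 18` where the sum
#' runs over groups of tied values of size `t_g`.
#'
#' @param x numeric series; missing values are removed with order preserved.
#' @return A list with integer `S`, `varS` and the effective length `n`.
#' @export
mk_statistic <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("series too short: need at least 4 finite values",
                  call. = FALSE)
  # S via rank counts: sum over j of (#x_i < x_j) - (#x_i > x_j), i < j
  s <- 0L
  for (j in 2:n) {
    d <- x[j] - x[1:(j - 1)]
    s <- s + sum(d > 0) - sum(d < 0)
  }
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  list(S = as.integer(s), varS = var_s, n = n)
}

#' Sen's slope estimator
#'
#' The median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)`, `i < j`.
#' Robust to outliers and exact for noiseless linear series. Pairs with
#' duplicate times are rejected as malformed input.
#'
#' @param x numeric series.
#' @param t time values (default the series indices).
#' @return The slope in units of `x` per unit `t`.
#' @export
sens_slope <- function(x, t = seq_along(x)) {
  ok <- !is.na(x)
  x <- x[ok]; t <- t[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate time values", call. = FALSE)
  pairs <- utils::combn(n, 2)
  slopes <- (x[pairs[2, ]] - x[pairs[1, ]]) / (t[pairs[2, ]] - t[pairs[1, ]])
  stats::median(slopes)
}

mk_z <- function(S, varS) {
  if (varS <= 0) return(0)
  if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
}

#' Mann-Kendall trend test
#'
#' Two-sided nonparametric test of the null hypothesis of no monotone
#' trend. The normal score uses the standard continuity correction,
#' `Z = (S -/+ 1)/sqrt(varS)`; Kendall's tau is tie-adjusted
#' (`tau = S / sqrt(D (D - T))` with `D = n(n-1)/2` and `T` the tied-pair
#' count — with time untied this is tau-b). A constant series gives
#' `S = 0`, `p = 1`.
#'
#' @param x numeric series (at least 4 finite values).
#' @param alpha two-sided significance level.
#' @param t time values for the Sen's slope (default indices).
#' @return An object of class `trend_result`: list with `n`, `S`, `varS`,
#'   `Z`, `p`, `tau`, `sen_slope`, `significant`, `alpha`, `method`.
#' @export
mk_test <- function(x, alpha = 0.05, t = seq_along(x)) {
  ok <- !is.na(x)
  st <- mk_statistic(x[ok])
  n <- st$n
  z <- mk_z(st$S, st$varS)
  p <- if (st$varS <= 0) 1 else 2 * stats::pnorm(-abs(z))
  D <- n * (n - 1) / 2
  ties <- table(x[ok]); ties <- ties[ties > 1]
  T_ties <- sum(ties * (ties - 1) / 2)
  tau <- if (D - T_ties > 0) st$S / sqrt(D * (D - T_ties)) else 0
  slope <- sens_slope(x[ok], t[ok])
  structure(list(n = n, S = st$S, varS = st$varS, Z = z, p = p, tau = tau,
                 sen_slope = slope, significant = p < alpha, alpha = alpha,
                 method = "mk"),
            class = "trend_result")
}

#' Trend-free pre-whitening transform
#'
#' Removes lag-1 autocorrelation from a series without destroying its
#' trend, so that the Mann-Kendall test keeps its nominal size under serial
#' correlation: (1) estimate the trend as the Sen's slope `beta`;
#' (2) detrend; (3) estimate the lag-1 autocorrelation of the residuals
#' and apply the Kendall-type small-sample bias correction for a series
#' adjusted for mean and trend, `r1c = (n r1 + 2) / (n - 4)` (the raw
#' residual estimate is biased low, which would leave the series
#' under-whitened); (4) if the raw `r1` passes the whitening rule, remove
#' the AR(1) component (`y'_t = y_t - r1c y_(t-1)`, shortening the series
#' by one); (5) restore the trend at the whitened scale,
#' `out_t = y'_t + beta (1 - r1c) t`, on the original time indices
#' `2..n` — equivalent to pre-whitening the original series directly, so a
#' trend passes through the same filter as the noise and the test keeps
#' its nominal size under the autocorrelated null.
#'
#' With `whiten = "auto"` the AR(1) removal is applied only when
#' `|r1| >= 1.645 / sqrt(n)` (the two-sided 10% normal bound); `"always"`
#' and `"never"` override the gate. A residual series with zero variance
#' (e.g. a noiseless linear input) has `r1` treated as 0 and passes through
#' unchanged.
#'
#' @param x numeric series, at least 10 finite values.
#' @param whiten whitening rule, `"auto"`, `"always"` or `"never"`.
#' @return A list: `series` (the whitened, trend-preserving series), `t`
#'   (its time indices into the input), `r1` (raw residual lag-1
#'   autocorrelation), `r1_used` (bias-corrected value applied), `beta`,
#'   `whitened` (logical).
#' @export
tfpw_transform <- function(x, whiten = c("auto", "always", "never")) {
  whiten <- match.arg(whiten)
  ok <- !is.na(x)
  x <- x[ok]
  n <- length(x)
  if (n < 10) stop("series too short for TFPW: need at least 10 values",
                   call. = FALSE)
  tt <- seq_len(n)
  beta <- sens_slope(x, tt)
  y <- x - beta * tt
  yc <- y - mean(y)
  denom <- sum(yc^2)
  r1 <- if (denom > 0) sum(yc[-n] * yc[-1]) / denom else 0
  r1c <- min((n * r1 + 2) / (n - 4), 0.99)
  do_whiten <- switch(whiten,
                      auto = abs(r1) >= 1.645 / sqrt(n),
                      always = TRUE,
                      never = FALSE)
  if (do_whiten && denom > 0) {
    yp <- y[-1] - r1c * y[-n]
    tp <- tt[-1]
    out <- yp + beta * (1 - r1c) * tp
  } else {
    do_whiten <- FALSE
    out <- x
    tp <- tt
    r1c <- r1
  }
  list(series = out, t = tp, r1 = r1, r1_used = r1c, beta = beta,
       whitened = do_whiten)
}

#' Trend-free pre-whitened Mann-Kendall test
#'
#' Applies [tfpw_transform()] and runs [mk_test()] on the blended series.
#' The reported Sen's slope is computed from the original series: the slope
#' is a property of the data and pre-whitening only repairs the inference.
#'
#' @inheritParams tfpw_transform
#' @param alpha two-sided significance level.
#' @return A `trend_result` with `method = "tfpw-mk"` and the transform's
#'   `r1` and `whitened` flag attached.
#' @export
tfpw_mk_test <- function(x, alpha = 0.05,
                         whiten = c("auto", "always", "never")) {
  tw <- tfpw_transform(x, whiten)
  res <- mk_test(tw$series, alpha = alpha, t = tw$t)
  res$sen_slope <- sens_slope(x[!is.na(x)])
  res$method <- "tfpw-mk"
  res$r1 <- tw$r1
  res$whitened <- tw$whitened
  res
}

#' Magnitude change over a period as a percentage of the mean
#'
#' `100 * slope * n / mean`: the Sen's slope times the period length,
#' expressed relative to the series mean.
#'
#' @param slope Sen's slope, units per year.
#' @param n period length, years.
#' @param mean series mean (nonzero).
#' @return Percent change.
#' @export
percentage_change <- function(slope, n, mean) {
  if (mean == 0) stop("undefined percentage change: mean is zero",
                      call. = FALSE)
  100 * slope * n / mean
}

#' Trend test on a series tibble
#'
#' Data-frame-first wrapper: runs [mk_test()] or [tfpw_mk_test()] on the
#' `value` column of a series tibble (as produced by
#' [efficiency_series()]) and returns the fit.
#'
#' @param data a tibble with columns `time` and `value`.
#' @param method `"tfpw-mk"` (default) or `"mk"`.
#' @param alpha two-sided significance level.
#' @param ... passed to the underlying test.
#' @return A `trend_result`.
#' @export
trend_test <- function(data, method = c("tfpw-mk", "mk"), alpha = 0.05,
                       ...) {
  method <- match.arg(method)
  stopifnot(all(c("time", "value") %in% names(data)))
  o <- order(data$time)
  x <- data$value[o]
  res <- if (method == "mk") mk_test(x, alpha = alpha, ...) else
    tfpw_mk_test(x, alpha = alpha, ...)
  # slope per year on the real time axis
  res$sen_slope <- sens_slope(x[!is.na(x)], data$time[o][!is.na(x)])
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat("<trend_result> ", x$method, "\n", sep = "")
  cat(sprintf("  n = %d, S = %d, varS = %.3f, Z = %.4f, p = %.4g\n",
              x$n, x$S, x$varS, x$Z, x$p))
  cat(sprintf("  tau = %.4f, Sen's slope = %.6g / yr, significant at %.2g: %s\n",
              x$tau, x$sen_slope, x$alpha,
              if (x$significant) "yes" else "no"))
  invisible(x)
}

#' Tidy a trend test result
#'
#' @param x a `trend_result`.
#' @param ... unused.
#' @return One-row tibble with the test statistics.
#' @method tidy trend_result
#' @export
tidy.trend_result <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, S = x$S, varS = x$varS,
                 Z = x$Z, p.value = x$p, tau = x$tau,
                 sen_slope = x$sen_slope, significant = x$significant)
}

#' Glance at a trend test result
#'
#' @param x a `trend_result`.
#' @param ... unused.
#' @return One-row tibble: `p.value`, `sen_slope`, `significant`.
#' @method glance trend_result
#' @export
glance.trend_result <- function(x, ...) {
  tibble::tibble(p.value = x$p, sen_slope = x$sen_slope,
                 significant = x$significant)
}
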