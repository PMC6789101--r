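#' Compare a modeled WUE series against a reference product
#'
#' Aligns the two series on a window of years, reports the mean absolute
#' error and mean bias (model minus reference), and runs the pre-whitened
#' Mann-Kendall test on each series so diverging trend conclusions (e.g. a
#' significant modeled decline against a flat observational product) are
#' visible side by side.
#'
#' @param model_series tibble with `time`, `value`: the model's global WUE
#'   (conventionally from the varying-climate scenario SG1).
#' @param reference_series tibble with `time`, `value`: the reference WUE.
#' @param window years to compare over (default 1982:2008, 27 values).
#' @param alpha significance level for the trend tests.
#' @param model_name label for the report.
#' @return A list of class `comparison_report`: `model`, `window`, `mae`,
#'   `bias`, `model_trend`, `reference_trend`.
#' @export
compare_to_reference <- function(model_series, reference_series,
                                 window = 1982:2008, alpha = 0.05,
                                 model_name = "model") {
  for (s in list(model_series, reference_series)) {
    if (!all(window %in% s$time)) {
      stop("window not covered by both series", call. = FALSE)
    }
  }
  m <- model_series$value[match(window, model_series$time)]
  r <- reference_series$value[match(window, reference_series$time)]
  structure(
    list(model = model_name, window = window,
         mae = mean(abs(m - r)), bias = mean(m - r),
         model_trend = tfpw_mk_test(m, alpha = alpha),
         reference_trend = tfpw_mk_test(r, alpha = alpha)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$model, ", ", min(x$window), "-",
      max(x$window), "\n", sep = "")
  cat(sprintf("  MAE = %.4f, bias = %+.4f\n", x$mae, x$bias))
  cat(sprintf("  model trend:     p = %.3g, slope = %+.4g%s\n",
              x$model_trend$p, x$model_trend$sen_slope,
              if (x$model_trend$significant) " *" else ""))
  cat(sprintf("  reference trend: p = %.3g, slope = %+.4g%s\n",
              x$reference_trend$p, x$reference_trend$sen_slope,
              if (x$reference_trend$significant) " *" else ""))
  invisible(x)
}

#' Glance at a comparison report
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return One-row tibble with MAE, bias and both trend p-values.
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(model = x$model, mae = x$mae, bias = x$bias,
                 model_p = x$model_trend$p,
                 model_significant = x$model_trend$significant,
                 reference_p = x$reference_trend$p,
                 reference_significant = x$reference_trend$significant)
}

monthly_parts <- function(time) {
  year <- floor(time + 1e-6)
  month <- as.integer(round((time - year) * 12)) + 1L
  list(year = year, month = month)
}

#' Growing-season LAI series north of the nitrogen-limited boundary
#'
#' The nitrogen-deposition LAI diagnostic: monthly LAI from the
#' all-drivers scenario is restricted to cells with center latitude north
#' of `lat_min` (strictly; these are the nitrogen-limited areas) and to the
#' growing-season months (April-October), then averaged — equal month
#' weights, cosine-latitude cell weights — into one annual series. The
#' BG1 - SG3 difference isolates the nitrogen-deposition effect; the
#' procedure applies only to carbon-nitrogen models with prognostic LAI.
#'
#' @param ensemble a [scenario_ensemble()] (carbon-nitrogen, dynamic LAI).
#' @param months months to include (default 4:10).
#' @param lat_min southern boundary, degrees north (default 25).
#' @return A tibble with columns `time`, `bg1`, `sg3`, `effect`
#'   (`bg1 - sg3`).
#' @export
lai_ndep_series <- function(ensemble, months = 4:10, lat_min = 25) {
  if (!ensemble$has_nitrogen) {
    stop("not applicable: ", ensemble$model_name, " is carbon-only",
         call. = FALSE)
  }
  if (!ensemble$lai_dynamic) {
    stop("not applicable: ", ensemble$model_name,
         " LAI is not dynamically estimated", call. = FALSE)
  }
  one <- function(scenario) {
    lai <- ensemble$fields[[scenario]][["lai"]]
    if (is.null(lai)) stop("quantity unavailable: no LAI for ", scenario,
                           call. = FALSE)
    mp <- monthly_parts(lai$time)
    keep_t <- mp$month %in% months
    sub <- lai
    sub$values <- lai$values[, , keep_t, drop = FALSE]
    sub$time <- lai$time[keep_t]
    s <- area_weighted_mean(sub, band_scope(lat_min, 90))
    yr <- monthly_parts(s$time)$year
    agg <- tapply(s$value, yr, mean)  # equal month weights within a year
    tibble::tibble(time = as.numeric(names(agg)), value = as.numeric(agg))
  }
  s_bg1 <- one("BG1")
  s_sg3 <- one("SG3")
  tibble::tibble(time = s_bg1$time, bg1 = s_bg1$value, sg3 = s_sg3$value,
                 effect = s_bg1$value - s_sg3$value)
}
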