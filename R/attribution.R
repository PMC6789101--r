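# differencing pairs that isolate each driver in the factorial design
DRIVER_PAIRS <- list(climate = c("SG1", "RG1"),
                     co2 = c("SG3", "SG2"),
                     ndep = c("BG1", "SG3"))

#' Per-year effect of one driver on a quantity
#'
#' Factorial differencing: the climate effect is SG1 - RG1, the CO2
#' fertilization effect SG3 - SG2 and the nitrogen-deposition effect
#' BG1 - SG3 (carbon-nitrogen models only). `driver = "combined"` is the
#' net change of the all-drivers scenario relative to its first year (see
#' [net_change()]). For `wue`/`cue` the efficiency is computed per scenario
#' first and the efficiencies are differenced, not the fluxes.
#'
#' @param ensemble a [scenario_ensemble()].
#' @param driver `"climate"`, `"co2"`, `"ndep"` or `"combined"`.
#' @param quantity response variable (see [efficiency_series()]).
#' @param scope aggregation scope.
#' @param config an [eco_config()].
#' @return A tibble with columns `time`, `value` and attributes `driver`,
#'   `quantity` (class `driver_effect`).
#' @export
driver_effect <- function(ensemble, driver, quantity, scope = "global",
                          config = eco_config()) {
  if (driver == "combined") return(net_change(ensemble, quantity, scope,
                                              config))
  pair <- DRIVER_PAIRS[[driver]]
  if (is.null(pair)) stop("unknown driver: ", driver, call. = FALSE)
  if (driver == "ndep" && !ensemble$has_nitrogen) {
    stop("driver unavailable for model type: ", ensemble$model_name,
         " is carbon-only", call. = FALSE)
  }
  hi <- efficiency_series(ensemble, pair[1], quantity, scope, config)
  lo <- efficiency_series(ensemble, pair[2], quantity, scope, config)
  out <- new_series(hi$time, hi$value - lo$value, quantity,
                    attr(hi, "units"), scope)
  attr(out, "driver") <- driver
  class(out) <- c("driver_effect", class(out))
  out
}

#' Net change of the all-drivers scenario relative to the first year
#'
#' The combined effect of climate, CO2 and nitrogen deposition: the BG1
#' series (SG3 for carbon-only models) minus its value in the baseline
#' year, so the series starts at exactly zero.
#'
#' @inheritParams driver_effect
#' @param baseline_year reference year (default the first year present).
#' @return A `driver_effect` tibble with `driver = "combined"`.
#' @export
net_change <- function(ensemble, quantity, scope = "global",
                       config = eco_config(), baseline_year = NULL) {
  sc <- maximal_scenario(ensemble)
  s <- efficiency_series(ensemble, sc, quantity, scope, config)
  if (is.null(baseline_year)) baseline_year <- min(s$time)
  i0 <- match(baseline_year, s$time)
  if (is.na(i0)) stop("baseline year ", baseline_year,
                      " absent from time axis", call. = FALSE)
  out <- new_series(s$time, s$value - s$value[i0], quantity,
                    attr(s, "units"), scope)
  attr(out, "driver") <- "combined"
  class(out) <- c("driver_effect", class(out))
  out
}

#' Percent contribution of a driver effect
#'
#' The mean of the effect series as a percentage of the mean of the
#' all-drivers scenario series (BG1 for carbon-nitrogen models, SG3 for
#' carbon-only), over the same years and scope.
#'
#' @param effect a `driver_effect` tibble from [driver_effect()].
#' @param ensemble the [scenario_ensemble()] the effect came from.
#' @param years years to average over (default all years in the effect).
#' @param config an [eco_config()].
#' @return Percent contribution (signed).
#' @export
percent_contribution <- function(effect, ensemble, years = NULL,
                                 config = eco_config()) {
  if (is.null(years)) years <- effect$time
  denom <- efficiency_series(ensemble, maximal_scenario(ensemble),
                             attr(effect, "quantity"),
                             attr(effect, "scope"), config)
  num <- mean(effect$value[effect$time %in% years], na.rm = TRUE)
  den <- mean(denom$value[denom$time %in% years], na.rm = TRUE)
  if (!is.finite(den) || den == 0) {
    stop("undefined contribution: denominator mean is zero", call. = FALSE)
  }
  100 * num / den
}

#' Percent increase between two years of a series
#'
#' `100 * (x[y1] - x[y0]) / x[y0]`.
#'
#' @param data a tibble with columns `time` and `value`.
#' @param y0,y1 start and end years (both must be present).
#' @return Percent increase.
#' @export
percent_increase <- function(data, y0 = 1901, y1 = 2010) {
  i0 <- match(y0, data$time); i1 <- match(y1, data$time)
  if (is.na(i0) || is.na(i1)) stop("year absent from series", call. = FALSE)
  if (data$value[i0] == 0) stop("undefined percent increase: value at ",
                                y0, " is zero", call. = FALSE)
  100 * (data$value[i1] - data$value[i0]) / data$value[i0]
}

applicable_drivers <- function(ensemble) {
  if (ensemble$has_nitrogen) c("climate", "co2", "ndep") else
    c("climate", "co2")
}

# per-cell mean-over-period of the scenario difference for one driver,
# and of the all-drivers scenario (the contribution denominator)
cell_period_means <- function(ensemble, quantity, period, config) {
  get_mean <- function(scenario) {
    f <- efficiency_field(ensemble, scenario, quantity, config)
    keep <- f$time %in% period
    apply(f$values[, , keep, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  }
  drivers <- applicable_drivers(ensemble)
  eff <- lapply(stats::setNames(drivers, drivers), function(d) {
    pair <- DRIVER_PAIRS[[d]]
    get_mean(pair[1]) - get_mean(pair[2])
  })
  list(effects = eff, denom = get_mean(maximal_scenario(ensemble)))
}

#' Dominant-driver map
#'
#' For each land cell, the driver (climate, CO2 fertilization or nitrogen
#' deposition) whose percent contribution to the quantity over the period
#' has the largest absolute value. Cells where every contribution is below
#' `threshold` (in percentage points) are labeled `"none"`; exact ties are
#' broken in the fixed order climate > co2 > ndep. The nitrogen label is
#' impossible for carbon-only models.
#'
#' @param ensemble a [scenario_ensemble()].
#' @param quantity response variable.
#' @param period years to average over (default 1982:2008).
#' @param config an [eco_config()]; `config$dominance_threshold` sets the
#'   `"none"` cutoff.
#' @return A list of class `dominant_driver_map`: `label` (character
#'   lat x lon matrix, `NA` over ocean), `contribution` (named list of
#'   per-driver percent-contribution matrices), plus `lat`, `lon`,
#'   `quantity`, `period`.
#' @export
dominant_driver_map <- function(ensemble, quantity, period = 1982:2008,
                                config = eco_config()) {
  cpm <- cell_period_means(ensemble, quantity, period, config)
  drivers <- names(cpm$effects)
  contrib <- lapply(cpm$effects, function(e) 100 * e / cpm$denom)
  nlat <- nrow(cpm$denom); nlon <- ncol(cpm$denom)
  label <- matrix(NA_character_, nlat, nlon)
  mask <- ensemble$fields[[maximal_scenario(ensemble)]][[1]]$land_mask
  for (idx in which(mask)) {
    vals <- vapply(drivers, function(d) contrib[[d]][idx], numeric(1))
    vals[!is.finite(vals)] <- 0
    if (all(abs(vals) < config$dominance_threshold)) {
      label[idx] <- "none"
    } else {
      label[idx] <- drivers[which.max(abs(vals))]  # ties: first in order
    }
  }
  f <- ensemble$fields[[maximal_scenario(ensemble)]][[1]]
  structure(list(label = label, contribution = contrib, lat = f$lat,
                 lon = f$lon, land_mask = mask, quantity = quantity,
                 period = period, model = ensemble$model_name),
            class = "dominant_driver_map")
}

#' @export
print.dominant_driver_map <- function(x, ...) {
  cat("<dominant_driver_map> ", x$quantity, ", ", x$model, ", ",
      min(x$period), "-", max(x$period), "\n", sep = "")
  print(table(x$label[x$land_mask]))
  invisible(x)
}

#' Tidy a dominant-driver map
#'
#' @param x a `dominant_driver_map`.
#' @param ... unused.
#' @return A tibble with `lat`, `lon`, `label` and per-driver contribution
#'   columns (land cells only).
#' @method tidy dominant_driver_map
#' @export
tidy.dominant_driver_map <- function(x, ...) {
  idx <- which(x$land_mask, arr.ind = TRUE)
  out <- tibble::tibble(lat = x$lat[idx[, 1]], lon = x$lon[idx[, 2]],
                        label = x$label[x$land_mask])
  for (d in names(x$contribution)) {
    out[[paste0("pc_", d)]] <- x$contribution[[d]][x$land_mask]
  }
  out
}

#' Write a dominant-driver map as a categorical NetCDF grid
#'
#' Integer codes with `flag_values`/`flag_meanings` attributes
#' (0 none, 1 climate, 2 co2, 3 ndep; ocean is the fill value).
#'
#' @param map a [dominant_driver_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dominant_map <- function(map, path) {
  codes <- c(none = 0L, climate = 1L, co2 = 2L, ndep = 3L)
  vals <- matrix(-1L, nrow(map$label), ncol(map$label))
  vals[map$land_mask] <- codes[map$label[map$land_mask]]
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", map$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", map$lon)
  v <- ncdf4::ncvar_def("dominant_driver", "1", list(dim_lat, dim_lon),
                        missval = -1L, prec = "integer")
  nc <- ncdf4::nc_create(path, list(v))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v, vals)
  ncdf4::ncatt_put(nc, v, "flag_values", "0 1 2 3")
  ncdf4::ncatt_put(nc, v, "flag_meanings", "none climate co2 ndep")
  invisible(path)
}

#' Per-model, per-driver trend and contribution summary
#'
#' For each model and each applicable driver (plus the combined net
#' change), runs the pre-whitened Mann-Kendall test on the global effect
#' series and reports the Sen's slope, the percentage change over the
#' period and the percent contribution. Water-use-efficiency rows are
#' omitted for models lacking ET; the quantity is then reported for the
#' remaining models without error.
#'
#' @param ensembles list of [scenario_ensemble()]s.
#' @param quantity response variable.
#' @param scope aggregation scope.
#' @param config an [eco_config()].
#' @return A tibble: one row per (model, driver).
#' @export
ensemble_summary <- function(ensembles, quantity, scope = "global",
                             config = eco_config()) {
  proto <- tibble::tibble(model = character(), has_nitrogen = logical(),
                          quantity = character(), driver = character(),
                          sen_slope = numeric(), p.value = numeric(),
                          significant = logical(), pct_change = numeric(),
                          pct_contribution = numeric())
  rows <- purrr::map_dfr(ensembles, function(ens) {
    if (quantity == "wue" && !"et" %in% model_variables(ens)) {
      return(tibble::tibble())
    }
    drivers <- c(applicable_drivers(ens), "combined")
    purrr::map_dfr(drivers, function(d) {
      eff <- driver_effect(ens, d, quantity, scope, config)
      tr <- trend_test(eff, method = "tfpw-mk", alpha = config$alpha)
      full <- efficiency_series(ens, maximal_scenario(ens), quantity,
                                scope, config)
      pc <- if (d == "combined") NA_real_ else
        percent_contribution(eff, ens, config = config)
      pct <- percentage_change(tr$sen_slope, length(full$time),
                               mean(full$value, na.rm = TRUE))
      tibble::tibble(model = ens$model_name,
                     has_nitrogen = ens$has_nitrogen,
                     quantity = quantity, driver = d,
                     sen_slope = tr$sen_slope, p.value = tr$p,
                     significant = tr$significant,
                     pct_change = pct, pct_contribution = pc)
    })
  })
  dplyr::bind_rows(proto, rows)
}
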