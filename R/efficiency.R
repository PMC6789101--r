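#' Water-use efficiency field: GPP / ET
#'
#' WUE is the carbon gained per unit water lost, gC/kgH2O. Cells where ET is
#' below `et_floor` are set missing rather than producing near-infinite
#' ratios (deserts, ice).
#'
#' @param gpp GPP [grid_field()], gC m-2 yr-1.
#' @param et ET [grid_field()], kgH2O m-2 yr-1.
#' @param et_floor minimum ET, kgH2O m-2 yr-1.
#' @return A WUE [grid_field()].
#' @export
compute_wue <- function(gpp, et, et_floor = 10) {
  out <- field_binop(gpp, et, function(g, e) {
    ifelse(!is.na(e) & e < et_floor, NA_real_, g / e)
  })
  out$variable <- "wue"
  out$units <- canonical_units("wue")
  out
}

#' Carbon-use efficiency field: NPP / GPP
#'
#' CUE is the fraction of assimilated carbon retained as net production.
#' Cells with GPP below `gpp_floor` are set missing. Values outside `[0, 1]`
#' (possible when a model produces negative NPP) are retained, not clipped
#' — clipping would bias trend statistics — and counted by [cue_qc()].
#'
#' @param npp NPP [grid_field()], gC m-2 yr-1.
#' @param gpp GPP [grid_field()], gC m-2 yr-1.
#' @param gpp_floor minimum GPP, gC m-2 yr-1.
#' @return A CUE [grid_field()].
#' @export
compute_cue <- function(npp, gpp, gpp_floor = 1) {
  out <- field_binop(npp, gpp, function(n, g) {
    ifelse(!is.na(g) & g < gpp_floor, NA_real_, n / g)
  })
  out$variable <- "cue"
  out$units <- canonical_units("cue")
  out
}

#' QC report for a CUE field
#'
#' @param cue a CUE [grid_field()].
#' @return A list: counts of finite values, values below 0 and above 1, and
#'   the fraction outside `[0, 1]`.
#' @export
cue_qc <- function(cue) {
  v <- cue$values[!is.na(cue$values)]
  list(n = length(v),
       n_below_0 = sum(v < 0),
       n_above_1 = sum(v > 1),
       frac_outside = if (length(v)) mean(v < 0 | v > 1) else 0)
}

# resolve a scope argument into a lat x lon logical matrix of included cells
scope_mask <- function(field, scope) {
  m <- field$land_mask
  if (identical(scope, "global")) return(m)
  if (is.list(scope) && identical(scope$type, "band")) {
    keep <- field$lat > scope$lat_min & field$lat <= scope$lat_max
    m[!keep, ] <- FALSE
    return(m)
  }
  if (is.list(scope) && identical(scope$type, "cell")) {
    mm <- matrix(FALSE, nrow(m), ncol(m))
    mm[scope$i, scope$j] <- m[scope$i, scope$j]
    return(mm)
  }
  stop("unknown scope; use \"global\", band_scope() or cell_scope()",
       call. = FALSE)
}

#' Latitude-band scope
#'
#' Cells with center latitude in `(lat_min, lat_max]`; the lower bound is
#' exclusive so "north of 25" excludes a cell centered exactly at 25.
#'
#' @param lat_min,lat_max band bounds, degrees north.
#' @return A scope object for [area_weighted_mean()].
#' @export
band_scope <- function(lat_min, lat_max = 90) {
  list(type = "band", lat_min = lat_min, lat_max = lat_max)
}

#' Single-cell scope
#'
#' @param i,j latitude / longitude indices.
#' @return A scope object for [area_weighted_mean()].
#' @export
cell_scope <- function(i, j) list(type = "cell", i = i, j = j)

#' Area-weighted mean series of a gridded field
#'
#' For each time step, the mean over unmasked, non-missing land cells in the
#' scope, weighted by the cosine of latitude (cell area on an equal-angle
#' grid). Missing cells are excluded from numerator and denominator alike.
#'
#' @param field a [grid_field()].
#' @param scope `"global"`, a [band_scope()] or a [cell_scope()].
#' @return A tibble with columns `time` and `value` (class
#'   `efficiency_series`, carrying `quantity`, `units` and `scope`
#'   attributes).
#' @export
area_weighted_mean <- function(field, scope = "global") {
  m <- scope_mask(field, scope)
  idx <- which(m)
  if (!length(idx)) stop("empty aggregation domain", call. = FALSE)
  w_lat <- cos(field$lat * pi / 180)
  w <- matrix(rep(w_lat, length(field$lon)), nrow = length(field$lat))[idx]
  vals <- vapply(seq_along(field$time), function(k) {
    x <- field$values[, , k][idx]
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * x[ok]) / sum(w[ok])
  }, numeric(1))
  new_series(field$time, vals, quantity = field$variable,
             units = field$units, scope = scope)
}

new_series <- function(time, value, quantity, units, scope = "global") {
  out <- tibble::tibble(time = time, value = value)
  attr(out, "quantity") <- quantity
  attr(out, "units") <- units
  attr(out, "scope") <- scope
  class(out) <- c("efficiency_series", class(out))
  out
}

# area-weighted total (numerator of the mean); shared missing pattern assumed
weighted_series <- function(field, scope) {
  area_weighted_mean(field, scope)
}

#' Aggregate-then-divide and divide-then-aggregate efficiency series
#'
#' An efficiency ratio over a region can be formed two ways: divide the
#' area-weighted mean fluxes (`ratio_of_means`, robust to near-zero
#' denominators and the pipeline default) or average the per-cell ratios
#' (`mean_of_ratios`). The two differ whenever the ratio covaries spatially
#' with the denominator; both are returned for sensitivity analysis.
#'
#' @param num numerator [grid_field()] (GPP for WUE, NPP for CUE).
#' @param den denominator [grid_field()] (ET for WUE, GPP for CUE).
#' @param scope aggregation scope (see [area_weighted_mean()]).
#' @param floor denominator floor applied in the per-cell ratio branch.
#' @param quantity label for the resulting series.
#' @return A tibble with columns `time`, `ratio_of_means`, `mean_of_ratios`.
#' @export
ratio_of_means_vs_mean_of_ratios <- function(num, den, scope = "global",
                                             floor = 0, quantity = "ratio") {
  check_same_grid(num, den)
  rom_num <- area_weighted_mean(num, scope)
  rom_den <- area_weighted_mean(den, scope)
  ratio_field <- field_binop(num, den, function(a, b) {
    ifelse(!is.na(b) & b < floor, NA_real_, a / b)
  })
  mor <- area_weighted_mean(ratio_field, scope)
  tibble::tibble(time = rom_num$time,
                 ratio_of_means = rom_num$value / rom_den$value,
                 mean_of_ratios = mor$value)
}

#' Aggregated efficiency series for one scenario of a model
#'
#' Computes the requested quantity for one scenario and reduces it to an
#' annual series at the given scope. For `wue` and `cue` the default forms
#' the ratio of area-weighted mean fluxes (aggregate-then-divide); set
#' `aggregation = "mean_of_ratios"` to average per-cell ratios instead.
#' Plain variables are area-weighted means.
#'
#' @param ensemble a [scenario_ensemble()].
#' @param scenario scenario code.
#' @param quantity one of `wue`, `cue`, `gpp`, `npp`, `ra`, `et`, `lai`,
#'   `soil_moisture`, `soil_temperature`.
#' @param scope aggregation scope.
#' @param config an [eco_config()] (floors, aggregation mode).
#' @return An `efficiency_series` tibble (`time`, `value`).
#' @export
efficiency_series <- function(ensemble, scenario, quantity,
                              scope = "global", config = eco_config()) {
  fl <- ensemble$fields[[scenario]]
  if (is.null(fl)) stop("scenario ", scenario, " not available for model ",
                        ensemble$model_name, call. = FALSE)
  need <- switch(quantity, wue = c("gpp", "et"), cue = c("npp", "gpp"),
                 quantity)
  missing_vars <- setdiff(need, names(fl))
  if (length(missing_vars)) {
    stop("quantity unavailable: model ", ensemble$model_name, " lacks ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (quantity == "wue") {
    if (config$aggregation == "ratio_of_means") {
      g <- area_weighted_mean(fl$gpp, scope)
      e <- area_weighted_mean(fl$et, scope)
      new_series(g$time, g$value / e$value, "wue", canonical_units("wue"),
                 scope)
    } else {
      area_weighted_mean(compute_wue(fl$gpp, fl$et, config$et_floor), scope)
    }
  } else if (quantity == "cue") {
    if (config$aggregation == "ratio_of_means") {
      n <- area_weighted_mean(fl$npp, scope)
      g <- area_weighted_mean(fl$gpp, scope)
      new_series(n$time, n$value / g$value, "cue", canonical_units("cue"),
                 scope)
    } else {
      area_weighted_mean(compute_cue(fl$npp, fl$gpp, config$gpp_floor),
                         scope)
    }
  } else {
    area_weighted_mean(fl[[quantity]], scope)
  }
}

#' Per-cell efficiency field for one scenario
#'
#' @inheritParams efficiency_series
#' @return A [grid_field()] of the requested quantity.
#' @export
efficiency_field <- function(ensemble, scenario, quantity,
                             config = eco_config()) {
  fl <- ensemble$fields[[scenario]]
  if (is.null(fl)) stop("scenario ", scenario, " not available for model ",
                        ensemble$model_name, call. = FALSE)
  switch(quantity,
    wue = {
      if (!all(c("gpp", "et") %in% names(fl)))
        stop("quantity unavailable: model ", ensemble$model_name,
             " lacks et", call. = FALSE)
      compute_wue(fl$gpp, fl$et, config$et_floor)
    },
    cue = compute_cue(fl$npp, fl$gpp, config$gpp_floor),
    {
      if (!quantity %in% names(fl))
        stop("quantity unavailable: model ", ensemble$model_name, " lacks ",
             quantity, call. = FALSE)
      fl[[quantity]]
    })
}
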