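#' Write a gridded field to CF-style NetCDF
#'
#' Dimensions `lat`, `lon`, `time`; the data variable carries `units` and
#' `_FillValue` attributes and an explicit integer `land_mask` variable.
#' Output is deterministic for a fixed input (no timestamps are written).
#'
#' @param field a [grid_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  fill <- 1e20
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_time <- ncdf4::ncdim_def("time", "year", field$time, unlim = FALSE)
  var_main <- ncdf4::ncvar_def(field$variable, field$units,
                               list(dim_lat, dim_lon, dim_time),
                               missval = fill, prec = "double")
  var_mask <- ncdf4::ncvar_def("land_mask", "1", list(dim_lat, dim_lon),
                               prec = "integer")
  nc <- ncdf4::nc_create(path, list(var_main, var_mask))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vals <- field$values
  vals[is.na(vals)] <- fill
  ncdf4::ncvar_put(nc, var_main, vals)
  ncdf4::ncvar_put(nc, var_mask, ifelse(field$land_mask, 1L, 0L))
  ncdf4::ncatt_put(nc, var_main, "frequency", field$frequency)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.6")
  invisible(path)
}

#' Read a gridded field from CF-style NetCDF
#'
#' Reads one variable from a file with `lat`/`lon`/`time` coordinates and
#' normalizes its units to the canonical set (e.g. `kgC m-2 s-1` fluxes are
#' converted to gC m-2 yr-1 with a 365-day year). The land mask is taken from
#' an explicit `land_mask` variable when present, else inferred from the
#' missing pattern (cells missing at every time are ocean).
#'
#' @param path NetCDF file path.
#' @param variable name of the variable to read.
#' @return A [grid_field()] in canonical units.
#' @export
read_field <- function(path, variable) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!variable %in% names(nc$var)) {
    stop("variable not found: '", variable, "' in ", path, call. = FALSE)
  }
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  time <- as.numeric(ncdf4::ncvar_get(nc, "time"))
  check_monotonic(lat, "lat")
  check_monotonic(lon, "lon")
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  dim(vals) <- c(length(lat), length(lon), length(time))
  units_att <- ncdf4::ncatt_get(nc, variable, "units")
  if (!isTRUE(units_att$hasatt)) {
    stop("unknown units: variable '", variable, "' has no units attribute",
         call. = FALSE)
  }
  freq_att <- ncdf4::ncatt_get(nc, variable, "frequency")
  freq <- if (isTRUE(freq_att$hasatt)) freq_att$value else
    if (all(time == round(time))) "annual" else "monthly"
  mask <- NULL
  if ("land_mask" %in% names(nc$var)) {
    mask <- ncdf4::ncvar_get(nc, "land_mask", collapse_degen = FALSE)
    dim(mask) <- c(length(lat), length(lon))
    mask <- mask != 0
  }
  f <- grid_field(vals, lat, lon, time, variable = variable,
                  units = units_att$value, land_mask = mask,
                  frequency = freq)
  normalize_units(f)
}

#' Run configuration
#'
#' Bundles the knobs shared across the pipeline stages. All arguments have
#' the pipeline defaults; a YAML file with the same keys can be loaded with
#' [read_config()].
#'
#' @param years annual time axis (calendar years).
#' @param alpha two-sided significance level for trend tests.
#' @param et_floor minimum ET (kgH2O m-2 yr-1) below which WUE is missing.
#' @param gpp_floor minimum GPP (gC m-2 yr-1) below which CUE is missing.
#' @param window reference-comparison window (inclusive years).
#' @param dominance_threshold minimum absolute percent contribution for a
#'   cell to receive a driver label (percentage points).
#' @param seed integer random seed for the synthetic generator.
#' @param aggregation `"ratio_of_means"` (aggregate fluxes, then divide;
#'   default) or `"mean_of_ratios"` for WUE/CUE aggregation.
#' @return A list of class `eco_config`.
#' @export
eco_config <- function(years = 1901:2010, alpha = 0.05, et_floor = 10,
                       gpp_floor = 1, window = 1982:2008,
                       dominance_threshold = 0.1, seed = 1L,
                       aggregation = c("ratio_of_means", "mean_of_ratios")) {
  aggregation <- match.arg(aggregation)
  stopifnot(alpha > 0, alpha < 1, all(window %in% years))
  structure(list(years = years, alpha = alpha, et_floor = et_floor,
                 gpp_floor = gpp_floor, window = window,
                 dominance_threshold = dominance_threshold,
                 seed = as.integer(seed), aggregation = aggregation),
            class = "eco_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [eco_config()] defaults.
#' `years` and `window` may be given as `[first, last]` pairs.
#'
#' @param path YAML file.
#' @return An `eco_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(eco_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (k in c("years", "window")) {
    if (!is.null(raw[[k]]) && length(raw[[k]]) == 2) {
      raw[[k]] <- raw[[k]][1]:raw[[k]][2]
    }
  }
  do.call(eco_config, raw)
}

SCENARIOS <- c("RG1", "SG1", "SG2", "SG3", "BG1")
VARIABLES <- c("gpp", "npp", "ra", "et", "lai", "soil_moisture",
               "soil_temperature")

#' Construct a scenario ensemble for one model
#'
#' @param model_name model label.
#' @param has_nitrogen `TRUE` for carbon-nitrogen models (which have the BG1
#'   scenario), `FALSE` for carbon-only models (maximal scenario SG3).
#' @param fields named list `fields[[scenario]][[variable]]` of
#'   [grid_field()]s sharing one grid and annual time axis.
#' @param lai_dynamic whether the model's LAI is prognostic (satellite-forced
#'   LAI is excluded from the N-deposition LAI analysis).
#' @return An object of class `scenario_ensemble`.
#' @export
scenario_ensemble <- function(model_name, has_nitrogen, fields,
                              lai_dynamic = TRUE) {
  stopifnot(is.list(fields), all(names(fields) %in% SCENARIOS))
  if (!has_nitrogen && "BG1" %in% names(fields)) {
    stop("scenario inconsistent with model type: C-only model '", model_name,
         "' has BG1", call. = FALSE)
  }
  ref <- NULL
  for (sc in names(fields)) {
    for (v in names(fields[[sc]])) {
      f <- fields[[sc]][[v]]
      stopifnot(inherits(f, "grid_field"))
      if (f$frequency == "monthly") next  # monthly LAI has its own axis
      if (is.null(ref)) ref <- f
      if (!isTRUE(all.equal(ref$lat, f$lat)) ||
          !isTRUE(all.equal(ref$lon, f$lon)) ||
          !isTRUE(all.equal(ref$time, f$time))) {
        stop("inconsistent grid across scenarios of model '", model_name,
             "'", call. = FALSE)
      }
    }
  }
  # a variable is present for all scenarios that carry it, never partially
  structure(list(model_name = model_name, has_nitrogen = has_nitrogen,
                 fields = fields, lai_dynamic = lai_dynamic),
            class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat("<scenario_ensemble> ", x$model_name,
      if (x$has_nitrogen) " (C-N)" else " (C-only)", "\n", sep = "")
  for (sc in names(x$fields)) {
    cat("  ", sc, ": ", paste(names(x$fields[[sc]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Scenarios available to a model
#'
#' @param ensemble a [scenario_ensemble()].
#' @return Character vector of scenario codes.
#' @export
scenarios <- function(ensemble) names(ensemble$fields)

#' The model's maximal (all-drivers) scenario
#'
#' BG1 for carbon-nitrogen models, SG3 for carbon-only models.
#'
#' @param ensemble a [scenario_ensemble()].
#' @return Scenario code.
#' @export
maximal_scenario <- function(ensemble) {
  if (ensemble$has_nitrogen) "BG1" else "SG3"
}

#' Variables a model provides
#'
#' @param ensemble a [scenario_ensemble()].
#' @return Character vector of variable names present in any scenario.
#' @export
model_variables <- function(ensemble) {
  unique(unlist(lapply(ensemble$fields, names)))
}

#' Load a factorial ensemble from a directory tree
#'
#' Expects the layout `root/<model>/<scenario>/<variable>.nc` written by
#' [write_ensemble()]. Model metadata (`has_nitrogen`, `lai_dynamic`) is read
#' from `root/<model>/model.json` when present, else inferred: a model with a
#' BG1 directory is treated as carbon-nitrogen. Every (scenario, variable)
#' file on disk is loaded; nothing is silently dropped.
#'
#' @param root ensemble root directory.
#' @param config an [eco_config()] (reserved for future validation hooks).
#' @return A named list of [scenario_ensemble()]s, one per model directory.
#' @export
load_ensemble <- function(root, config = eco_config()) {
  models <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(models)) stop("no model directories under ", root, call. = FALSE)
  out <- lapply(models, function(m) {
    mdir <- file.path(root, m)
    meta_path <- file.path(mdir, "model.json")
    scs <- intersect(SCENARIOS, list.dirs(mdir, recursive = FALSE,
                                          full.names = FALSE))
    meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
      list(has_nitrogen = "BG1" %in% scs, lai_dynamic = TRUE)
    fields <- lapply(stats::setNames(scs, scs), function(sc) {
      ncs <- sort(list.files(file.path(mdir, sc), pattern = "\\.nc$"))
      vars <- sub("\\.nc$", "", ncs)
      lapply(stats::setNames(vars, vars), function(v) {
        read_field(file.path(mdir, sc, paste0(v, ".nc")), v)
      })
    })
    scenario_ensemble(m, isTRUE(meta$has_nitrogen), fields,
                      lai_dynamic = isTRUE(meta$lai_dynamic))
  })
  stats::setNames(out, models)
}

#' Write an ensemble to the directory layout read by [load_ensemble()]
#'
#' @param ensemble a [scenario_ensemble()].
#' @param root output root directory (created if needed).
#' @return The model directory, invisibly.
#' @export
write_ensemble <- function(ensemble, root) {
  mdir <- file.path(root, ensemble$model_name)
  for (sc in names(ensemble$fields)) {
    d <- file.path(mdir, sc)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (v in names(ensemble$fields[[sc]])) {
      write_field(ensemble$fields[[sc]][[v]], file.path(d, paste0(v, ".nc")))
    }
  }
  jsonlite::write_json(
    list(model_name = ensemble$model_name,
         has_nitrogen = ensemble$has_nitrogen,
         lai_dynamic = ensemble$lai_dynamic),
    file.path(mdir, "model.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(mdir)
}
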