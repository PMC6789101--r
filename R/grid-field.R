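#' Gridded field container
#'
#' A `grid_field` holds one variable on a lat x lon x time grid together with
#' its coordinates, units and a land mask. It is the atom of all file I/O and
#' of the efficiency and attribution computations. Values over ocean cells
#' (mask `FALSE`) are always `NA`.
#'
#' The time axis is annual (integer calendar years) or monthly; monthly time
#' is stored as decimal years `year + (month - 1)/12` so that a single
#' numeric coordinate round-trips through NetCDF exactly.
#'
#' @param values numeric array with dim `c(length(lat), length(lon),
#'   length(time))`; ocean cells must be `NA` at all times (they are masked
#'   on construction).
#' @param lat,lon cell-center coordinates, degrees north / degrees east,
#'   strictly monotonic.
#' @param time numeric time coordinate: integer years, or decimal years for
#'   monthly data.
#' @param variable variable name, one of
#'   `c("gpp", "npp", "ra", "et", "lai", "soil_moisture", "soil_temperature",
#'   "wue", "cue")`.
#' @param units units string; must be one of the recognized spellings for the
#'   variable (see [normalize_units()]).
#' @param land_mask logical matrix `length(lat)` x `length(lon)`; defaults to
#'   cells that are non-missing at at least one time.
#' @param frequency `"annual"` or `"monthly"`.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, lat, lon, time, variable, units,
                       land_mask = NULL, frequency = c("annual", "monthly")) {
  frequency <- match.arg(frequency)
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-d array (lat, lon, time)", call. = FALSE)
  }
  if (!identical(dim(values), c(length(lat), length(lon), length(time)))) {
    stop("array shape must equal (len(lat), len(lon), len(time))", call. = FALSE)
  }
  check_monotonic(lat, "lat")
  check_monotonic(lon, "lon")
  if (anyDuplicated(time)) stop("duplicate time steps", call. = FALSE)
  if (is.null(land_mask)) {
    land_mask <- apply(!is.na(values), c(1, 2), any)
  }
  storage.mode(land_mask) <- "logical"
  if (!identical(dim(land_mask), c(length(lat), length(lon)))) {
    stop("land_mask shape must equal (len(lat), len(lon))", call. = FALSE)
  }
  # enforce: ocean is missing at all times
  values[rep(!land_mask, length(time))] <- NA_real_
  structure(
    list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
         time = as.numeric(time), variable = variable, units = units,
         land_mask = land_mask, frequency = frequency),
    class = "grid_field"
  )
}

check_monotonic <- function(x, name) {
  d <- diff(x)
  if (length(x) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("malformed grid: coordinate `", name, "` is not strictly monotonic",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.grid_field <- function(x, ...) {
  cat("<grid_field> ", x$variable, " [", x$units, "]\n", sep = "")
  cat("  grid: ", length(x$lat), " x ", length(x$lon),
      ", land cells: ", sum(x$land_mask), "\n", sep = "")
  cat("  time: ", x$frequency, ", ", length(x$time), " steps (",
      format(min(x$time)), "..", format(max(x$time)), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

#' Canonical units for each variable
#'
#' Carbon fluxes (GPP, NPP, Ra) are expressed in gC m-2 yr-1,
#' evapotranspiration in kgH2O m-2 yr-1 (equivalently mm yr-1), LAI in
#' m2 m-2, soil moisture in kg m-2 and soil temperature in K.
#'
#' @param variable variable name.
#' @return The canonical units string.
#' @export
canonical_units <- function(variable) {
  u <- c(gpp = "gC m-2 yr-1", npp = "gC m-2 yr-1", ra = "gC m-2 yr-1",
         et = "kgH2O m-2 yr-1", lai = "m2 m-2",
         soil_moisture = "kg m-2", soil_temperature = "K",
         wue = "gC kgH2O-1", cue = "1")
  if (!variable %in% names(u)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  unname(u[[variable]])
}

# seconds in the package's 365-day year (no leap handling; fluxes are
# self-consistent under this convention and the error is < 0.1%)
SECONDS_PER_YEAR <- 365 * 86400

# recognized input units -> multiplicative factor to canonical units,
# per variable class
unit_table <- function(variable) {
  carbon <- c("gC m-2 yr-1" = 1,
              "gC/m2/yr"    = 1,
              "gC m-2 s-1"  = SECONDS_PER_YEAR,
              "kgC m-2 s-1" = 1000 * SECONDS_PER_YEAR,
              "kgC m-2 yr-1" = 1000)
  water <- c("kgH2O m-2 yr-1" = 1,
             "mm yr-1"        = 1,
             "mm/yr"          = 1,
             "kg m-2 yr-1"    = 1,
             "kg m-2 s-1"     = SECONDS_PER_YEAR,
             "kgH2O m-2 s-1"  = SECONDS_PER_YEAR)
  switch(variable,
    gpp = , npp = , ra = carbon,
    et = water,
    lai = c("m2 m-2" = 1, "m2/m2" = 1, "1" = 1),
    soil_moisture = c("kg m-2" = 1, "mm" = 1),
    soil_temperature = c("K" = 1, "degC" = NA_real_),  # offset handled below
    wue = c("gC kgH2O-1" = 1, "gC/kgH2O" = 1),
    cue = c("1" = 1),
    stop("unknown variable: ", variable, call. = FALSE)
  )
}

#' Normalize a field's units to the canonical set
#'
#' Converts recognized unit spellings (e.g. `kgC m-2 s-1` carbon fluxes from
#' model archives) to the canonical per-year units using a 365-day year.
#' Normalization is idempotent: a field already in canonical units is
#' returned unchanged.
#'
#' @param field a [grid_field()].
#' @return The field with `units` set to [canonical_units()] and values
#'   rescaled.
#' @export
normalize_units <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  tab <- unit_table(field$variable)
  if (!field$units %in% names(tab)) {
    stop("unknown units '", field$units, "' for variable '", field$variable,
         "'", call. = FALSE)
  }
  if (field$variable == "soil_temperature" && field$units == "degC") {
    field$values <- field$values + 273.15
  } else {
    f <- tab[[field$units]]
    if (f != 1) field$values <- field$values * f
  }
  field$units <- canonical_units(field$variable)
  field
}

#' Tidy a gridded field into a long tibble
#'
#' @param x a [grid_field()].
#' @param ... unused.
#' @return A tibble with columns `lat`, `lon`, `time`, `value` (land cells
#'   only).
#' @method tidy grid_field
#' @export
tidy.grid_field <- function(x, ...) {
  idx <- which(x$land_mask, arr.ind = TRUE)
  tibble::tibble(
    lat  = rep(x$lat[idx[, 1]], times = length(x$time)),
    lon  = rep(x$lon[idx[, 2]], times = length(x$time)),
    time = rep(x$time, each = nrow(idx)),
    value = as.vector(vapply(seq_along(x$time), function(k) {
      x$values[, , k][idx]
    }, numeric(nrow(idx))))
  )
}

# elementwise binary op on two fields sharing a grid
field_binop <- function(a, b, op) {
  check_same_grid(a, b)
  out <- a
  out$values <- op(a$values, b$values)
  out
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$lat, b$lat)) || !isTRUE(all.equal(a$lon, b$lon)) ||
      !isTRUE(all.equal(a$time, b$time))) {
    stop("grid mismatch between fields", call. = FALSE)
  }
  invisible(TRUE)
}
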