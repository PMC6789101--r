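#' Scenario recipe: which drivers are active in each factorial scenario
#'
#' The factorial design is nested: RG1 holds every driver at its reference;
#' SG1 adds time-varying climate; SG2 adds land use; SG3 adds atmospheric
#' CO2; BG1 adds nitrogen deposition (carbon-nitrogen models only).
#'
#' @return Named list mapping scenario code to its active driver set.
#' @export
scenario_recipe <- function() {
  list(RG1 = character(0),
       SG1 = "climate",
       SG2 = c("climate", "landuse"),
       SG3 = c("climate", "landuse", "co2"),
       BG1 = c("climate", "landuse", "co2", "ndep"))
}

DRIVERS <- c("climate", "landuse", "co2", "ndep")
EFFECT_VARS <- c("gpp", "npp", "et", "lai", "soil_moisture",
                 "soil_temperature")

#' Specification of one pseudo-model
#'
#' Defines the baseline climatology, the injected driver effects and the
#' noise model for one synthetic ecosystem model. Driver effects are signed
#' fractional changes reached by the final year (multiplicative, linear in
#' time): an effect of `0.20` on GPP means that driver alone raises GPP by
#' 20% between the first and last simulation year. Soil moisture and
#' temperature effects are absolute changes in their own units.
#'
#' @param model_name label.
#' @param has_nitrogen carbon-nitrogen model? When `FALSE` the nitrogen
#'   deposition effect is forced to zero and no BG1 scenario is generated.
#' @param gpp0 baseline GPP, gC m-2 yr-1 (scalar or lat x lon matrix).
#' @param cue0 baseline CUE (NPP fraction of GPP), in (0, 1).
#' @param et0 baseline ET, kgH2O m-2 yr-1.
#' @param lai0 baseline annual-mean LAI, m2 m-2.
#' @param sm0 baseline soil moisture, kg m-2.
#' @param st0 baseline soil temperature, K.
#' @param effects named list `effects[[driver]][[variable]]` of fractional
#'   trends per simulation period (absolute for soil variables); drivers in
#'   `c("climate", "landuse", "co2", "ndep")`, variables in
#'   `c("gpp", "npp", "et", "lai", "soil_moisture", "soil_temperature")`.
#'   Unlisted entries are zero.
#' @param rho lag-1 autocorrelation of the interannual noise, in `[0, 0.9]`.
#' @param noise_sd innovation standard deviation as a fraction of baseline.
#' @param seasonal_amp amplitude of the monthly LAI seasonal cycle as a
#'   fraction of `lai0` (0 gives constant LAI across months).
#' @param lai_dynamic whether LAI is prognostic (see [lai_ndep_series()]).
#' @param seed per-model RNG seed.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model_name, has_nitrogen = TRUE,
                       gpp0 = 1200, cue0 = 0.5, et0 = 600, lai0 = 3,
                       sm0 = 250, st0 = 283, effects = list(),
                       rho = 0.3, noise_sd = 0.03, seasonal_amp = 0.3,
                       lai_dynamic = TRUE, seed = 1L) {
  stopifnot(rho >= 0, rho <= 0.9, noise_sd >= 0,
            all(cue0 > 0), all(cue0 < 1), all(gpp0 > 0), all(et0 > 0))
  eff <- lapply(stats::setNames(DRIVERS, DRIVERS), function(d) {
    e <- stats::setNames(numeric(length(EFFECT_VARS)), EFFECT_VARS)
    if (!is.null(effects[[d]])) {
      given <- effects[[d]]
      bad <- setdiff(names(given), EFFECT_VARS)
      if (length(bad)) stop("unknown effect variable: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      e[names(given)] <- unlist(given)
    }
    e
  })
  if (!has_nitrogen) eff$ndep[] <- 0
  structure(list(model_name = model_name, has_nitrogen = has_nitrogen,
                 gpp0 = gpp0, cue0 = cue0, et0 = et0, lai0 = lai0,
                 sm0 = sm0, st0 = st0, effects = eff, rho = rho,
                 noise_sd = noise_sd, seasonal_amp = seasonal_amp,
                 lai_dynamic = lai_dynamic, seed = as.integer(seed)),
            class = "model_spec")
}

#' Build a synthetic global grid with a land mask
#'
#' Cell centers are equally spaced: latitude bands covering \[-90, 90\] and
#' longitudes covering \[-180, 180). The land mask is a smoothed random
#' field thresholded so that exactly `round(land_fraction * n_cells)` cells
#' are land, which yields contiguous-ish continents rather than salt and
#' pepper.
#'
#' @param nlat,nlon grid size (each at least 2).
#' @param land_fraction fraction of cells that are land, in (0, 1].
#' @param seed RNG seed.
#' @return A list with `lat`, `lon` and logical matrix `land_mask`.
#' @export
make_grid <- function(nlat, nlon, land_fraction = 0.3, seed = 1L) {
  stopifnot(nlat >= 2, nlon >= 2)
  if (land_fraction <= 0) stop("no land: land_fraction must be positive",
                               call. = FALSE)
  stopifnot(land_fraction <= 1)
  lat <- -90 + (seq_len(nlat) - 0.5) * 180 / nlat
  lon <- -180 + (seq_len(nlon) - 0.5) * 360 / nlon
  z <- with_seed(seed, matrix(stats::rnorm(nlat * nlon), nlat, nlon))
  # three passes of nearest-neighbour smoothing (longitude wraps around)
  for (i in 1:3) {
    up <- z[c(1, seq_len(nlat - 1)), ]
    dn <- z[c(seq_len(nlat - 1) + 1, nlat), ]
    lf <- z[, c(nlon, seq_len(nlon - 1))]
    rt <- z[, c(seq_len(nlon - 1) + 1, 1)]
    z <- (z + up + dn + lf + rt) / 5
  }
  n_land <- max(1L, round(land_fraction * nlat * nlon))
  mask <- matrix(rank(-z, ties.method = "first") <= n_land, nlat, nlon)
  list(lat = lat, lon = lon, land_mask = mask)
}

#' Simulate a stationary AR(1) series
#'
#' `x_t = rho * x_(t-1) + e_t` with Gaussian innovations of standard
#' deviation `sd`; the initial value is drawn from the stationary
#' distribution `N(0, sd^2 / (1 - rho^2))` so the series is stationary from
#' the first sample.
#'
#' @param n series length (at least 2).
#' @param rho lag-1 coefficient, `|rho| < 1`.
#' @param sd innovation standard deviation.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of length `n`.
#' @export
ar1_series <- function(n, rho, sd, seed = NULL) {
  if (abs(rho) >= 1) stop("nonstationary: |rho| must be < 1", call. = FALSE)
  stopifnot(n >= 2)
  sim <- function() {
    if (sd == 0) return(numeric(n))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, sd = sd / sqrt(1 - rho^2))
    e <- stats::rnorm(n - 1, sd = sd)
    for (t in 2:n) x[t] <- rho * x[t - 1] + e[t - 1]
    x
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}

# AR(1) noise for many cells at once: rows = cells, cols = time
ar1_matrix <- function(ncell, n, rho, sd) {
  if (sd == 0 || ncell == 0) return(matrix(0, ncell, n))
  x <- matrix(0, ncell, n)
  x[, 1] <- stats::rnorm(ncell, sd = sd / sqrt(1 - rho^2))
  for (t in 2:n) x[, t] <- rho * x[, t - 1] + stats::rnorm(ncell, sd = sd)
  x
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  force(code)
}

as_baseline <- function(x, nlat, nlon) {
  if (length(x) == 1) matrix(x, nlat, nlon) else {
    stopifnot(identical(dim(x), c(nlat, nlon)))
    x
  }
}

#' Generate one pseudo-model's factorial scenario ensemble
#'
#' For every scenario the active drivers (per [scenario_recipe()]) act as a
#' shared linear-in-time multiplicative factor: on land,
#' `GPP_t = gpp0 * (1 + sum_d eff_d(gpp) * f_t) * (1 + noise_t)` with
#' `f_t = (t - t0) / (t_end - t0)`, and analogously for NPP (baseline
#' `cue0 * gpp0`), ET, LAI, soil moisture and temperature (the soil
#' variables additively). `Ra = GPP - NPP` by construction. Noise is AR(1)
#' per cell and shared across scenarios of the model (and between GPP and
#' NPP), so scenario differences isolate the injected effects exactly;
#' `shared_noise = FALSE` gives each scenario independent noise as a stress
#' test. Monthly LAI carries a fixed sinusoidal seasonal cycle (peaking in
#' July north of the equator, January south of it) scaled by the annual
#' driver factor.
#'
#' The multiplicative noise factor is floored at 0.05 so fluxes stay
#' positive and `Ra >= 0` holds for any admissible spec.
#'
#' @param spec a [model_spec()].
#' @param grid a grid from [make_grid()].
#' @param years annual time axis.
#' @param recipe a [scenario_recipe()].
#' @param shared_noise share noise realizations across scenarios (default).
#' @return A [scenario_ensemble()].
#' @export
generate_ensemble <- function(spec, grid, years = 1901:2010,
                              recipe = scenario_recipe(),
                              shared_noise = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  nlat <- length(grid$lat); nlon <- length(grid$lon); ny <- length(years)
  mask <- grid$land_mask
  land <- which(mask)
  frac <- (years - years[1]) / (years[length(years)] - years[1])
  if (!spec$has_nitrogen) recipe <- recipe[names(recipe) != "BG1"]

  base <- list(
    gpp = as_baseline(spec$gpp0, nlat, nlon),
    npp = as_baseline(spec$cue0, nlat, nlon) * as_baseline(spec$gpp0, nlat, nlon),
    et = as_baseline(spec$et0, nlat, nlon),
    lai = as_baseline(spec$lai0, nlat, nlon),
    soil_moisture = as_baseline(spec$sm0, nlat, nlon),
    soil_temperature = as_baseline(spec$st0, nlat, nlon))

  noise_streams <- c("gpp", "et", "lai", "soil_moisture", "soil_temperature")
  gen_noise <- function() {
    lapply(stats::setNames(noise_streams, noise_streams), function(v) {
      ar1_matrix(length(land), ny, spec$rho, spec$noise_sd)
    })
  }
  set.seed(spec$seed)
  noise <- gen_noise()

  eff_sum <- function(active, var) {
    if (!length(active)) return(0)
    sum(vapply(active, function(d) spec$effects[[d]][[var]], numeric(1)))
  }
  build_field <- function(var, active, nz, multiplicative = TRUE) {
    trend <- eff_sum(active, var) * frac            # length ny
    vals <- array(NA_real_, c(nlat, nlon, ny))
    b <- base[[var]][land]
    nf <- pmax(1 + nz, 0.05)                        # noise factor, floored
    for (k in seq_len(ny)) {
      slice <- matrix(NA_real_, nlat, nlon)
      slice[land] <- if (multiplicative) {
        b * (1 + trend[k]) * nf[, k]
      } else {
        b + trend[k] + b * nz[, k]
      }
      vals[, , k] <- slice
    }
    vals
  }
  seasonal <- function() {
    # lat x 12 matrix of seasonal factors, hemisphere-dependent peak
    peak <- ifelse(grid$lat >= 0, 7, 1)
    outer(peak, 1:12, function(p, m) 1 + spec$seasonal_amp *
            cos(2 * pi * (m - p) / 12))
  }
  sf <- seasonal()

  fields <- lapply(recipe, function(active) {
    if (!shared_noise) noise <- gen_noise()
    gpp <- build_field("gpp", active, noise$gpp)
    npp <- build_field("npp", active, noise$gpp)   # shared stream: Ra >= 0
    ra <- gpp - npp
    et <- build_field("et", active, noise$et)
    sm <- build_field("soil_moisture", active, noise$soil_moisture,
                      multiplicative = FALSE)
    st <- build_field("soil_temperature", active, noise$soil_temperature,
                      multiplicative = FALSE)
    # monthly LAI: annual driver factor times the seasonal cycle
    lai_ann <- build_field("lai", active, noise$lai)
    lai_m <- array(NA_real_, c(nlat, nlon, ny * 12))
    tm <- numeric(ny * 12)
    for (k in seq_len(ny)) for (m in 1:12) {
      j <- (k - 1) * 12 + m
      lai_m[, , j] <- lai_ann[, , k] * sf[, m]
      tm[j] <- years[k] + (m - 1) / 12
    }
    gf <- function(v, vals, time = years, freq = "annual") {
      grid_field(vals, grid$lat, grid$lon, time, variable = v,
                 units = canonical_units(v), land_mask = mask,
                 frequency = freq)
    }
    list(gpp = gf("gpp", gpp), npp = gf("npp", npp), ra = gf("ra", ra),
         et = gf("et", et), soil_moisture = gf("soil_moisture", sm),
         soil_temperature = gf("soil_temperature", st),
         lai = gf("lai", lai_m, time = tm, freq = "monthly"))
  })
  scenario_ensemble(spec$model_name, spec$has_nitrogen, fields,
                    lai_dynamic = spec$lai_dynamic)
}

#' Ground-truth ledger for a set of model specs
#'
#' Machine-readable record of every injected effect size, noise parameter
#' and seed, written beside the NetCDF tree so recovery tests can compare
#' pipeline output against what was actually injected.
#'
#' @param specs list of [model_spec()]s.
#' @return A tibble with one row per (model, driver, variable) effect.
#' @export
ground_truth <- function(specs) {
  purrr::map_dfr(specs, function(sp) {
    purrr::map_dfr(DRIVERS, function(d) {
      tibble::tibble(model = sp$model_name, has_nitrogen = sp$has_nitrogen,
                     driver = d, variable = EFFECT_VARS,
                     effect = unname(sp$effects[[d]]),
                     rho = sp$rho, noise_sd = sp$noise_sd, seed = sp$seed)
    })
  })
}

#' Generate a full synthetic archive on disk
#'
#' Writes `root/<model>/<scenario>/<variable>.nc` for each spec plus the
#' ground-truth ledger as `root/ground_truth.json`.
#'
#' @param specs list of [model_spec()]s.
#' @param grid a grid from [make_grid()].
#' @param root output directory.
#' @param years annual time axis.
#' @return `root`, invisibly.
#' @export
generate_archive <- function(specs, grid, root, years = 1901:2010) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (sp in specs) {
    write_ensemble(generate_ensemble(sp, grid, years), root)
  }
  jsonlite::write_json(ground_truth(specs),
                       file.path(root, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(root)
}

#' Default three-model study ensemble
#'
#' Three pseudo-models with contrasting dominant drivers, emulating the
#' qualitative structure of the real model archive: two carbon-nitrogen
#' models (one CO2-dominated, one nitrogen-deposition-dominated) and one
#' carbon-only model dominated by climate. Effect magnitudes follow the
#' ranges the literature reports for the 20th century: CO2 fertilization
#' raising GPP on the order of 20% with a much weaker ET response, a
#' climate-driven WUE decline of a few to ~20 percent, and a small positive
#' nitrogen-deposition effect (GPP a few percent, ET well under 1%).
#'
#' @param seed base seed; each model offsets it deterministically.
#' @param noise_sd interannual noise level (fraction of baseline).
#' @param rho lag-1 noise autocorrelation.
#' @return List of three [model_spec()]s.
#' @export
default_specs <- function(seed = 1L, noise_sd = 0.03, rho = 0.3) {
  list(
    model_spec("cnmod-co2", has_nitrogen = TRUE, seed = seed,
               noise_sd = noise_sd, rho = rho,
               effects = list(
                 climate = list(gpp = -0.03, npp = -0.03, et = 0.03,
                                soil_moisture = -15, soil_temperature = 1.2),
                 co2 = list(gpp = 0.20, npp = 0.22, et = 0.02, lai = 0.10),
                 ndep = list(gpp = 0.04, npp = 0.05, et = 0.005,
                             lai = 0.05))),
    model_spec("cnmod-ndep", has_nitrogen = TRUE, seed = seed + 1L,
               noise_sd = noise_sd, rho = rho,
               effects = list(
                 climate = list(gpp = -0.02, npp = -0.02, et = 0.02,
                                soil_moisture = -10, soil_temperature = 1.0),
                 co2 = list(gpp = 0.05, npp = 0.05, et = 0.01, lai = 0.03),
                 ndep = list(gpp = 0.15, npp = 0.18, et = 0.01,
                             lai = 0.12))),
    model_spec("cmod-clim", has_nitrogen = FALSE, seed = seed + 2L,
               noise_sd = noise_sd, rho = rho,
               effects = list(
                 climate = list(gpp = -0.12, npp = -0.14, et = 0.08,
                                soil_moisture = -20, soil_temperature = 1.5),
                 co2 = list(gpp = 0.06, npp = 0.06, et = 0.01, lai = 0.04)))
  )
}

#' Generate a synthetic reference WUE product
#'
#' Stand-in for an upscaled flux-tower water-use-efficiency product over a
#' comparison window: a spatially uniform base value plus an optional linear
#' trend and iid Gaussian noise per cell and year.
#'
#' @param grid a grid from [make_grid()].
#' @param years window years (default 1982:2008).
#' @param base_wue base WUE, gC/kgH2O.
#' @param trend linear trend, gC/kgH2O per year (default 0: flat reference).
#' @param sd iid noise standard deviation.
#' @param seed RNG seed.
#' @return A [grid_field()] of WUE.
#' @export
generate_reference_wue <- function(grid, years = 1982:2008, base_wue = 1.5,
                                   trend = 0, sd = 0, seed = 1L) {
  nlat <- length(grid$lat); nlon <- length(grid$lon); ny <- length(years)
  vals <- with_seed(seed, {
    v <- array(NA_real_, c(nlat, nlon, ny))
    land <- which(grid$land_mask)
    for (k in seq_len(ny)) {
      slice <- matrix(NA_real_, nlat, nlon)
      slice[land] <- base_wue + trend * (years[k] - years[1]) +
        stats::rnorm(length(land), sd = sd)
      v[, , k] <- slice
    }
    v
  })
  grid_field(vals, grid$lat, grid$lon, years, variable = "wue",
             units = canonical_units("wue"), land_mask = grid$land_mask)
}
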