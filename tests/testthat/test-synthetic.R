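test_that("make_grid produces the requested geometry and land fraction", {
  g <- make_grid(10, 20, 0.3, seed = 1)
  expect_length(g$lat, 10)
  expect_length(g$lon, 20)
  expect_true(all(diff(g$lat) > 0))
  expect_true(all(g$lon >= -180 & g$lon < 180))
  # rank thresholding pins the land count at round(fraction * n)
  expect_equal(sum(g$land_mask), 60)

  expect_true(all(make_grid(5, 5, 1.0, seed = 2)$land_mask))
  expect_identical(make_grid(8, 8, 0.4, seed = 9)$land_mask,
                   make_grid(8, 8, 0.4, seed = 9)$land_mask)
  expect_error(make_grid(5, 5, 0), "no land")
})

test_that("ar1_series has the stationary AR(1) moments", {
  lag1 <- function(v) {
    vc <- v - mean(v)
    sum(vc[-length(v)] * vc[-1]) / sum(vc^2)
  }
  x0 <- ar1_series(5000, rho = 0, sd = 1, seed = 1)
  expect_lt(abs(lag1(x0)), 3 / sqrt(5000))
  x5 <- ar1_series(5000, rho = 0.5, sd = 1, seed = 2)
  expect_lt(abs(lag1(x5) - 0.5), 0.05)
  # stationary variance sd^2 / (1 - rho^2)
  expect_equal(var(x5), 1 / (1 - 0.25), tolerance = 0.1)
  expect_identical(ar1_series(100, 0.3, sd = 0), numeric(100))
  expect_error(ar1_series(10, rho = 1, sd = 1), "nonstationary")
})

test_that("null ensemble is constant in time and identical across scenarios", {
  g <- tiny_grid()
  sp <- model_spec("null", has_nitrogen = TRUE, noise_sd = 0, seed = 5)
  ens <- generate_ensemble(sp, g, years = 1901:1910)
  for (sc in c("SG1", "SG2", "SG3", "BG1")) {
    expect_identical(ens$fields[[sc]]$gpp$values, ens$fields$RG1$gpp$values)
    expect_identical(ens$fields[[sc]]$et$values, ens$fields$RG1$et$values)
  }
  s <- efficiency_series(ens, "BG1", "gpp")
  expect_true(all(s$value == s$value[1]))
})

test_that("injected CO2 effect appears in SG3 - SG2 exactly at the final year", {
  g <- tiny_grid()
  sp <- model_spec("co2only", has_nitrogen = TRUE, noise_sd = 0, seed = 6,
                   effects = list(co2 = list(gpp = 0.20)))
  ens <- generate_ensemble(sp, g, years = 1901:2010)
  d2010 <- ens$fields$SG3$gpp$values[, , 110] - ens$fields$SG2$gpp$values[, , 110]
  land <- which(g$land_mask)
  expect_equal(d2010[land], rep(0.20 * 1200, length(land)), tolerance = 1e-12)
  # no effect at the first year
  d1901 <- ens$fields$SG3$gpp$values[, , 1] - ens$fields$SG2$gpp$values[, , 1]
  expect_true(all(d1901[land] == 0))
})

test_that("scenario differences stay noise-free under shared noise", {
  g <- tiny_grid()
  sp <- model_spec("noisy", has_nitrogen = TRUE, noise_sd = 0.05, seed = 7,
                   effects = list(climate = list(gpp = -0.1)))
  ens <- generate_ensemble(sp, g, years = 1901:1920)
  land <- which(g$land_mask)
  # SG1 - RG1 = gpp0 * (-0.1) * frac * noise_factor; relative to RG1 it is
  # exactly -0.1 * frac, independent of the noise realization
  frac <- (0:19) / 19
  for (k in c(5, 20)) {
    ratio <- (ens$fields$SG1$gpp$values[, , k] - ens$fields$RG1$gpp$values[, , k]) /
      ens$fields$RG1$gpp$values[, , k]
    expect_equal(ratio[land], rep(-0.1 * frac[k], length(land)),
                 tolerance = 1e-12)
  }
})

test_that("carbon-only models have no BG1 and no nitrogen effect", {
  g <- tiny_grid()
  sp <- model_spec("conly", has_nitrogen = FALSE, noise_sd = 0, seed = 8,
                   effects = list(ndep = list(gpp = 0.5)))
  expect_equal(unname(sp$effects$ndep["gpp"]), 0)  # forced to zero
  ens <- generate_ensemble(sp, g, years = 1901:1905)
  expect_false("BG1" %in% scenarios(ens))
  expect_identical(maximal_scenario(ens), "SG3")
})

test_that("Ra = GPP - NPP is non-negative everywhere", {
  g <- tiny_grid()
  sp <- model_spec("ra", has_nitrogen = TRUE, noise_sd = 0.1, seed = 9,
                   effects = list(co2 = list(gpp = 0.1, npp = 0.2)))
  ens <- generate_ensemble(sp, g, years = 1901:1930)
  for (sc in scenarios(ens)) {
    ra <- ens$fields[[sc]]$ra$values
    expect_true(all(ra[!is.na(ra)] >= 0))
    expect_equal(ens$fields[[sc]]$ra$values,
                 ens$fields[[sc]]$gpp$values - ens$fields[[sc]]$npp$values)
  }
})

test_that("generation is deterministic for a fixed spec and seed", {
  g <- tiny_grid()
  sp <- model_spec("det", has_nitrogen = TRUE, noise_sd = 0.05, seed = 10)
  e1 <- generate_ensemble(sp, g, years = 1901:1910)
  e2 <- generate_ensemble(sp, g, years = 1901:1910)
  expect_identical(e1$fields$BG1$gpp$values, e2$fields$BG1$gpp$values)
  expect_identical(e1$fields$SG1$lai$values, e2$fields$SG1$lai$values)
})

test_that("ground-truth ledger records every injected effect", {
  specs <- default_specs(seed = 1)
  gt <- ground_truth(specs)
  expect_s3_class(gt, "tbl_df")
  expect_identical(nrow(gt), 3L * 4L * 6L)  # models x drivers x variables
  row <- dplyr::filter(gt, model == "cnmod-co2", driver == "co2",
                       variable == "gpp")
  expect_equal(row$effect, 0.20)
  # carbon-only model has zero ndep effects
  cm <- dplyr::filter(gt, model == "cmod-clim", driver == "ndep")
  expect_true(all(cm$effect == 0))
})

test_that("reference WUE generator honors base, trend and determinism", {
  g <- tiny_grid()
  flat <- generate_reference_wue(g, 1982:2008, base_wue = 1.5, sd = 0)
  land <- which(g$land_mask)
  expect_true(all(flat$values[, , 27][land] == 1.5))
  sloped <- generate_reference_wue(g, 1982:2008, base_wue = 1.5,
                                   trend = 0.01, sd = 0)
  expect_equal(sloped$values[, , 27][land][1], 1.5 + 0.01 * 26)
  a <- generate_reference_wue(g, sd = 0.1, seed = 3)
  b <- generate_reference_wue(g, sd = 0.1, seed = 3)
  expect_identical(a$values, b$values)
})

test_that("a flat noisy reference rejects at about the nominal rate", {
  g <- tiny_grid(nlat = 4, nlon = 4, land_fraction = 0.5)
  rej <- vapply(1:150, function(s) {
    ref <- generate_reference_wue(g, 1982:2008, trend = 0, sd = 0.05,
                                  seed = s)
    trend_test(area_weighted_mean(ref), method = "tfpw-mk")$significant
  }, logical(1))
  expect_lt(mean(rej), 0.12)
})
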