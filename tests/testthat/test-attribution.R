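make_test_ensemble <- function(effects, seed = 20, noise_sd = 0,
                               has_nitrogen = TRUE, years = 1901:2010,
                               grid = tiny_grid()) {
  sp <- model_spec("t", has_nitrogen = has_nitrogen, noise_sd = noise_sd,
                   seed = seed, effects = effects)
  generate_ensemble(sp, grid, years = years)
}

test_that("driver effects are zero for a null ensemble and recover closed forms", {
  ens0 <- make_test_ensemble(list())
  for (d in c("climate", "co2", "ndep")) {
    eff <- driver_effect(ens0, d, "wue")
    expect_true(all(eff$value == 0), label = d)
  }

  # injected CO2 effect on GPP only: WUE CO2 effect in 2010 = 0.20 * WUE0
  ens <- make_test_ensemble(list(co2 = list(gpp = 0.20)))
  eff <- driver_effect(ens, "co2", "wue")
  expect_equal(eff$value[110], 0.20 * (1200 / 600), tolerance = 1e-10)
  expect_equal(eff$value[1], 0)
})

test_that("exchanging the scenario pair negates the climate effect", {
  ens <- make_test_ensemble(list(climate = list(gpp = -0.1, et = 0.05)))
  eff <- driver_effect(ens, "climate", "wue")
  swapped <- ens
  swapped$fields[c("SG1", "RG1")] <- swapped$fields[c("RG1", "SG1")]
  eff2 <- driver_effect(swapped, "climate", "wue")
  expect_equal(eff2$value, -eff$value, tolerance = 1e-12)
})

test_that("ndep effect is refused for carbon-only models", {
  ens <- make_test_ensemble(list(), has_nitrogen = FALSE)
  expect_error(driver_effect(ens, "ndep", "cue"),
               "driver unavailable for model type")
})

test_that("net change is anchored at zero in the baseline year", {
  ens <- make_test_ensemble(list(co2 = list(gpp = 0.10, et = 0.0)))
  nc <- net_change(ens, "wue")
  expect_identical(nc$value[1], 0)
  # constant series: all-zero net change
  nc0 <- net_change(make_test_ensemble(list()), "cue")
  expect_true(all(nc0$value == 0))
  # +10% combined WUE effect by 2010
  expect_equal(nc$value[110], 0.10 * 2.0, tolerance = 1e-10)
})

test_that("percent contribution matches hand arithmetic and generator algebra", {
  # constant effect 0.1 against denominator 2.0 -> 5%
  ens <- make_test_ensemble(list(co2 = list(gpp = 0.20)))
  ens0 <- make_test_ensemble(list())  # constant WUE = 2.0 denominator
  eff <- driver_effect(ens, "co2", "wue")
  eff$value <- rep(0.1, nrow(eff))
  expect_equal(percent_contribution(eff, ens0),
               100 * 0.1 / 2.0, tolerance = 1e-10)

  # closed form: mean(0.20 * wue0 * frac) / mean(wue_bg1)
  eff2 <- driver_effect(ens, "co2", "wue")
  denom <- efficiency_series(ens, "BG1", "wue")
  want <- 100 * mean(eff2$value) / mean(denom$value)
  expect_equal(percent_contribution(eff2, ens), want, tolerance = 1e-9)
  # invariant under common rescaling of every scenario's fields
  scaled <- ens
  for (sc in scenarios(scaled)) for (v in c("gpp", "npp", "ra", "et")) {
    scaled$fields[[sc]][[v]]$values <- scaled$fields[[sc]][[v]]$values * 4
  }
  eff3 <- driver_effect(scaled, "co2", "wue")
  expect_equal(percent_contribution(eff3, scaled),
               percent_contribution(eff2, ens), tolerance = 1e-9)
})

test_that("percent increase matches its definition on generated GPP", {
  d <- tibble::tibble(time = c(1901, 2010), value = c(100, 104))
  expect_equal(percent_increase(d), 4)
  expect_equal(percent_increase(tibble::tibble(time = c(1901, 2010),
                                               value = c(5, 5))), 0)
  ens <- make_test_ensemble(list(co2 = list(gpp = 0.20)))
  s <- efficiency_series(ens, "SG3", "gpp")
  expect_equal(percent_increase(s), 20, tolerance = 1e-9)
  expect_error(percent_increase(tibble::tibble(time = 1901:1902,
                                               value = 1:2), y1 = 2010),
               "absent")
})

test_that("additivity of single-driver effects up to the interaction term", {
  ens <- make_test_ensemble(list(climate = list(gpp = -0.05, et = 0.03),
                                 co2 = list(gpp = 0.20, et = 0.02),
                                 ndep = list(gpp = 0.04, et = 0.005)))
  total <- net_change(ens, "wue")$value[110]
  parts <- sum(vapply(c("climate", "co2", "ndep"), function(d) {
    driver_effect(ens, d, "wue")$value[110]
  }, numeric(1)))
  # effects are a few percent to 20%: second-order interactions stay small
  expect_equal(parts, total, tolerance = 0.02)
})

test_that("dominant-driver map labels the injected driver everywhere", {
  ens <- make_test_ensemble(list(co2 = list(gpp = 0.20)))
  m <- dominant_driver_map(ens, "wue")
  expect_true(all(m$label[m$land_mask] == "co2"))
  expect_true(all(is.na(m$label[!m$land_mask])))

  m0 <- dominant_driver_map(make_test_ensemble(list()), "wue")
  expect_true(all(m0$label[m0$land_mask] == "none"))
})

test_that("dominant-driver map resolves a north/south spatial split", {
  g <- tiny_grid(nlat = 10, nlon = 12, land_fraction = 0.6, seed = 30)
  nlat <- 10; nlon <- 12
  north <- matrix(rep(g$lat > 45, nlon), nlat, nlon)
  # cell-wise effect maps are not part of model_spec; emulate the split by
  # stitching two generated ensembles along the 45N boundary
  sp_n <- model_spec("n", has_nitrogen = TRUE, noise_sd = 0.01, seed = 31,
                     effects = list(climate = list(gpp = -0.25)))
  sp_s <- model_spec("s", has_nitrogen = TRUE, noise_sd = 0.01, seed = 31,
                     effects = list(co2 = list(gpp = 0.25)))
  e_n <- generate_ensemble(sp_n, g)
  e_s <- generate_ensemble(sp_s, g)
  stitched <- e_n
  for (sc in scenarios(e_n)) for (v in names(e_n$fields[[sc]])) {
    vn <- e_n$fields[[sc]][[v]]$values
    vs <- e_s$fields[[sc]][[v]]$values
    keep_n <- rep(north, dim(vn)[3])
    vn[!keep_n] <- vs[!keep_n]
    stitched$fields[[sc]][[v]]$values <- vn
  }
  m <- dominant_driver_map(stitched, "wue")
  want <- ifelse(north, "climate", "co2")[m$land_mask]
  got <- m$label[m$land_mask]
  expect_gt(mean(got == want), 0.9)
})

test_that("ensemble summary reflects ground truth and the missing-ET rule", {
  g <- tiny_grid()
  specs <- default_specs(seed = 40, noise_sd = 0)
  ensembles <- lapply(specs, generate_ensemble, grid = g,
                      years = 1901:2010)
  # drop ET entirely from one model (the missing-ET rule)
  for (sc in scenarios(ensembles[[2]])) ensembles[[2]]$fields[[sc]]$et <- NULL

  tab_wue <- ensemble_summary(ensembles, "wue")
  expect_false("cnmod-ndep" %in% tab_wue$model)  # no ET -> no WUE rows
  tab_cue <- ensemble_summary(ensembles, "cue")
  expect_true("cnmod-ndep" %in% tab_cue$model)   # CUE still reported

  # per-model dominant driver (argmax |contribution|) matches the ledger
  dom <- tab_wue |>
    dplyr::filter(driver != "combined") |>
    dplyr::group_by(model) |>
    dplyr::slice_max(abs(pct_contribution), n = 1) |>
    dplyr::ungroup()
  expect_identical(dom$driver[dom$model == "cnmod-co2"], "co2")
  expect_identical(dom$driver[dom$model == "cmod-clim"], "climate")

  # null ensemble: nothing significant, zero change
  null_tab <- ensemble_summary(list(make_test_ensemble(list())), "cue")
  expect_true(all(!null_tab$significant))
  expect_true(all(null_tab$pct_change == 0))
})
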