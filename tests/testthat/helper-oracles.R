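# Independent brute-force oracles for the trend statistics. These enumerate
# all pairs directly and are kept deliberately separate from the package's
# implementations.

oracle_mk <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[j] - x[i])
  }
  # tie-corrected variance by explicit tie-group enumeration
  groups <- rle(sort(x))$lengths
  corr <- 0
  for (t in groups) corr <- corr + t * (t - 1) * (2 * t + 5)
  list(S = as.integer(s),
       varS = (n * (n - 1) * (2 * n + 5) - corr) / 18)
}

oracle_sen <- function(x, t = seq_along(x)) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    slopes <- c(slopes, (x[j] - x[i]) / (t[j] - t[i]))
  }
  median(slopes)
}

# battery of random short series, with ties, under a fixed seed
random_series_battery <- function(n_series = 200, max_n = 12, seed = 42) {
  withr::with_seed(seed, lapply(seq_len(n_series), function(i) {
    n <- sample(4:max_n, 1)
    if (runif(1) < 0.5) {
      round(runif(n, 0, 5))  # heavy ties
    } else {
      rnorm(n)
    }
  }))
}

# a small synthetic grid + noiseless spec shared across tests
tiny_grid <- function(nlat = 6, nlon = 8, land_fraction = 0.5, seed = 7) {
  make_grid(nlat, nlon, land_fraction, seed = seed)
}

uniform_field <- function(value, grid, years = 1901:1910,
                          variable = "gpp") {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  vals <- array(value, c(nlat, nlon, length(years)))
  grid_field(vals, grid$lat, grid$lon, years, variable = variable,
             units = canonical_units(variable),
             land_mask = grid$land_mask)
}
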