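#' Plot driver-effect series for a set of models
#'
#' One line per model of the per-year effect of a driver on a quantity —
#' the factorial-difference curves (climate, CO2 fertilization, nitrogen
#' deposition, or the combined net change).
#'
#' @param ensembles list of [scenario_ensemble()]s.
#' @param driver driver to plot (see [driver_effect()]).
#' @param quantity response variable.
#' @param scope aggregation scope.
#' @param config an [eco_config()].
#' @return A ggplot object.
#' @export
plot_driver_effect <- function(ensembles, driver, quantity,
                               scope = "global", config = eco_config()) {
  dat <- purrr::map_dfr(ensembles, function(ens) {
    if (driver == "ndep" && !ens$has_nitrogen) return(tibble::tibble())
    if (quantity == "wue" && !"et" %in% model_variables(ens)) {
      return(tibble::tibble())
    }
    eff <- driver_effect(ens, driver, quantity, scope, config)
    tibble::tibble(model = ens$model_name, time = eff$time,
                   value = eff$value)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$model)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year",
                  y = paste0("Δ", toupper(quantity)),
                  colour = "Model",
                  title = paste0(toupper(quantity), " effect: ", driver)) +
    ggplot2::theme_minimal()
}

#' Plot an efficiency series
#'
#' @param object an `efficiency_series` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot efficiency_series
#' @export
autoplot.efficiency_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year",
                  y = paste0(toupper(attr(object, "quantity")),
                             " [", attr(object, "units"), "]")) +
    ggplot2::theme_minimal()
}

#' Plot a dominant-driver map
#'
#' Tile map of the per-cell dominant environmental driver.
#'
#' @param object a [dominant_driver_map()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dominant_driver_map
#' @export
autoplot.dominant_driver_map <- function(object, ...) {
  dat <- tidy.dominant_driver_map(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lon, y = .data$lat,
                                    fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(climate = "#d95f02",
                                          co2 = "#1b9e77",
                                          ndep = "#7570b3",
                                          none = "grey80"),
                               na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Driver",
                  title = paste0("Dominant driver of ",
                                 toupper(object$quantity), ", ",
                                 min(object$period), "-",
                                 max(object$period))) +
    ggplot2::theme_minimal()
}
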