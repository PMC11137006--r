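#' Plot the time course of a simulation
#'
#' Facets the headline observables — live cancer cells, cumulative dead
#' cells, mean oncoprotein expression and live CAR T-cells — against
#' simulated time in days.
#'
#' @param object a `cart_sim`.
#' @param metrics which metric columns to facet.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cart_sim <- function(object,
                              metrics = c("live_cancer", "cum_dead",
                                          "mean_oncoprotein", "live_tcells"),
                              ...) {
  dat <- tidy(object) |> dplyr::filter(.data$metric %in% metrics)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(colour = "#08519c") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cell-type composition over time
#'
#' Stacked area chart of the four oncoprotein-defined type fractions among
#' live cancer cells.
#'
#' @param sim a `cart_sim`.
#' @return A ggplot object.
#' @export
plot_type_fractions <- function(sim) {
  dat <- sim$metrics |>
    dplyr::select("time", dplyr::starts_with("frac_type")) |>
    tidyr::pivot_longer(-"time", names_to = "type", values_to = "fraction") |>
    dplyr::mutate(day = .data$time / 1440,
                  type = gsub("frac_", "", .data$type))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$fraction,
                                    fill = .data$type)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", direction = -1) +
    ggplot2::labs(x = "time (days)", y = "fraction of live cells",
                  fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution table
#'
#' Number density per spherical shell and cell class, as produced by
#' [radial_distribution()].
#'
#' @param gr a radial-distribution tibble.
#' @return A ggplot object.
#' @export
plot_radial_distribution <- function(gr) {
  ggplot2::ggplot(gr, ggplot2::aes(x = .data$r_mid, y = .data$density,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from organoid centre of mass (um)",
                  y = "number density (cells/um^3)", colour = NULL) +
    ggplot2::theme_minimal()
}
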