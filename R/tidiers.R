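#' Tidy a simulation result
#'
#' Returns the per-save-time observables in long format: one row per
#' (time, metric) pair, ready for faceted plotting or joins across runs.
#'
#' @param x a `cart_sim`.
#' @param ... unused.
#' @return A tibble with columns `time` (min), `day`, `metric`, `value`.
#' @export
tidy.cart_sim <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(-"time", names_to = "metric", values_to = "value") |>
    dplyr::mutate(day = .data$time / 1440, .after = "time")
}

#' One-row summary of a simulation
#'
#' @param x a `cart_sim`.
#' @param ... unused.
#' @return A one-row tibble: initial and final live cancer counts, the
#'   minimum live count over the run, cumulative deaths and kills, initial
#'   and final mean oncoprotein, administered T-cell count, dead-per-CAR-T
#'   ratio and free T-cell count (NA for untreated runs), and the trailing
#'   growth rate (1/day).
#' @export
glance.cart_sim <- function(x, ...) {
  m <- x$metrics
  treated <- nrow(x$kill_ledger) > 0
  dpc <- if (treated) dead_per_cart(x) else NULL
  gr <- tryCatch(suppressWarnings(growth_rate(m)), error = function(e) NA_real_)
  tibble::tibble(
    initial_live_cancer = m$live_cancer[1],
    final_live_cancer = tail(m$live_cancer, 1),
    min_live_cancer = min(m$live_cancer),
    cum_dead = tail(m$cum_dead, 1),
    cum_kills = tail(m$cum_kills, 1),
    initial_mean_oncoprotein = m$mean_oncoprotein[1],
    final_mean_oncoprotein = tail(m$mean_oncoprotein, 1),
    tcells_administered = nrow(x$kill_ledger),
    dead_per_cart = if (treated) dpc$ratio else NA_real_,
    free_tcells = if (treated) dpc$free_tcells else NA_integer_,
    growth_rate = gr
  )
}
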