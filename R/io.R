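#' Write and read metrics tables
#'
#' Metrics CSVs carry one row per save time with a header naming every
#' column; times are minutes, counts are cells, `mean_oncoprotein` is
#' dimensionless, type fractions sum to one over live cells.  On read, the
#' cumulative columns are re-checked for monotonicity and a warning names
#' any violation.
#'
#' @param metrics a metrics tibble (or `cart_sim`).
#' @param path file path.
#' @return `write_metrics` returns `path` invisibly; `read_metrics` returns
#'   the tibble.
#' @export
write_metrics <- function(metrics, path) {
  if (inherits(metrics, "cart_sim")) metrics <- metrics$metrics
  readr::write_csv(metrics, path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("cum_dead", "cum_kills", "cum_dead_hypoxia"),
                        names(out))) {
    if (is.unsorted(out[[col]])) {
      warn(sprintf("cumulative column '%s' is not non-decreasing", col))
    }
  }
  out
}

#' Write and read point-cloud snapshots
#'
#' Snapshots are whitespace/CSV particle tables consumable by standard
#' particle viewers: one row per agent with id, kind (`cancer` or `cart`),
#' type label, position (um), radius (um), oncoprotein, cycle phase and an
#' alive flag.  `read_snapshot(write_snapshot(x))` round-trips all fields.
#'
#' @param population a data frame with at least `x`, `y`, `z`; missing
#'   snapshot columns are filled with defaults.
#' @param path file path.
#' @param kind agent kind recorded in the `kind` column.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot` the
#'   tibble.
#' @export
write_snapshot <- function(population, path, kind = "cancer") {
  n <- nrow(population)
  snap <- tibble::tibble(
    id = rep_len(col_or(population, "id", seq_len(max(n, 1))), n),
    kind = rep_len(col_or(population, "kind", kind), n),
    type_label = rep_len(col_or(population, "type", NA_integer_), n),
    x = population$x, y = population$y, z = population$z,
    radius = rep_len(col_or(population, "radius", NA_real_), n),
    oncoprotein = rep_len(
      col_or(population, "o", col_or(population, "oncoprotein", NA_real_)), n),
    phase = rep_len(col_or(population, "phase", NA_integer_), n),
    alive_flag = as.integer(rep_len(col_or(population, "death", "none"),
                                    n) == "none")
  )
  readr::write_csv(snap, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("malformed snapshot file '%s': %s",
                                      path, conditionMessage(e)))
  )
  required <- c("id", "kind", "x", "y", "z")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(sprintf("snapshot file '%s' lacks column(s): %s (line 1)",
                  path, paste(missing, collapse = ", ")))
  }
  out
}

#' Write a per-T-cell kill ledger
#'
#' @param sim a `cart_sim` (or its kill-ledger tibble).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_kill_ledger <- function(sim, path) {
  ledger <- if (inherits(sim, "cart_sim")) sim$kill_ledger else sim
  readr::write_csv(ledger, path)
  invisible(path)
}

#' Run manifest
#'
#' A manifest echoes the full configuration, the seed, the package version
#' and a parameter hash; re-launching [simulate_organoid()] from a manifest's
#' configuration reproduces the metrics series bitwise.
#'
#' @param sim a `cart_sim`.
#' @return A list of class `cartsim_manifest`.
#' @export
run_manifest <- function(sim) {
  structure(
    list(
      config = sim$config,
      seed = as.integer(sim$config$seed),
      package_version = as.character(utils::packageVersion("cartsim")),
      config_hash = rlang::hash(unclass(sim$config)),
      n_save_points = nrow(sim$metrics),
      finished = TRUE
    ),
    class = "cartsim_manifest"
  )
}

#' Re-run a simulation from its manifest
#'
#' @param manifest a `cartsim_manifest`.
#' @return A new `cart_sim`, bitwise-identical in its metrics to the
#'   original run.
#' @export
simulate_from_manifest <- function(manifest) {
  simulate_organoid(manifest$config)
}
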