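#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quadrant resampling result
#'
#' @param x A `quadrant_resample` from [resample_proportions()].
#' @param ... Unused.
#' @return Tibble with one row per quadrant: point, mean and sd of the
#'   proportion across resamples.
#' @export
tidy.quadrant_resample <- function(x, ...) {
  x$summary
}

#' @rdname tidy.quadrant_resample
#' @return `glance()`: one-row tibble with `n` mutants, `B` resamples and
#'   the mean both-improve proportion.
#' @export
glance.quadrant_resample <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    B = x$B,
    prop_both_improve = x$summary$mean[x$summary$quadrant == "both-improve"]
  )
}

#' Tidy an inferred mutation-rate grid
#'
#' @param x A `dfe_grid` from [invert_dfe()].
#' @param ... Unused.
#' @return The grid as a plain tibble.
#' @export
tidy.dfe_grid <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.dfe_grid
#' @return `glance()`: one-row tibble with the total detected count and the
#'   integrated beneficial rate `Ub` implied by the grid.
#' @export
glance.dfe_grid <- function(x, ...) {
  tibble::tibble(
    n_detected = sum(x$count),
    total_rate = attr(x, "total_rate"),
    n_bins = nrow(x)
  )
}

#' Tidy an evolution simulation
#'
#' @param x An `evolution_sim` from [simulate_evolution()].
#' @param ... Unused.
#' @return The count table.
#' @export
tidy.evolution_sim <- function(x, ...) {
  x$counts
}

#' @rdname tidy.evolution_sim
#' @export
glance.evolution_sim <- function(x, ...) {
  tibble::tibble(
    n_lineages = nrow(x$truth$lineages),
    n_transfers = x$truth$config$n_transfers,
    n_established = sum(x$truth$events$established),
    n_detected = sum(x$truth$events$detected),
    final_mean_fitness = x$truth$xbar$xbar[nrow(x$truth$xbar)]
  )
}
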