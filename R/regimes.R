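#' Serial-transfer regimes and growth-phase schedules
#'
#' A transfer regime describes one serial-dilution condition of a batch-culture
#' evolution or fitness-measurement experiment: the ordered sequence of growth
#' phases a population experiences between transfers, with the hours spent in
#' each phase. The canonical conditions are named `"1D"`, `"2D"`, `"3D"` and
#' `"5D"` (24, 48, 72 and 120 h cycles). In the 1-Day cycle the cells spend
#' 4 h in lag phase, 16 h fermenting glucose and 4 h respiring ethanol; longer
#' cycles append further respiration and then stationary phase.
#'
#' @param name Regime label, e.g. `"2D"`.
#' @param schedule Data frame with columns `phase` (one of `"lag"`,
#'   `"fermentation"`, `"respiration"`, `"stationary"`) and `hours`
#'   (non-negative durations), in chronological order.
#' @param generations_per_cycle Approximate number of generations per transfer
#'   cycle. Reporting metadata only: all selection coefficients in this package
#'   are natural-log based and per cycle, never per generation.
#'
#' @return An object of class `transfer_regime`: a list with elements `name`,
#'   `schedule` (tibble), `cycle_hours` and `generations_per_cycle`.
#' @examples
#' r <- transfer_regime("1D", data.frame(
#'   phase = c("lag", "fermentation", "respiration"),
#'   hours = c(4, 16, 4)
#' ))
#' r$cycle_hours
#' @seealso [default_regimes()], [compose_cycle_fitness()]
#' @export
transfer_regime <- function(name, schedule, generations_per_cycle = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  schedule <- tibble::as_tibble(schedule)
  if (!all(c("phase", "hours") %in% names(schedule))) {
    stop("`schedule` must have columns `phase` and `hours`", call. = FALSE)
  }
  bad <- setdiff(schedule$phase, names(.phase_levels))
  if (length(bad) > 0L) {
    stop("unknown phase label(s) in schedule: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(schedule$hours < 0)) stop("phase durations must be non-negative", call. = FALSE)
  structure(
    list(
      name = name,
      schedule = schedule,
      cycle_hours = sum(schedule$hours),
      generations_per_cycle = generations_per_cycle
    ),
    class = "transfer_regime"
  )
}

# lag is pinned to a zero per-hour contribution for every genotype
.phase_levels <- c(lag = 0, fermentation = 1, respiration = 2, stationary = 3)

#' @export
print.transfer_regime <- function(x, ...) {
  cat("<transfer_regime> ", x$name, " (", x$cycle_hours, " h/cycle",
      if (!is.na(x$generations_per_cycle)) {
        paste0(", ~", x$generations_per_cycle, " gen/cycle")
      },
      ")\n", sep = "")
  sched <- paste0(x$schedule$hours, "h ", x$schedule$phase)
  cat("  ", paste(sched, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Default transfer regimes of the two-step evolution design
#'
#' The four serial-transfer conditions used throughout: 1-Day (4 h lag + 16 h
#' fermentation + 4 h respiration), 2-Day (1-Day plus 24 h respiration), 3-Day
#' (2-Day plus 12 h respiration and 12 h stationary) and 5-Day (3-Day plus
#' 48 h stationary).
#'
#' @param names Which regimes to return (subset of `"1D"`, `"2D"`, `"3D"`,
#'   `"5D"`).
#' @return A named list of [transfer_regime] objects.
#' @examples
#' default_regimes()[["2D"]]
#' @export
default_regimes <- function(names = c("1D", "2D", "3D", "5D")) {
  names <- match.arg(names, several.ok = TRUE)
  sched <- function(phase, hours) tibble::tibble(phase = phase, hours = hours)
  all <- list(
    "1D" = transfer_regime(
      "1D", sched(c("lag", "fermentation", "respiration"), c(4, 16, 4)),
      generations_per_cycle = 7
    ),
    "2D" = transfer_regime(
      "2D", sched(c("lag", "fermentation", "respiration"), c(4, 16, 28)),
      generations_per_cycle = 8
    ),
    "3D" = transfer_regime(
      "3D",
      sched(c("lag", "fermentation", "respiration", "stationary"),
            c(4, 16, 40, 12)),
      generations_per_cycle = 8
    ),
    "5D" = transfer_regime(
      "5D",
      sched(c("lag", "fermentation", "respiration", "stationary"),
            c(4, 16, 40, 60)),
      generations_per_cycle = 8
    )
  )
  all[names]
}

#' Total hours per phase of a regime
#'
#' @param regime A [transfer_regime].
#' @return Named numeric vector of summed hours for `lag`, `fermentation`,
#'   `respiration` and `stationary`.
#' @examples
#' phase_hours(default_regimes()[["2D"]])
#' @export
phase_hours <- function(regime) {
  stopifnot(inherits(regime, "transfer_regime"))
  out <- c(lag = 0, fermentation = 0, respiration = 0, stationary = 0)
  agg <- tapply(regime$schedule$hours, regime$schedule$phase, sum)
  out[names(agg)] <- agg
  out
}

#' Compose per-cycle fitness from per-hour phase performances
#'
#' The forward model linking a genotype's per-hour performance in each growth
#' phase to its per-cycle selection coefficient under a transfer regime: the
#' per-cycle fitness is the schedule-weighted sum of the per-hour performances,
#' with lag phase contributing zero by construction. Performances and fitness
#' are natural-log based and relative to the common ancestor, whose profile is
#' all zeros.
#'
#' @param profiles Data frame with one row per genotype and numeric columns
#'   `fer`, `res`, `sta`: per-hour selection coefficients in fermentation,
#'   respiration and stationary phase. Other columns (e.g. a lineage id) are
#'   carried through.
#' @param regimes A [transfer_regime], or a list of them (default: all four
#'   canonical regimes).
#' @return A tibble in long format: the input columns plus `condition` (regime
#'   name) and `s` (per-cycle selection coefficient), one row per genotype and
#'   regime.
#' @examples
#' compose_cycle_fitness(
#'   data.frame(lineage = "m1", fer = 0.01, res = 0.02, sta = -0.005)
#' )
#' @export
compose_cycle_fitness <- function(profiles, regimes = default_regimes()) {
  profiles <- tibble::as_tibble(profiles)
  stopifnot(all(c("fer", "res", "sta") %in% names(profiles)))
  if (inherits(regimes, "transfer_regime")) regimes <- list(regimes)
  purrr::map_dfr(regimes, function(rg) {
    h <- phase_hours(rg)
    dplyr::mutate(
      profiles,
      condition = rg$name,
      s = h[["fermentation"]] * .data$fer +
        h[["respiration"]] * .data$res +
        h[["stationary"]] * .data$sta
    )
  })
}

#' Read or write transfer regimes as JSON
#'
#' Round-trippable JSON serialization for regime definitions, so that a set of
#' conditions can be shared as a plain-text config.
#'
#' @param regimes Named list of [transfer_regime] objects.
#' @param path File path to write to / read from.
#' @return `regimes_to_json()` returns `path` invisibly; `regimes_from_json()`
#'   returns a named list of [transfer_regime] objects.
#' @examples
#' tf <- tempfile(fileext = ".json")
#' regimes_to_json(default_regimes(), tf)
#' regimes_from_json(tf)[["5D"]]
#' @export
regimes_to_json <- function(regimes, path) {
  payload <- purrr::map(regimes, function(rg) {
    list(
      name = rg$name,
      schedule = as.data.frame(rg$schedule),
      generations_per_cycle = rg$generations_per_cycle
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname regimes_to_json
#' @export
regimes_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- purrr::map(payload, function(p) {
    transfer_regime(p$name, p$schedule,
                    generations_per_cycle = p$generations_per_cycle)
  })
  names(out) <- purrr::map_chr(out, "name")
  out
}
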