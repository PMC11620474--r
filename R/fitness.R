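#' Pseudocounted barcode frequencies
#'
#' Converts a count table to within-sample frequencies. A pseudocount added to
#' every lineage keeps zero-count endpoints finite without noticeably biasing
#' large counts. A sample is one (condition, replicate, timepoint) combination.
#'
#' @param counts Count table: columns `barcode`, `condition`, `replicate`,
#'   `timepoint`, `count` (and optionally `class`).
#' @param pseudocount Added to every count before normalization (default 0.5).
#' @param ancestor_read_retention Fraction of ancestor-barcode reads that
#'   survived restriction-digest depletion (1 = no depletion). When below 1
#'   (and a `class` column labels the ancestor), the returned `cellf`
#'   un-depletes the ancestor so that it estimates the cell fraction rather
#'   than the read fraction.
#' @param ancestor_class `class` value labelling the ancestor lineage.
#' @return The input with columns `depth` (raw sample depth), `freq`
#'   (pseudocounted read frequency) and `cellf` (estimated cell frequency)
#'   appended.
#' @export
barcode_frequencies <- function(counts, pseudocount = 0.5,
                                ancestor_read_retention = 1,
                                ancestor_class = "ancestor") {
  counts <- tibble::as_tibble(counts)
  has_class <- "class" %in% names(counts)
  counts |>
    dplyr::group_by(.data$condition, .data$replicate, .data$timepoint) |>
    dplyr::mutate(
      depth = sum(.data$count),
      freq = (.data$count + pseudocount) /
        sum(.data$count + pseudocount),
      cellf = {
        w <- .data$count + pseudocount
        if (has_class && ancestor_read_retention < 1) {
          w[.data$class == ancestor_class] <-
            w[.data$class == ancestor_class] / ancestor_read_retention
        }
        w / sum(w)
      }
    ) |>
    dplyr::ungroup()
}

#' Mean fitness of the population from neutral reference lineages
#'
#' In a pooled competition assay the per-cycle mean fitness of the population
#' is read off the decline of a set of known-neutral reference lineages: over
#' an interval, `xbar = -log(F_N(t1) / F_N(t0)) / (t1 - t0)` where `F_N` is
#' the summed frequency of the neutral set. Summing first (a count-weighted
#' estimator) minimizes variance compared to averaging per-lineage estimates.
#'
#' The standard error combines, by the delta method, the counting variance of
#' the summed neutral reads at both endpoints and, when `bottleneck` is
#' finite, the multinomial cell sampling at each serial-transfer bottleneck.
#'
#' @inheritParams barcode_frequencies
#' @param neutral_classes Values of the `class` column treated as neutral
#'   references. The two 60-lineage neutral pools are treated as one set by
#'   default; pass a single pool label to separate them.
#' @param bottleneck Number of cells transferred per cycle. `Inf` (default)
#'   restricts the error model to sequencing counting noise.
#' @return A tibble with one row per (condition, replicate, interval):
#'   `condition`, `replicate`, `t0`, `t1`, `xbar`, `se`, `n_neutral`.
#' @examples
#' counts <- tibble::tibble(
#'   barcode = rep(c("n1", "a"), 2), class = rep(c("neutral", "adaptive"), 2),
#'   condition = "2D", replicate = 1, timepoint = rep(0:1, each = 2),
#'   count = c(400, 9600, 200, 9800)
#' )
#' mean_fitness_from_neutrals(counts, pseudocount = 0)
#' @export
mean_fitness_from_neutrals <- function(counts, neutral_classes = "neutral",
                                       pseudocount = 0.5, bottleneck = Inf,
                                       ancestor_read_retention = 1,
                                       ancestor_class = "ancestor") {
  counts <- tibble::as_tibble(counts)
  stopifnot("class" %in% names(counts))
  if (!any(counts$class %in% neutral_classes)) {
    stop("no neutral lineages (class in ",
         paste(neutral_classes, collapse = ", "), ") in the count table",
         call. = FALSE)
  }
  freq <- barcode_frequencies(counts, pseudocount, ancestor_read_retention,
                              ancestor_class)
  per_tp <- freq |>
    dplyr::filter(.data$class %in% neutral_classes) |>
    dplyr::group_by(.data$condition, .data$replicate, .data$timepoint) |>
    dplyr::summarise(
      f_n = sum(.data$freq),
      cf_n = sum(.data$cellf),
      n_n = sum(.data$count),
      n_lineage = dplyr::n(),
      .groups = "drop"
    )
  per_tp |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::reframe({
      v <- .endpoint_var(.data$n_n, .data$cf_n, pseudocount, bottleneck)
      k <- length(v)
      tp <- .data$timepoint
      f_n <- .data$f_n
      n_lineage <- .data$n_lineage
      tibble::tibble(
        t0 = tp[-k],
        t1 = tp[-1L],
        xbar = -diff(log(f_n)) / diff(tp),
        se = sqrt(v[-k] + v[-1L]) / diff(tp),
        n_neutral = n_lineage[-1L]
      )
    })
}

# log-frequency variance of one endpoint: sequencing counting noise plus,
# when the transfer bottleneck is finite, multinomial cell sampling at the
# transfer (cellf must be the cell fraction, not the depleted read fraction)
.endpoint_var <- function(n, cellf, pseudocount, bottleneck) {
  1 / (n + pseudocount) + 1 / (cellf * bottleneck)
}

#' Per-lineage fitness from log-frequency change, mean-fitness corrected
#'
#' A lineage's per-cycle selection coefficient over an interval is its
#' log-frequency change per cycle plus the population mean fitness over the
#' same interval: `s = log(f(t1)/f(t0)) / (t1 - t0) + xbar`. The variance sums
#' the counting (and optional bottleneck) variance of both endpoints, scaled
#' by the squared interval length, and the mean-fitness variance.
#'
#' @inheritParams mean_fitness_from_neutrals
#' @param mean_fitness Mean-fitness track from [mean_fitness_from_neutrals()]
#'   (or any tibble with `condition`, `replicate`, `t0`, `t1`, `xbar`, `se`).
#' @param intervals Optional tibble of intervals (`condition`, `t0`, `t1`) to
#'   restrict to, e.g. from [select_intervals()]. Default: every interval
#'   present in `mean_fitness`.
#' @return A tibble with one row per (barcode, condition, replicate,
#'   interval): `s`, `se`, raw endpoint counts `n0`/`n1` and a `flag` column
#'   (`"zero-endpoints"` when both raw counts are zero -- the estimate is then
#'   driven entirely by the pseudocount and is flagged, not dropped).
#' @seealso [pool_replicates()] to combine replicate estimates.
#' @export
lineage_fitness <- function(counts, mean_fitness, intervals = NULL,
                            pseudocount = 0.5, bottleneck = Inf,
                            ancestor_read_retention = 1,
                            ancestor_class = "ancestor") {
  freq <- barcode_frequencies(counts, pseudocount, ancestor_read_retention,
                              ancestor_class)
  mf <- tibble::as_tibble(mean_fitness)
  if (!is.null(intervals)) {
    mf <- dplyr::semi_join(mf, tibble::as_tibble(intervals),
                           by = intersect(names(mf), c("condition", "t0", "t1")))
  }
  keep <- c("barcode", if ("class" %in% names(freq)) "class",
            "condition", "replicate", "timepoint", "count", "freq", "cellf")
  freq <- freq[keep]
  e0 <- dplyr::inner_join(
    mf, freq,
    by = c("condition", "replicate", "t0" = "timepoint"),
    relationship = "one-to-many"
  ) |>
    dplyr::rename(n0 = "count", f0 = "freq", cf0 = "cellf")
  both <- dplyr::inner_join(
    e0,
    dplyr::rename(freq, n1 = "count", f1 = "freq", cf1 = "cellf"),
    by = c("condition", "replicate", "t1" = "timepoint", "barcode",
           if ("class" %in% names(freq)) "class")
  )
  both |>
    dplyr::mutate(
      dt = .data$t1 - .data$t0,
      s = log(.data$f1 / .data$f0) / .data$dt + .data$xbar,
      se = sqrt(
        (.endpoint_var(.data$n0, .data$cf0, pseudocount, bottleneck) +
           .endpoint_var(.data$n1, .data$cf1, pseudocount, bottleneck)) /
          .data$dt^2 +
          .data$se^2
      ),
      flag = dplyr::if_else(.data$n0 == 0 & .data$n1 == 0,
                            "zero-endpoints", NA_character_)
    ) |>
    dplyr::select(dplyr::any_of(c(
      "barcode", "class", "condition", "replicate", "t0", "t1",
      "s", "se", "n0", "n1", "flag"
    )))
}

#' Pool replicate fitness estimates by inverse-variance weighting
#'
#' @param fits Output of [lineage_fitness()].
#' @return One row per (barcode, condition, interval) with pooled `s`, `se`,
#'   `replicate = "pooled"` and `n_replicates`.
#' @export
pool_replicates <- function(fits) {
  fits |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("barcode", "class", "condition", "t0", "t1")
    ))) |>
    dplyr::summarise(
      s = stats::weighted.mean(.data$s, 1 / .data$se^2),
      se = sqrt(1 / sum(1 / .data$se^2)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(replicate = "pooled")
}

#' Select usable measurement intervals by ancestor dominance
#'
#' Fitness in this assay is frequency dependent: estimates are only comparable
#' across studies while the shared ancestor still dominates the population.
#' An interval qualifies when the ancestor's cell fraction at its start is at
#' least `ancestor_threshold` (default 0.80). The 2-Day condition is
#' additionally capped to its first interval (timepoint 0 to 1) regardless of
#' ancestor fraction, the convention under which 2-Day fitness is reported
#' throughout.
#'
#' When the ancestor barcode was depleted before sequencing (restriction
#' digestion of the ancestral barcode), its read fraction under-represents its
#' cell fraction; supply the retention `ancestor_read_retention` so the cell
#' fraction can be restored before thresholding.
#'
#' @inheritParams mean_fitness_from_neutrals
#' @param ancestor_threshold Minimum starting ancestor cell fraction.
#' @param ancestor_class Value of `class` labelling the ancestor lineage.
#' @param ancestor_read_retention Fraction of ancestor reads surviving
#'   depletion (1 = no depletion).
#' @param cap_2d Cap condition `"2D"` to the (0, 1) interval (default TRUE).
#' @return Tibble of qualifying intervals: `condition`, `t0`, `t1`,
#'   `ancestor_fraction` (averaged over replicates). Zero rows, with a
#'   warning, when nothing qualifies.
#' @export
select_intervals <- function(counts, ancestor_threshold = 0.8,
                             ancestor_class = "ancestor",
                             ancestor_read_retention = 1, cap_2d = TRUE) {
  counts <- tibble::as_tibble(counts)
  stopifnot("class" %in% names(counts))
  if (!any(counts$class == ancestor_class)) {
    stop("no lineage labelled with ancestor class '", ancestor_class, "'",
         call. = FALSE)
  }
  anc <- counts |>
    dplyr::group_by(.data$condition, .data$replicate, .data$timepoint) |>
    dplyr::summarise(
      n_anc = sum(.data$count[.data$class == ancestor_class]),
      n_oth = sum(.data$count[.data$class != ancestor_class]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      anc_cells = .data$n_anc / ancestor_read_retention,
      ancestor_fraction = .data$anc_cells / (.data$anc_cells + .data$n_oth)
    ) |>
    dplyr::group_by(.data$condition, .data$timepoint) |>
    dplyr::summarise(ancestor_fraction = mean(.data$ancestor_fraction),
                     .groups = "drop")
  out <- anc |>
    dplyr::group_by(.data$condition) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::reframe(
      t0 = .data$timepoint[-dplyr::n()],
      t1 = .data$timepoint[-1L],
      ancestor_fraction = .data$ancestor_fraction[-dplyr::n()]
    ) |>
    dplyr::filter(.data$ancestor_fraction >= ancestor_threshold)
  if (cap_2d) {
    out <- dplyr::filter(out, .data$condition != "2D" |
                           (.data$t0 == 0 & .data$t1 == 1))
  }
  if (nrow(out) == 0L) {
    warning("no interval meets the ancestor-fraction threshold", call. = FALSE)
  }
  out
}

#' Frequency-dependence diagnostic for per-interval fitness estimates
#'
#' Strongly adaptive lineages can depress the apparent fitness of other
#' mutants once they dominate the culture, even after mean-fitness
#' correction. This diagnostic expresses each mutant's per-interval fitness as
#' a percent deviation from its reference estimate (by default the earliest
#' interval measured) and pairs it with the adaptive-class fraction of the
#' population at the interval start, so a systematic decline with adaptive
#' takeover is visible.
#'
#' @param fits Per-interval fitness estimates (a [lineage_fitness()] or
#'   [pool_replicates()] result).
#' @param counts The count table the estimates came from (for the
#'   adaptive-fraction covariate).
#' @param adaptive_classes `class` values counted as adaptive.
#' @return Tibble with one row per (mutant, non-reference interval):
#'   `condition`, `t0`, `t1`, `adaptive_fraction`, `barcode`, `s`, `s_ref`,
#'   `deviation_pct` (`NA`, flagged, where `s_ref` is 0) and per-interval
#'   `median_deviation_pct`.
#' @export
frequency_dependence_diagnostic <- function(fits, counts,
                                            adaptive_classes = "adaptive") {
  fits <- tibble::as_tibble(fits)
  adaptive_frac <- counts |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$condition, .data$timepoint) |>
    dplyr::summarise(
      adaptive_fraction = sum(.data$count[.data$class %in% adaptive_classes]) /
        sum(.data$count),
      .groups = "drop"
    )
  ref <- fits |>
    dplyr::group_by(.data$barcode, .data$condition) |>
    dplyr::slice_min(.data$t0, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("barcode", "condition", s_ref = "s", t_ref = "t0")
  fits |>
    dplyr::inner_join(ref, by = c("barcode", "condition")) |>
    dplyr::filter(.data$t0 != .data$t_ref) |>
    dplyr::left_join(adaptive_frac,
                     by = c("condition", "t0" = "timepoint")) |>
    dplyr::mutate(
      deviation_pct = dplyr::if_else(
        .data$s_ref == 0, NA_real_,
        100 * (.data$s - .data$s_ref) / .data$s_ref
      ),
      flag = dplyr::if_else(.data$s_ref == 0, "zero-reference", NA_character_)
    ) |>
    dplyr::group_by(.data$condition, .data$t0, .data$t1) |>
    dplyr::mutate(median_deviation_pct =
                    stats::median(.data$deviation_pct, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c(
      "condition", "t0", "t1", "adaptive_fraction", "barcode",
      "s", "s_ref", "deviation_pct", "median_deviation_pct", "flag"
    )))
}
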