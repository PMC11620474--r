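#' Decompose per-cycle fitness into per-hour growth-phase performances
#'
#' Inverts the schedule-based forward model of [compose_cycle_fitness()] on the
#' canonical regimes. Because the 24-to-48 h window of a 2-Day cycle contains
#' only respiration, respiration performance per hour is
#' `(f2 - f1) / 24`. Fermentation performance removes the 4 respiration hours
#' from the 1-Day fitness and divides the remainder over the 16 fermentation
#' hours: `(f1 - 4 * res) / 16`. Stationary performance is the 5-Day minus
#' 3-Day fitness over the 48 extra stationary hours: `(f5 - f3) / 48`.
#'
#' The 1-Day fitness enters both the fermentation and respiration formulas, so
#' shared 1-Day measurement noise would induce a spurious negative correlation
#' between the two performances. The replicate-splitting rule avoids this:
#' respiration uses the second 1-Day replicate and fermentation the first, so
#' that 1-Day counting noise enters the two estimates independently.
#'
#' Standard errors are first-order propagation treating the named inputs as
#' independent. Written as linear forms,
#' `res = f2/24 - f1b/24` and `fer = f1a/16 - f2/96 + f1b/96`, giving
#' `se_res = sqrt(se_f2^2 + se_f1b^2) / 24` and
#' `se_fer = sqrt(se_f1a^2/256 + (se_f2^2 + se_f1b^2)/9216)`.
#'
#' @param fits Data frame of per-lineage fitness estimates with columns
#'   `lineage`, `condition` (`"1D"`, `"2D"`, `"3D"`, `"5D"`), `replicate`,
#'   `s` and `se`. Replicates of the 2-, 3- and 5-Day conditions are pooled by
#'   inverse-variance weighting; the two 1-Day replicates are kept separate and
#'   split between fermentation and respiration as described.
#' @param rep1,rep2 Which 1-Day replicate labels feed fermentation (`rep1`)
#'   and respiration (`rep2`). Default: the first and second label in sort
#'   order. Flask numbering is arbitrary, so consumers may remap.
#' @param pool How to pool replicates within the 2/3/5-Day conditions:
#'   `"ivw"` (inverse-variance weighted mean, default) or `"between"`
#'   (unweighted mean with empirical between-replicate SE).
#' @return A tibble with one row per lineage: `fer`, `res`, `sta`, `se_fer`,
#'   `se_res`, `se_sta`, `baseline = "ancestor"`, and `cov_fer_res` (nonzero
#'   only when a single 1-Day replicate had to serve both formulas, in which
#'   case a warning is issued). `sta`/`se_sta` are `NA` when the 3- or 5-Day
#'   condition is absent; `fer`/`res` are `NA` (with `flag` set) when the 1- or
#'   2-Day condition is absent.
#' @examples
#' fits <- data.frame(
#'   lineage = "m1",
#'   condition = c("1D", "1D", "2D", "3D", "5D"),
#'   replicate = c(1, 2, 1, 1, 1),
#'   s = c(0.24, 0.24, 0.72, 0.90, 0.66),
#'   se = 0.01
#' )
#' decompose_performances(fits)
#' @seealso [parent_reference()], [relative_to_parent()]
#' @export
decompose_performances <- function(fits, rep1 = NULL, rep2 = NULL,
                                   pool = c("ivw", "between")) {
  fits <- tibble::as_tibble(fits)
  stopifnot(all(c("lineage", "condition", "s", "se") %in% names(fits)))
  pool <- match.arg(pool)
  if (!"replicate" %in% names(fits)) fits$replicate <- 1L

  one_day <- dplyr::filter(fits, .data$condition == "1D")
  reps <- sort(unique(one_day$replicate))
  if (is.null(rep1)) rep1 <- if (length(reps) >= 1L) reps[[1L]] else NA
  if (is.null(rep2)) rep2 <- if (length(reps) >= 2L) reps[[2L]] else rep1
  single_rep <- length(reps) == 1L
  if (single_rep && nrow(one_day) > 0L) {
    warning("only one 1-Day replicate: fermentation and respiration share ",
            "its noise; cov_fer_res is reported", call. = FALSE)
  }

  pooled <- fits |>
    dplyr::filter(.data$condition %in% c("2D", "3D", "5D")) |>
    dplyr::group_by(.data$lineage, .data$condition) |>
    dplyr::summarise(
      s = if (pool == "ivw") {
        stats::weighted.mean(.data$s, 1 / .data$se^2)
      } else {
        mean(.data$s)
      },
      se = if (pool == "ivw") {
        sqrt(1 / sum(1 / .data$se^2))
      } else if (dplyr::n() > 1L) {
        stats::sd(.data$s) / sqrt(dplyr::n())
      } else {
        .data$se[[1L]]
      },
      .groups = "drop"
    )

  pick <- function(df, cond, rep = NULL) {
    keep <- df$condition == cond
    if (!is.null(rep)) keep <- keep & df$replicate %in% rep
    df[keep, c("lineage", "s", "se")]
  }
  wide <- tibble::tibble(lineage = unique(fits$lineage)) |>
    dplyr::left_join(
      dplyr::rename(pick(one_day, "1D", rep1), f1a = "s", se1a = "se"),
      by = "lineage"
    ) |>
    dplyr::left_join(
      dplyr::rename(pick(one_day, "1D", rep2), f1b = "s", se1b = "se"),
      by = "lineage"
    ) |>
    dplyr::left_join(
      dplyr::rename(pick(pooled, "2D"), f2 = "s", se2 = "se"),
      by = "lineage"
    ) |>
    dplyr::left_join(
      dplyr::rename(pick(pooled, "3D"), f3 = "s", se3 = "se"),
      by = "lineage"
    ) |>
    dplyr::left_join(
      dplyr::rename(pick(pooled, "5D"), f5 = "s", se5 = "se"),
      by = "lineage"
    )

  out <- wide |>
    dplyr::mutate(
      res = (.data$f2 - .data$f1b) / 24,
      fer = (.data$f1a - 4 * .data$res) / 16,
      sta = (.data$f5 - .data$f3) / 48,
      se_res = sqrt(.data$se2^2 + .data$se1b^2) / 24,
      se_fer = sqrt(.data$se1a^2 / 256 + (.data$se2^2 + .data$se1b^2) / 9216),
      se_sta = sqrt(.data$se5^2 + .data$se3^2) / 48,
      # when one 1-Day flask serves both formulas its variance is shared:
      # cov(fer, res) = cov(f1/16 - (f2 - f1)/96, (f2 - f1)/24)
      cov_fer_res = if (single_rep) {
        .data$se1a^2 * (1 / (16 * 24) + 1 / (96 * 24)) -
          .data$se2^2 / (96 * 24)
      } else {
        0
      },
      baseline = "ancestor",
      flag = dplyr::case_when(
        is.na(.data$f2) ~ "missing-2D",
        is.na(.data$f1a) ~ "missing-1D",
        .default = NA_character_
      )
    ) |>
    dplyr::select(
      "lineage", "fer", "res", "sta", "se_fer", "se_res", "se_sta",
      "cov_fer_res", "baseline", "flag"
    )
  if (anyNA(out$fer) || anyNA(out$res)) {
    warning("fermentation/respiration undefined for ",
            sum(is.na(out$fer) | is.na(out$res)),
            " lineage(s) with missing 1-Day or 2-Day fitness", call. = FALSE)
  }
  out
}

#' Estimate per-hour phase performances from a multi-regime count table
#'
#' Convenience pipeline: infers mean fitness from the neutral pool, selects
#' the earliest usable interval per condition (ancestor-dominance rule plus
#' the 2-Day first-interval cap), estimates per-lineage fitness, pools
#' replicates of the 2-/3-/5-Day conditions while keeping the two 1-Day
#' replicates separate for the fermentation/respiration split, and
#' decomposes into per-hour performances.
#'
#' @inheritParams mean_fitness_from_neutrals
#' @inheritParams select_intervals
#' @return A performance tibble as from [decompose_performances()].
#' @examples
#' prof <- tibble::tibble(
#'   lineage = c("anc", "n1", "n2", "m1"),
#'   class = c("ancestor", "neutral", "neutral", "adaptive"),
#'   fer = c(0, 0, 0, 0.01), res = c(0, 0, 0, 0.02), sta = 0
#' )
#' sim <- simulate_fitness_assay(prof, read_depth = 1e4,
#'                               bottleneck_size = 1e4,
#'                               ancestor_read_retention = 1, seed = 1)
#' estimate_performances(sim$counts, bottleneck = 1e4)
#' @export
estimate_performances <- function(counts, neutral_classes = "neutral",
                                  pseudocount = 0.5, bottleneck = Inf,
                                  ancestor_read_retention = 1,
                                  ancestor_class = "ancestor",
                                  ancestor_threshold = 0.8) {
  mf <- mean_fitness_from_neutrals(counts, neutral_classes, pseudocount,
                                   bottleneck, ancestor_read_retention,
                                   ancestor_class)
  iv <- select_intervals(counts, ancestor_threshold, ancestor_class,
                         ancestor_read_retention) |>
    dplyr::group_by(.data$condition) |>
    dplyr::slice_min(.data$t0, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  lf <- lineage_fitness(counts, mf, intervals = iv, pseudocount = pseudocount,
                        bottleneck = bottleneck,
                        ancestor_read_retention = ancestor_read_retention,
                        ancestor_class = ancestor_class)
  fits <- dplyr::bind_rows(
    dplyr::filter(lf, .data$condition == "1D") |>
      dplyr::mutate(replicate = as.character(.data$replicate)),
    pool_replicates(dplyr::filter(lf, .data$condition != "1D"))
  ) |>
    dplyr::rename(lineage = "barcode")
  decompose_performances(fits)
}

#' Parental reference performance from neutral sibling lineages
#'
#' Second-step mutants are interpreted relative to the first-step strain they
#' evolved from. The parental reference is either the unweighted mean of the
#' parent's neutral-haploid lineages (SE = sd/sqrt(n), or the propagated SE
#' when only one such lineage exists), or a single designated barcoded lineage
#' taken verbatim -- the fallback when no neutral clones of a parent were
#' isolated.
#'
#' @param performances Tibble of performance estimates as returned by
#'   [decompose_performances()], with a `lineage` column.
#' @param lineages Character vector of lineage ids to use: the parent's
#'   neutral-haploid lineages (`strategy = "neutral-mean"`) or a single
#'   designated lineage (`strategy = "designated-lineage"`).
#' @param strategy Reference strategy; see above.
#' @return A one-row tibble with the same performance columns, `baseline =
#'   "ancestor"` and `n_ref`, the number of lineages averaged.
#' @examples
#' perf <- tibble::tibble(
#'   lineage = c("n1", "n2", "n3"),
#'   fer = c(0.010, 0.012, 0.014), res = 0.02, sta = 0,
#'   se_fer = 0.001, se_res = 0.001, se_sta = 0.001,
#'   baseline = "ancestor"
#' )
#' parent_reference(perf, c("n1", "n2", "n3"))
#' @export
parent_reference <- function(performances, lineages,
                             strategy = c("neutral-mean", "designated-lineage")) {
  strategy <- match.arg(strategy)
  performances <- tibble::as_tibble(performances)
  rows <- dplyr::filter(performances, .data$lineage %in% lineages)
  if (nrow(rows) == 0L) {
    stop("no qualifying reference lineages among: ",
         paste(lineages, collapse = ", "), call. = FALSE)
  }
  if (strategy == "designated-lineage") {
    if (length(lineages) != 1L) {
      stop("designated-lineage strategy requires exactly one lineage id",
           call. = FALSE)
    }
    out <- rows[1L, ]
    out$n_ref <- 1L
    return(out)
  }
  n <- nrow(rows)
  mean_se <- function(x, se) {
    if (n == 1L) list(m = x, se = se)
    else list(m = mean(x), se = stats::sd(x) / sqrt(n))
  }
  f <- mean_se(rows$fer, rows$se_fer)
  r <- mean_se(rows$res, rows$se_res)
  s <- mean_se(rows$sta, rows$se_sta)
  tibble::tibble(
    lineage = paste0("ref(", n, " neutrals)"),
    fer = f$m, res = r$m, sta = s$m,
    se_fer = f$se, se_res = r$se, se_sta = s$se,
    cov_fer_res = 0, baseline = "ancestor", n_ref = n
  )
}

#' Express performances relative to a parental strain
#'
#' Component-wise difference of two ancestor-referenced performance estimates,
#' with errors added in quadrature. The result carries `baseline = "parent"`
#' and is the input to quadrant classification.
#'
#' @param children Performance tibble (ancestor baseline), one row per mutant.
#' @param parent One-row performance tibble (ancestor baseline), e.g. from
#'   [parent_reference()].
#' @return Tibble like `children` with differenced performances, quadrature
#'   SEs and `baseline = "parent"`.
#' @examples
#' child <- tibble::tibble(lineage = "m", fer = 0.02, res = 0.03, sta = 0,
#'                         se_fer = 0.002, se_res = 0.004, se_sta = 0.002,
#'                         baseline = "ancestor")
#' parent <- tibble::tibble(lineage = "p", fer = 0.01, res = 0.01, sta = 0,
#'                          se_fer = 0.002, se_res = 0.003, se_sta = 0.002,
#'                          baseline = "ancestor")
#' relative_to_parent(child, parent)
#' @export
relative_to_parent <- function(children, parent) {
  children <- tibble::as_tibble(children)
  parent <- tibble::as_tibble(parent)
  stopifnot(nrow(parent) == 1L)
  if (!all(children$baseline == "ancestor") || parent$baseline != "ancestor") {
    stop("both inputs must be ancestor-baselined", call. = FALSE)
  }
  dplyr::mutate(
    children,
    fer = .data$fer - parent$fer,
    res = .data$res - parent$res,
    sta = .data$sta - parent$sta,
    se_fer = sqrt(.data$se_fer^2 + parent$se_fer^2),
    se_res = sqrt(.data$se_res^2 + parent$se_res^2),
    se_sta = sqrt(.data$se_sta^2 + parent$se_sta^2),
    baseline = "parent"
  )
}
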