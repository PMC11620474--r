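#' Classify mutants into pleiotropy quadrants
#'
#' A mutant is pleiotropically adaptive when it improves both fermentation and
#' respiration performance relative to its parental strain, and adaptively
#' modular when it improves only one. "Improve" means strictly greater than
#' zero: a performance change of exactly zero counts as non-improvement (the
#' boundary has measure zero under resampling, so the convention is
#' inconsequential there).
#'
#' @param deltas Parent-referenced performance tibble (see
#'   [relative_to_parent()]) with columns `fer` and `res` (and ideally
#'   `baseline = "parent"`).
#' @return The input with a `quadrant` factor appended: `"both-improve"`,
#'   `"resp-only"`, `"ferm-only"` or `"neither"`.
#' @examples
#' classify_quadrant(tibble::tibble(fer = c(0.01, -0.004, 0),
#'                                  res = c(0.02, 0.02, 0.02)))
#' @export
classify_quadrant <- function(deltas) {
  deltas <- tibble::as_tibble(deltas)
  if ("baseline" %in% names(deltas) && !all(deltas$baseline == "parent")) {
    stop("quadrants are defined on parent-referenced performances", call. = FALSE)
  }
  dplyr::mutate(deltas, quadrant = .quadrant_of(.data$fer, .data$res))
}

.quadrant_levels <- c("both-improve", "resp-only", "ferm-only", "neither")

.quadrant_of <- function(fer, res) {
  factor(
    dplyr::case_when(
      fer > 0 & res > 0 ~ "both-improve",
      res > 0 ~ "resp-only",
      fer > 0 ~ "ferm-only",
      .default = "neither"
    ),
    levels = .quadrant_levels
  )
}

#' Quadrant proportions under measurement-error resampling
#'
#' Point classification of mutants into quadrants ignores measurement error;
#' a mutant near an axis may fall on either side. Each of `B` resamples
#' redraws every mutant's (fermentation, respiration) performance change from
#' a Gaussian centred on its estimate with its standard error, reclassifies,
#' and tallies quadrant proportions. The mean and standard deviation of each
#' quadrant's proportion across resamples quantify the classification and its
#' uncertainty.
#'
#' The fermentation and respiration draws are independent by default: the
#' replicate-splitting rule of [decompose_performances()] removes the dominant
#' shared-noise term. A correlation can be supplied for sensitivity checks
#' (per-mutant `cov_fer_res` columns are then honoured too).
#'
#' @param deltas Tibble with columns `fer`, `res`, `se_fer`, `se_res`
#'   (optionally `cov_fer_res`).
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed; fixing it makes the output bitwise reproducible.
#' @param correlation Correlation between the fermentation and respiration
#'   errors of a mutant (default 0).
#' @return An object of class `quadrant_resample`: list with `summary` (tibble
#'   of quadrant, point/mean/sd proportion), `draws` (B x 4 matrix of
#'   per-resample proportions), `B`, `n`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' d <- tibble::tibble(fer = c(0.01, -0.002), res = c(0.02, 0.015),
#'                     se_fer = 0.002, se_res = 0.002)
#' resample_proportions(d, B = 100, seed = 1)
#' @export
resample_proportions <- function(deltas, B = 1000, seed = NULL,
                                 correlation = 0) {
  deltas <- tibble::as_tibble(deltas)
  stopifnot(B >= 1, all(is.finite(deltas$se_fer)), all(is.finite(deltas$se_res)))
  if (!is.null(seed)) set.seed(seed)
  draws <- .resample_quadrant_props(deltas, B, correlation)
  point <- as.vector(prop.table(table(.quadrant_of(deltas$fer, deltas$res))))
  structure(
    list(
      summary = tibble::tibble(
        quadrant = .quadrant_levels,
        point = point,
        mean = as.numeric(colMeans(draws)),
        sd = as.numeric(apply(draws, 2, stats::sd))
      ),
      draws = draws,
      B = B,
      n = nrow(deltas)
    ),
    class = "quadrant_resample"
  )
}

# B x 4 matrix of quadrant proportions, one row per resample
.resample_quadrant_props <- function(deltas, B, correlation = 0) {
  n <- nrow(deltas)
  rho <- if ("cov_fer_res" %in% names(deltas) && correlation == 0) {
    deltas$cov_fer_res / (deltas$se_fer * deltas$se_res)
  } else {
    rep(correlation, n)
  }
  rho[!is.finite(rho)] <- 0
  draws <- matrix(0, nrow = B, ncol = 4,
                  dimnames = list(NULL, .quadrant_levels))
  for (b in seq_len(B)) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    fer <- deltas$fer + deltas$se_fer * z1
    res <- deltas$res + deltas$se_res * z2
    draws[b, ] <- tabulate(.quadrant_of(fer, res), 4L) / n
  }
  draws
}

#' @export
print.quadrant_resample <- function(x, ...) {
  cat("<quadrant_resample> ", x$n, " mutants, ", x$B, " resamples\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Resampling test for a difference in quadrant proportions
#'
#' Tests whether the proportion of group A mutants in a quadrant (by default
#' `"both-improve"`) is lower than that of group B, by drawing paired
#' measurement-error resamples of both groups and counting how often the
#' ordering fails. The p-value is the fraction of resamples with
#' `proportion(A) >= proportion(B)`, with add-one smoothing: `p = (1 + #fail)
#' / (B + 1)`, so the smallest attainable p is `1 / (B + 1)`.
#'
#' @param a,b Performance-change tibbles for the two groups (columns as in
#'   [resample_proportions()]).
#' @param quadrant Quadrant whose proportion is compared.
#' @param B Number of paired resamples.
#' @param seed Integer seed.
#' @return One-row tibble: per-group mean proportions, `p_value`, `B`.
#' @examples
#' a <- tibble::tibble(fer = -0.01, res = 0.02, se_fer = 1e-4, se_res = 1e-4)
#' b <- tibble::tibble(fer = 0.01, res = 0.02, se_fer = 1e-4, se_res = 1e-4)
#' resampling_difference_test(a, b, B = 199, seed = 1)
#' @export
resampling_difference_test <- function(a, b, quadrant = "both-improve",
                                       B = 1000, seed = NULL) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  quadrant <- match.arg(quadrant, .quadrant_levels)
  if (!is.null(seed)) set.seed(seed)
  pa <- .resample_quadrant_props(tibble::as_tibble(a), B)[, quadrant]
  pb <- .resample_quadrant_props(tibble::as_tibble(b), B)[, quadrant]
  tibble::tibble(
    quadrant = quadrant,
    prop_a = mean(pa),
    prop_b = mean(pb),
    p_value = (1 + sum(pa >= pb)) / (B + 1),
    B = B
  )
}

#' Exact two-sided Fisher test for a 2x2 contingency table
#'
#' Exact test of association in a 2x2 table by the point-probability method:
#' with margins fixed, the two-sided p-value sums the hypergeometric
#' probabilities of every table whose probability does not exceed that of the
#' observed table. The odds ratio is the sample odds ratio `ad/bc` (with 0 and
#' Inf handled).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`. Alternatively `a` may be a 2x2 matrix.
#' @return One-row tibble: `odds_ratio`, `p_value`.
#' @examples
#' # both-improvers vs respiration-only improvers, by stationary improvement
#' fisher_exact_2x2(7, 102, 70, 127)
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("a margin of the table is zero; the test is undefined", call. = FALSE)
  }
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- stats::dhyper(support, r1, r2, c1, log = TRUE)
  obs <- logp[support == a]
  # tables at most a hair more probable than the observed one count as tied
  p <- sum(exp(logp)[logp <= obs + 1e-7])
  or <- (a * d) / (b * c)
  tibble::tibble(odds_ratio = or, p_value = min(p, 1))
}

#' Partial correlation of two variables controlling for a third
#'
#' Pearson correlation between `x` and `y` after removing the linear effect
#' of `z` from both (equivalently, the correlation of the ordinary
#' least-squares residuals of `x` on `z` and `y` on `z`). Used to ask whether
#' one growth-phase performance contributes to fitness in the evolution
#' condition beyond what the fitness-measurement assay already explains.
#' The p-value is from the t distribution with `n - 3` degrees of freedom.
#'
#' @param x,y,z Equal-length numeric vectors, length at least 4.
#' @return One-row tibble: `r`, `statistic` (t), `df`, `p_value`, `n`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- -z + rnorm(50)
#' partial_correlation(x, y, z)
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete observations", call. = FALSE)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  denom <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (!is.finite(denom) || denom < 1e-8) {
    stop("zero residual variance after controlling for z", call. = FALSE)
  }
  r <- (rxy - rxz * ryz) / denom
  df <- n - 3L
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r = r,
    statistic = tstat,
    df = df,
    p_value = 2 * stats::pt(-abs(tstat), df),
    n = n
  )
}

#' Two-standard-error significance flag
#'
#' The convention used when calling a performance change real: significant iff
#' `|delta| >= k * se`, with `k = 2` (roughly an FDR of 0.05 in this design).
#'
#' @param delta Estimate(s).
#' @param se Standard error(s), non-negative.
#' @param k Multiplier (default 2).
#' @return Logical vector.
#' @examples
#' flag_significant(c(0.01, 0.005), se = 0.004)
#' @export
flag_significant <- function(delta, se, k = 2) {
  stopifnot(all(se >= 0))
  abs(delta) >= k * se
}

#' Cluster parameters for mutant-class assignment
#'
#' Builds the per-condition fitness centroids of the neutral-haploid and
#' pure-diploid reference clusters from labelled examples, for use by
#' [assign_mutant_class()]. Membership is later judged in SE-normalized units
#' (a Mahalanobis-style distance with a diagonal scale).
#'
#' @param fits Tibble of fitness estimates with columns `lineage`,
#'   `condition`, `s`, `se` and `class_label` giving the known cluster
#'   (`"neutral-haploid"` or `"pure-diploid"`) of reference lineages.
#' @return Tibble `class`, `condition`, `centroid`, `scale` where `scale` is
#'   the per-condition spread (sd across reference lineages, floored by the
#'   median SE).
#' @export
cluster_params <- function(fits) {
  fits |>
    tibble::as_tibble() |>
    dplyr::filter(.data$class_label %in% c("neutral-haploid", "pure-diploid")) |>
    dplyr::group_by(class = .data$class_label, .data$condition) |>
    dplyr::summarise(
      centroid = mean(.data$s),
      scale = max(stats::sd(.data$s), stats::median(.data$se), na.rm = TRUE),
      .groups = "drop"
    )
}

#' Assign mutants to ploidy/fitness classes
#'
#' Combines the benomyl ploidy call with clustering on fitness across assay
#' conditions. A mutant whose fitness vector lies within `radius`
#' SE-normalized units of the pure-diploid centroid in every condition is a
#' pure diploid even if benomyl called it haploid (the cluster overrides the
#' plate assay); likewise for the neutral-haploid cluster. Diploids outside
#' the pure-diploid cluster carry extra beneficial mutations and are
#' high-fitness diploids; haploids outside the neutral cluster are adaptive
#' haploids.
#'
#' Mutants of the gene `PAB1` are benomyl-sensitive and mis-called diploid by
#' the plate assay; they are overridden by their respiration performance
#' relative to the parental strain: less than 0.06 per hour means adaptive
#' haploid, at or above 0.06 means high-fitness diploid.
#'
#' @param mutants Tibble with columns `lineage`, `ploidy_call` (`"haploid"`
#'   or `"diploid"`), optionally `gene` and `d_res` (respiration performance
#'   relative to parent, required for the PAB1 rule).
#' @param fits Fitness estimates (`lineage`, `condition`, `s`) across the
#'   assay conditions, covering every mutant.
#' @param params Cluster centroids/scales from [cluster_params()].
#' @param radius Cluster membership radius in SE-normalized units (default 3).
#' @param pab1_res_cutoff Respiration-performance cutoff of the PAB1 override
#'   (default 0.06 per hour).
#' @return `mutants` with `mutant_class` appended: one of `"neutral-haploid"`,
#'   `"pure-diploid"`, `"adaptive-haploid"`, `"high-fitness-diploid"`.
#' @export
assign_mutant_class <- function(mutants, fits, params, radius = 3,
                                pab1_res_cutoff = 0.06) {
  mutants <- tibble::as_tibble(mutants)
  fits <- tibble::as_tibble(fits)
  missing_fit <- setdiff(mutants$lineage, fits$lineage)
  if (length(missing_fit) > 0L) {
    stop("no fitness vector for lineage(s): ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  }
  in_cluster <- function(lin, cls) {
    p <- dplyr::filter(params, .data$class == cls)
    v <- dplyr::inner_join(dplyr::filter(fits, .data$lineage == lin), p,
                           by = "condition")
    nrow(v) > 0L && all(abs(v$s - v$centroid) / v$scale <= radius)
  }
  cls <- purrr::map_chr(seq_len(nrow(mutants)), function(i) {
    lin <- mutants$lineage[[i]]
    gene <- if ("gene" %in% names(mutants)) mutants$gene[[i]] else NA_character_
    if (!is.na(gene) && gene == "PAB1") {
      d_res <- mutants$d_res[[i]]
      return(if (d_res < pab1_res_cutoff) "adaptive-haploid"
             else "high-fitness-diploid")
    }
    if (in_cluster(lin, "neutral-haploid")) return("neutral-haploid")
    if (in_cluster(lin, "pure-diploid")) return("pure-diploid")
    if (mutants$ploidy_call[[i]] == "diploid") "high-fitness-diploid"
    else "adaptive-haploid"
  })
  dplyr::mutate(mutants, mutant_class = cls)
}
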