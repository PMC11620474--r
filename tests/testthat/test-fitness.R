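test_that("neutral-pool mean fitness matches hand-computed log declines", {
  # summed neutral frequency halves over one cycle -> xbar = log 2
  counts <- fixture_counts(c(400, 9600), c(200, 9800),
                           classes = c("neutral", "adaptive"))
  mf <- mean_fitness_from_neutrals(counts, pseudocount = 0)
  expect_equal(mf$xbar, log(2))
  # constant neutral frequency -> xbar = 0
  counts2 <- fixture_counts(c(400, 9600), c(400, 9600),
                            classes = c("neutral", "adaptive"))
  expect_equal(mean_fitness_from_neutrals(counts2, pseudocount = 0)$xbar, 0)
  # a table with no neutral class is unusable
  counts3 <- fixture_counts(c(1, 2), c(1, 2), classes = c("adaptive", "adaptive"))
  expect_error(mean_fitness_from_neutrals(counts3), "no neutral")
})

test_that("lineage fitness is the mean-fitness-corrected log-frequency change", {
  mf_ln2 <- tibble::tibble(condition = "2D", replicate = 1, t0 = 0, t1 = 1,
                           xbar = log(2), se = 0)
  # frequency constant across one cycle -> s equals xbar
  counts <- fixture_counts(c(100, 9900), c(100, 9900),
                           classes = c("adaptive", "ancestor"))
  lf <- lineage_fitness(counts, mf_ln2, pseudocount = 0)
  expect_equal(lf$s[lf$barcode == "b01"], log(2))
  # frequency doubles with xbar = 0 -> s = log 2
  mf0 <- dplyr::mutate(mf_ln2, xbar = 0)
  counts2 <- fixture_counts(c(100, 9900), c(200, 9800),
                            classes = c("adaptive", "ancestor"))
  lf2 <- lineage_fitness(counts2, mf0, pseudocount = 0)
  expect_equal(lf2$s[lf2$barcode == "b01"],
               log((200 / 10000) / (100 / 10000)))
})

test_that("zero endpoints follow the pseudocounted closed form and are flagged", {
  depth <- 1e6
  counts <- fixture_counts(c(0, 300, depth - 300), c(0, 300, depth - 300),
                           classes = c("adaptive", "neutral", "ancestor"))
  mf <- tibble::tibble(condition = "2D", replicate = 1, t0 = 0, t1 = 1,
                       xbar = 0.1, se = 0.002)
  lf <- lineage_fitness(counts, mf, pseudocount = 0.5)
  row <- lf[lf$barcode == "b01", ]
  # closed form: f = (n + 0.5) / (depth + 0.5 * n_lineages), s = dlog f + xbar
  f <- (0 + 0.5) / (depth + 0.5 * 3)
  expect_equal(row$s, log(f / f) + 0.1)
  expect_true(is.finite(row$s))
  expect_equal(row$flag, "zero-endpoints")
  expect_equal(row$se, sqrt(2 * (1 / 0.5) + 0.002^2))
})

test_that("fitness estimates are invariant to uniform count rescaling", {
  counts <- fixture_counts(c(120, 480, 9400), c(80, 470, 9450),
                           classes = c("adaptive", "neutral", "ancestor"))
  mf <- mean_fitness_from_neutrals(counts, pseudocount = 0)
  lf <- lineage_fitness(counts, mf, pseudocount = 0)
  scaled <- dplyr::mutate(counts, count = count * 7L)
  mfs <- mean_fitness_from_neutrals(scaled, pseudocount = 0)
  lfs <- lineage_fitness(scaled, mfs, pseudocount = 0)
  expect_equal(lfs$s, lf$s)
})

test_that("interval selection follows the ancestor threshold and the 2-Day cap", {
  mk <- function(fracs, condition) {
    purrr::map_dfr(seq_along(fracs) - 1L, function(t) {
      tibble::tibble(
        barcode = c("anc", "rest"), class = c("ancestor", "adaptive"),
        condition = condition, replicate = 1, timepoint = t,
        count = c(round(1e4 * fracs[t + 1L]), round(1e4 * (1 - fracs[t + 1L])))
      )
    })
  }
  # declining ancestor: only the first interval starts above 80%
  iv <- select_intervals(mk(c(0.91, 0.60, 0.30), "1D"))
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$t0, iv$t1), c(0, 1))
  # 2-Day condition is capped to (0,1) even when the ancestor stays dominant
  iv2 <- select_intervals(mk(c(0.95, 0.94, 0.93), "2D"))
  expect_equal(nrow(iv2), 1L)
  expect_equal(c(iv2$t0, iv2$t1), c(0, 1))
  # threshold 0 admits every interval outside the 2-Day cap
  iv3 <- select_intervals(mk(c(0.91, 0.60, 0.30), "1D"),
                          ancestor_threshold = 0)
  expect_equal(nrow(iv3), 2L)
  expect_warning(select_intervals(mk(c(0.5, 0.4), "1D")), "no interval")
})

test_that("depleted ancestor reads are un-depleted before thresholding", {
  # 94% of cells but 1% read retention: raw read fraction ~13%
  counts <- fixture_counts(c(94e4 * 0.01, 6e4), c(94e4 * 0.01, 6e4),
                           classes = c("ancestor", "adaptive"),
                           condition = "1D")
  expect_warning(select_intervals(counts), "no interval")
  iv <- select_intervals(counts, ancestor_read_retention = 0.01)
  expect_equal(nrow(iv), 1L)
  expect_gt(iv$ancestor_fraction, 0.9)
})

test_that("mean-fitness estimator recovers a known neutral decline rate", {
  # population engineered so neutral frequencies decline by 0.5 per 2-Day
  # cycle: half the culture carries s with 0.5 + 0.5 exp(s) = exp(0.5)
  s_a <- log(2 * exp(0.5) - 1)
  prof <- dplyr::bind_rows(
    tibble::tibble(lineage = "anc", class = "ancestor",
                   fer = 0, res = 0, sta = 0),
    tibble::tibble(lineage = sprintf("n%02d", 1:60), class = "neutral",
                   fer = 0, res = 0, sta = 0),
    tibble::tibble(lineage = "big", class = "adaptive",
                   fer = 0, res = s_a / 28, sta = 0)
  )
  hits <- vapply(1:100, function(seed) {
    sim <- simulate_fitness_assay(
      prof, regimes = default_regimes("2D"),
      n_transfers = 1, replicates = 1,
      composition = c(ancestor = 0.25, neutral = 0.25, adaptive = 0.5),
      read_depth = 2e4, bottleneck_size = 2e4,
      ancestor_read_retention = 1, seed = seed
    )
    mf <- mean_fitness_from_neutrals(sim$counts, bottleneck = 2e4)
    abs(mf$xbar - 0.5) < 3 * mf$se
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("mean-fitness correction centres neutral lineages on zero", {
  # neutral estimates carry a small negative log-count bias of order
  # 1/(2 * cells per lineage) from drift through the transfer bottleneck;
  # "centred on zero" means that bias is negligible against the per-lineage
  # measurement error the estimator itself reports
  prof <- fixture_profiles(n_neutral = 60, n_adaptive = 40)
  out <- purrr::map_dfr(1:30, function(seed) {
    sim <- simulate_fitness_assay(
      prof, regimes = default_regimes("2D"), n_transfers = 1,
      replicates = 1, read_depth = 1e5, bottleneck_size = 1e6, seed = seed
    )
    mf <- mean_fitness_from_neutrals(sim$counts, bottleneck = 1e6,
                                     ancestor_read_retention = 0.01)
    lf <- lineage_fitness(sim$counts, mf, bottleneck = 1e6,
                          ancestor_read_retention = 0.01)
    neu <- lf[lf$class == "neutral", ]
    tibble::tibble(mean_s = mean(neu$s), med_se = stats::median(neu$se))
  })
  expect_lt(abs(mean(out$mean_s)), 0.1 * stats::median(out$med_se))
})

test_that("frequency-dependence diagnostic reports percent deviations", {
  fits <- tibble::tibble(
    barcode = rep(c("m1", "m2"), each = 3),
    condition = "1D",
    t0 = rep(0:2, 2), t1 = rep(1:3, 2),
    s = c(1, 1, 1, 1, 0.5, 0.25),
    se = 0.01
  )
  counts <- purrr::map_dfr(0:3, function(t) {
    tibble::tibble(barcode = c("m1", "a"), class = c("neutral", "adaptive"),
                   condition = "1D", replicate = 1, timepoint = t,
                   count = c(900 - 100 * t, 100 + 100 * t))
  })
  diag <- frequency_dependence_diagnostic(fits, counts)
  m1 <- diag[diag$barcode == "m1", ]
  expect_equal(m1$deviation_pct, c(0, 0))
  m2 <- diag[diag$barcode == "m2", ]
  expect_equal(m2$deviation_pct, c(-50, -75))
  # adaptive fraction is read off the interval-start composition
  expect_equal(diag$adaptive_fraction[diag$t0 == 1], rep(0.2, 2))
  # zero-reference mutants are flagged, not silently dropped
  fits0 <- dplyr::mutate(fits, s = ifelse(barcode == "m2" & t0 == 0, 0, s))
  d0 <- frequency_dependence_diagnostic(fits0, counts)
  expect_true(all(is.na(d0$deviation_pct[d0$barcode == "m2"])))
  expect_true(all(d0$flag[d0$barcode == "m2"] == "zero-reference"))
})

test_that("replicate pooling is inverse-variance weighted", {
  fits <- tibble::tibble(
    barcode = "m", condition = "2D", replicate = 1:2, t0 = 0, t1 = 1,
    s = c(1, 2), se = c(0.1, 0.2)
  )
  pooled <- pool_replicates(fits)
  w <- 1 / c(0.1, 0.2)^2
  expect_equal(pooled$s, sum(w * c(1, 2)) / sum(w))
  expect_equal(pooled$se, sqrt(1 / sum(w)))
  expect_equal(pooled$n_replicates, 2L)
})
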