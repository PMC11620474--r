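test_that("quadrant calls treat zero as non-improvement", {
  q <- classify_quadrant(tibble::tibble(
    fer = c(0.01, -0.004, 0, -0.01, 0.01),
    res = c(0.02, 0.02, 0.02, -0.02, 0)
  ))
  expect_equal(as.character(q$quadrant),
               c("both-improve", "resp-only", "resp-only", "neither",
                 "ferm-only"))
})

test_that("resampled proportions are deterministic, sum to one, and concentrate", {
  d <- withr::with_seed(1, tibble::tibble(
    fer = stats::rnorm(50, 0, 0.01), res = stats::rnorm(50, 0, 0.01),
    se_fer = 0.002, se_res = 0.002
  ))
  a <- resample_proportions(d, B = 200, seed = 99)
  b <- resample_proportions(d, B = 200, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_equal(rowSums(a$draws), rep(1, 200))
  # estimates far from the axes leave nothing to resampling uncertainty
  far <- tibble::tibble(fer = c(0.05, -0.05), res = c(0.05, 0.05),
                        se_fer = 0.001, se_res = 0.001)
  rf <- resample_proportions(far, B = 200, seed = 1)
  expect_equal(rf$summary$sd, rep(0, 4))
  expect_equal(rf$summary$mean, rf$summary$point)
})

test_that("a single borderline mutant splits along the zero axis", {
  one <- tibble::tibble(fer = 0, res = 0.05, se_fer = 0.003, se_res = 0.001)
  r <- resample_proportions(one, B = 4000, seed = 7)
  p_both <- r$summary$mean[r$summary$quadrant == "both-improve"]
  expect_equal(p_both, 0.5, tolerance = 0.05)
  # resampling SD converges to the binomial/orthant closed form
  expect_equal(r$summary$sd[r$summary$quadrant == "both-improve"],
               sqrt(0.5 * 0.5), tolerance = 0.05)
})

test_that("the proportion-difference resampling test separates and calibrates", {
  same <- withr::with_seed(31, tibble::tibble(
    fer = stats::rnorm(40, 0, 0.002), res = stats::rnorm(40, 0.01, 0.002),
    se_fer = 0.002, se_res = 0.002
  ))
  p_same <- resampling_difference_test(same, same, B = 400, seed = 3)$p_value
  expect_gt(p_same, 0.2)
  expect_lt(p_same, 0.8)
  a <- tibble::tibble(fer = rep(-0.05, 10), res = 0.05, se_fer = 0.001,
                      se_res = 0.001)
  b <- tibble::tibble(fer = rep(0.05, 10), res = 0.05, se_fer = 0.001,
                      se_res = 0.001)
  out <- resampling_difference_test(a, b, B = 400, seed = 3)
  expect_equal(out$p_value, 1 / 401)
})

test_that("the exact 2x2 test agrees with full enumeration for all small margins", {
  worst <- 0
  for (n in c(4, 9, 17, 24)) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        a_min <- max(0, c1 - (n - r1))
        a_max <- min(r1, c1)
        for (a in a_min:a_max) {
          b <- r1 - a; c <- c1 - a; d <- n - r1 - c
          worst <- max(worst, abs(fisher_exact_2x2(a, b, c, d)$p_value -
                                    fisher_enum_oracle(a, b, c, d)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("the exact 2x2 test matches known values and the reference routine", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p_value, 1 / 3)
  tables <- withr::with_seed(8, purrr::map(1:25, function(i) {
    matrix(stats::rpois(4, sample(c(3, 20, 80), 1)) + 1, 2)
  }))
  for (m in tables) {
    expect_equal(fisher_exact_2x2(m)$p_value,
                 stats::fisher.test(m)$p.value,
                 tolerance = 1e-8)
  }
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("partial correlation matches the residual-regression oracle", {
  withr::with_seed(15, {
    z <- stats::rnorm(60)
    x <- 0.5 * z + stats::rnorm(60)
    y <- -0.3 * z + 0.4 * x + stats::rnorm(60)
  })
  pc <- partial_correlation(x, y, z)
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  oracle <- stats::cor(rx, ry)
  expect_equal(pc$r, oracle, tolerance = 1e-10)
  t_or <- oracle * sqrt((60 - 3) / (1 - oracle^2))
  expect_equal(pc$p_value, 2 * stats::pt(-abs(t_or), 57), tolerance = 1e-10)
  # y identical to x: perfect partial correlation
  expect_equal(partial_correlation(x, x + 0, z)$r, 1)
  # x independent of y given z: mostly null across seeds
  hits <- purrr::map_lgl(1:20, function(seed) {
    withr::with_seed(seed, {
      z <- stats::rnorm(500); x <- stats::rnorm(500); y <- z + stats::rnorm(500)
    })
    out <- partial_correlation(x, y, z)
    abs(out$r) < 0.1 & out$p_value > 0.05
  })
  expect_gte(mean(hits), 0.9)
  expect_error(partial_correlation(1:3, 1:3, 1:3), "at least 4")
  expect_error(partial_correlation(1:10, 1:10 * 2, 1:10), "zero residual")
})

test_that("significance flags use the k-standard-error rule", {
  expect_true(flag_significant(0.01, 0.004))
  expect_false(flag_significant(0.005, 0.004))
  expect_true(flag_significant(0.001, 0))      # zero error, nonzero effect
  expect_equal(flag_significant(c(0.01, 0.005), c(0.004, 0.004)),
               c(TRUE, FALSE))
  expect_error(flag_significant(1, -0.1), "se")
})

test_that("mutant classes combine clusters, benomyl calls and the PAB1 rule", {
  conditions <- c("1D", "2D")
  ref_fits <- dplyr::bind_rows(
    tidyr::expand_grid(lineage = sprintf("nh%d", 1:5), condition = conditions) |>
      dplyr::mutate(s = 0, se = 0.02, class_label = "neutral-haploid"),
    tidyr::expand_grid(lineage = sprintf("pd%d", 1:5), condition = conditions) |>
      dplyr::mutate(s = c(0.2, 0.6)[match(condition, conditions)], se = 0.02,
                    class_label = "pure-diploid")
  )
  ref_fits$s <- ref_fits$s + withr::with_seed(2, stats::rnorm(nrow(ref_fits), 0, 0.01))
  params <- cluster_params(ref_fits)
  expect_equal(nrow(params), 4L)
  fits <- dplyr::bind_rows(
    tibble::tibble(lineage = "m_neut", condition = conditions, s = c(0.01, -0.01)),
    tibble::tibble(lineage = "m_dip", condition = conditions, s = c(0.21, 0.59)),
    tibble::tibble(lineage = "m_adapt", condition = conditions, s = c(0.9, 1.8)),
    tibble::tibble(lineage = "m_hifit", condition = conditions, s = c(0.8, 1.9)),
    tibble::tibble(lineage = "m_pab1a", condition = conditions, s = c(0.5, 1.0)),
    tibble::tibble(lineage = "m_pab1d", condition = conditions, s = c(0.5, 1.0))
  )
  mutants <- tibble::tibble(
    lineage = c("m_neut", "m_dip", "m_adapt", "m_hifit", "m_pab1a", "m_pab1d"),
    ploidy_call = c("haploid", "haploid", "haploid", "diploid",
                    "diploid", "diploid"),
    gene = c(NA, NA, NA, NA, "PAB1", "PAB1"),
    d_res = c(NA, NA, NA, NA, 0.03, 0.08)
  )
  out <- assign_mutant_class(mutants, fits, params)
  expect_equal(out$mutant_class,
               c("neutral-haploid",
                 "pure-diploid",        # cluster overrides the benomyl call
                 "adaptive-haploid",    # haploid far above the neutral cluster
                 "high-fitness-diploid",
                 "adaptive-haploid",    # PAB1 with d_res < 0.06
                 "high-fitness-diploid" # PAB1 with d_res >= 0.06
               ))
  expect_error(assign_mutant_class(mutants, fits[fits$lineage != "m_neut", ],
                                   params),
               "no fitness vector")
})
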