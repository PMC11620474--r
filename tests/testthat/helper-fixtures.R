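# shared in-code fixtures for the test suite

# a small pooled-assay population: dominating ancestor, neutral pools,
# adaptive lineages with known phase profiles
fixture_profiles <- function(n_neutral = 120, n_adaptive = 100, seed = 2) {
  withr::with_seed(seed, dplyr::bind_rows(
    tibble::tibble(lineage = "anc", class = "ancestor",
                   fer = 0, res = 0, sta = 0),
    tibble::tibble(lineage = sprintf("n%03d", seq_len(n_neutral)),
                   class = "neutral", fer = 0, res = 0, sta = 0),
    tibble::tibble(lineage = sprintf("a%03d", seq_len(n_adaptive)),
                   class = "adaptive",
                   fer = stats::runif(n_adaptive, 0, 0.02),
                   res = stats::runif(n_adaptive, 0, 0.03),
                   sta = stats::runif(n_adaptive, -0.01, 0))
  ))
}

# deterministic two-timepoint count table for hand-checked estimators
fixture_counts <- function(counts0, counts1, classes,
                           condition = "2D", replicate = 1) {
  barcodes <- sprintf("b%02d", seq_along(counts0))
  dplyr::bind_rows(
    tibble::tibble(barcode = barcodes, class = classes, condition = condition,
                   replicate = replicate, timepoint = 0L, count = counts0),
    tibble::tibble(barcode = barcodes, class = classes, condition = condition,
                   replicate = replicate, timepoint = 1L, count = counts1)
  )
}

# random phase profiles spanning the performance range of this system
random_profiles <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    lineage = sprintf("m%04d", seq_len(n)),
    fer = stats::runif(n, -0.02, 0.05),
    res = stats::runif(n, -0.02, 0.05),
    sta = stats::runif(n, -0.04, 0.02)
  ))
}

# exhaustive-enumeration oracle for the two-sided Fisher test
# (choose() arithmetic, independent of dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
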