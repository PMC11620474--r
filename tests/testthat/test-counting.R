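spec <- library_spec()
wl <- withr::with_seed(1, random_barcodes(20))

small_counts <- function(n_samples = 3, per = 40, seed = 7) {
  withr::with_seed(seed, tidyr::expand_grid(
    sample = sprintf("s%d", seq_len(n_samples)),
    barcode = wl[1:8]
  ) |>
    dplyr::mutate(count = stats::rpois(dplyr::n(), per) + 1L))
}

test_that("error-free reads roundtrip exactly through extraction and counting", {
  sc <- small_counts()
  sheet <- build_sample_sheet(unique(sc$sample), spec)
  reads <- generate_reads(sc, spec, sheet, seed = 1)
  fields <- extract_read_fields(reads, spec)
  expect_true(all(fields$valid))
  demux <- demultiplex(fields, sheet)
  expect_true(all(demux$status == "assigned"))
  expect_equal(demux$sample, demux$sample_truth)
  counted <- count_barcodes(demux, wl)
  merged <- dplyr::full_join(sc, counted, by = c("sample", "barcode"))
  expect_equal(merged$count.x, merged$count.y)
  expect_equal(attr(counted, "n_discarded"), 0L)
})

test_that("UMI deduplication collapses PCR duplicates back to molecule counts", {
  sc <- small_counts(n_samples = 2, per = 25)
  sheet <- build_sample_sheet(unique(sc$sample), spec)
  reads <- generate_reads(sc, spec, sheet, duplication_rate = 1, seed = 3)
  expect_gt(nrow(reads), sum(sc$count))  # duplicates present
  counted <- extract_read_fields(reads, spec) |>
    demultiplex(sheet) |>
    count_barcodes(wl)
  merged <- dplyr::full_join(sc, counted, by = c("sample", "barcode"))
  expect_equal(merged$count.x, merged$count.y)   # UMIs deduplicate
  expect_true(any(merged$reads > merged$count.y)) # raw reads exceed molecules
})

test_that("anchors tolerate substitutions and report failure reasons", {
  bc <- wl[1]
  mk <- function(seq) tibble::tibble(illumina_index = "i701", sequence = seq)
  umi <- "ACGTACGT"; inl <- spec$inline_indices[1]
  exact <- paste0(umi, inl, spec$anchor5, bc, spec$anchor3)
  f <- extract_read_fields(mk(exact), spec)
  expect_true(f$valid)
  expect_equal(c(f$umi, f$inline_index, f$barcode), c(umi, inl, bc))
  # one substitution inside the 5' anchor leaves the fields unchanged
  a5 <- spec$anchor5
  substr(a5, 5, 5) <- ifelse(substr(a5, 5, 5) == "A", "C", "A")
  f1 <- extract_read_fields(mk(paste0(umi, inl, a5, bc, spec$anchor3)), spec)
  expect_true(f1$valid)
  expect_equal(f1$barcode, bc)
  # a missing 3' anchor is a missing-anchor failure
  f2 <- extract_read_fields(mk(paste0(umi, inl, spec$anchor5, bc)), spec)
  expect_false(f2$valid)
  expect_equal(f2$failure_reason, "missing-anchor")
  # truncated upstream of the 5' anchor is a short read
  f3 <- extract_read_fields(mk(paste0(inl, spec$anchor5, bc, spec$anchor3)),
                            spec)
  expect_equal(f3$failure_reason, "short-read")
  # an inline index outside the library set is a bad index
  f4 <- extract_read_fields(mk(paste0(umi, "TTTTTTT", spec$anchor5, bc,
                                      spec$anchor3)), spec)
  expect_equal(f4$failure_reason, "bad-index")
})

test_that("demultiplexing separates assigned, hopped and unmatched reads", {
  sheet <- tibble::tibble(sample = c("s1", "s2"),
                          illumina_index = c("i701", "i702"),
                          inline_index = spec$inline_indices[1:2])
  mk <- function(illumina, inline) {
    tibble::tibble(illumina_index = illumina, inline_index = inline,
                   umi = "ACGTACGT", barcode = wl[1], valid = TRUE,
                   failure_reason = NA_character_)
  }
  d <- demultiplex(dplyr::bind_rows(
    mk("i701", spec$inline_indices[1]),  # listed combination
    mk("i701", spec$inline_indices[2]),  # components known, pair absent
    mk("i799", spec$inline_indices[1])   # unknown Illumina index
  ), sheet)
  expect_equal(d$status, c("assigned", "hopped", "unmatched"))
  expect_equal(d$sample, c("s1", NA, NA))
  expect_error(demultiplex(mk("i701", spec$inline_indices[1]),
                           dplyr::bind_rows(sheet, sheet)),
               "duplicate index combination")
})

test_that("injected index swaps are tallied as hopped at the injected rate", {
  sc <- small_counts(n_samples = 4, per = 60, seed = 10)
  # distinct Illumina indices so a swapped index always breaks the pairing
  sheet <- tibble::tibble(sample = unique(sc$sample),
                          illumina_index = sprintf("i70%d", 1:4),
                          inline_index = spec$inline_indices[1:4])
  reads <- generate_reads(sc, spec, sheet, seed = 11)
  # swap the Illumina index of ~1% of reads to another sample's index whose
  # inline pairing differs, mimicking template swaps on the flow cell
  n <- nrow(reads)
  withr::with_seed(12, {
    swap <- stats::runif(n) < 0.01
    reads$illumina_index[swap] <-
      sheet$illumina_index[match(reads$sample[swap], sheet$sample) %% 4 + 1]
  })
  d <- extract_read_fields(reads, spec) |> demultiplex(sheet)
  n_hop <- sum(d$status == "hopped")
  ci <- stats::binom.test(n_hop, n, p = 0.01)$conf.int
  expect_true(ci[1] <= 0.013 && ci[2] >= 0.007)
  # conservation: every read lands in exactly one tally
  expect_equal(sum(d$status %in% c("assigned", "hopped", "unmatched",
                                   "invalid")), n)
})

test_that("whitelist matching assigns unique neighbours and discards ties", {
  expect_equal(match_whitelist(wl[3], wl), wl[3])
  # one substitution away from exactly one entry
  mut <- wl[4]
  substr(mut, 7, 7) <- ifelse(substr(mut, 7, 7) == "G", "T", "G")
  expect_equal(match_whitelist(mut, wl), wl[4])
  # equidistant from two entries at distance 2 -> discarded
  pair <- c("AAAAAAAAAA", "AAAAAAAATT")
  expect_true(is.na(match_whitelist("AAAAAAAAGC", pair,
                                    max_edit_distance = 2)))
  # beyond the radius -> discarded
  expect_true(is.na(match_whitelist(strrep("A", 26), wl)))
  expect_error(match_whitelist("A", character(0)), "empty whitelist")
  expect_error(match_whitelist("A", c("AA", "AA")), "distinct")
})

test_that("reads survive substitution noise at the expected assignment rate", {
  sc <- small_counts(n_samples = 2, per = 50, seed = 20)
  sheet <- build_sample_sheet(unique(sc$sample), spec)
  reads <- generate_reads(sc, spec, sheet, error_rate = 0.01, seed = 21)
  d <- extract_read_fields(reads, spec) |> demultiplex(sheet)
  assigned <- dplyr::filter(d, status == "assigned")
  matched <- match_whitelist(assigned$barcode, wl)
  frac_ok <- sum(!is.na(matched)) / nrow(reads)
  expect_gte(frac_ok, 0.95)
})

test_that("metagrid assignment applies the three thresholds in order", {
  wells <- dplyr::bind_rows(
    tibble::tibble(plate = 1, well = "A1", barcode = c("A", "B"),
                   count = c(200, 100)),
    tibble::tibble(plate = 1, well = "A2", barcode = c("A", "B"),
                   count = c(120, 30)),
    tibble::tibble(plate = 1, well = "A3", barcode = c("A", "B", "C"),
                   count = c(120, 115, 65)),
    tibble::tibble(plate = 1, well = "A4", barcode = c("A", "B"),
                   count = c(180, 120)),
    tibble::tibble(plate = 1, well = "A5", barcode = "A", count = 250),
    tibble::tibble(plate = 1, well = "A6", barcode = "A", count = 0)
  )
  out <- assign_wells(wells) |> dplyr::arrange(well)
  expect_equal(out$status, c("assigned", "low-reads", "low-majority",
                             "low-ratio", "assigned", "empty"))
  expect_equal(out$assigned_barcode, c("A", NA, NA, NA, "A", NA))
  # boundary semantics: 200 reads and 60% are inclusive, 1.5x is strict
  edge <- tibble::tibble(plate = 1, well = "E", barcode = c("A", "B"),
                         count = c(120, 80))
  eo <- assign_wells(edge)  # total 200, frac 0.6, ratio exactly 1.5
  expect_equal(eo$status, "low-ratio")
})

test_that("well calls are permutation invariant and match brute force", {
  plates <- withr::with_seed(31, purrr::map_dfr(1:60, function(w) {
    k <- sample(1:5, 1)
    tibble::tibble(plate = 1L, well = sprintf("W%02d", w),
                   barcode = sample(LETTERS, k),
                   count = stats::rpois(k, lambda = sample(c(20, 120, 400), 1)))
  }))
  out <- assign_wells(plates)
  brute <- plates |>
    dplyr::group_by(well) |>
    dplyr::group_map(function(df, key) {
      cnt <- sort(df$count, decreasing = TRUE)
      tot <- sum(cnt)
      top <- cnt[1]; second <- ifelse(length(cnt) > 1, cnt[2], 0)
      status <- if (tot == 0) "empty"
        else if (tot < 200) "low-reads"
        else if (top / tot < 0.6) "low-majority"
        else if (top <= 1.5 * second) "low-ratio"
        else "assigned"
      tibble::tibble(well = key$well, status = status)
    }) |>
    dplyr::bind_rows()
  expect_equal(dplyr::arrange(out[c("well", "status")], well),
               dplyr::arrange(brute, well))
  shuffled <- withr::with_seed(5, plates[sample(nrow(plates)), ])
  out2 <- assign_wells(shuffled)
  expect_equal(dplyr::arrange(out2, well), dplyr::arrange(out, well))
})

test_that("FASTQ files written by the generator read back unchanged", {
  sc <- small_counts(n_samples = 1, per = 10)
  reads <- generate_reads(sc, spec, seed = 2)
  tf <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, tf)
  back <- read_fastq(tf)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$read_id, reads$read_id)
})
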