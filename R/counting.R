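#' Extract UMI, inline index and barcode from amplicon reads
#'
#' Locates the two constant anchors of the amplicon layout (allowing up to
#' `max_anchor_mismatch` substitutions each), slices out the barcode between
#' them and the inline index and UMI upstream of the 5' anchor. Failures are
#' data, not exceptions: a read that cannot be parsed comes back with
#' `valid = FALSE` and a `failure_reason` of `"missing-anchor"` (either
#' anchor not found), `"short-read"` (not enough sequence upstream of the 5'
#' anchor or an empty barcode) or `"bad-index"` (inline index not in the
#' library's index set).
#'
#' @param reads Tibble with a `sequence` column (e.g. from [generate_reads()]
#'   or [read_fastq()]); other columns are carried through.
#' @param spec A [library_spec].
#' @param max_anchor_mismatch Substitutions tolerated per anchor (default 2).
#' @param max_inline_mismatch Substitutions tolerated in the inline index
#'   (default 1): an observed index is corrected to its unique nearest
#'   library index within this Hamming distance, as sequencers'
#'   demultiplexers do.
#' @return The input plus `umi`, `inline_index` (corrected to the library
#'   set), `barcode`, `valid`, `failure_reason`.
#' @export
extract_read_fields <- function(reads, spec = library_spec(),
                                max_anchor_mismatch = 2L,
                                max_inline_mismatch = 1L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("extract_read_fields() requires the Biostrings package", call. = FALSE)
  }
  reads <- tibble::as_tibble(reads)
  stopifnot("sequence" %in% names(reads))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  first_start <- function(anchor, after = NULL) {
    hits <- Biostrings::vmatchPattern(anchor, seqs,
                                      max.mismatch = max_anchor_mismatch)
    starts <- Biostrings::startIndex(hits)
    purrr::map2_int(starts, seq_along(seqs), function(st, i) {
      if (is.null(st)) return(NA_integer_)
      if (!is.null(after)) st <- st[st > after[[i]]]
      if (length(st) == 0L) NA_integer_ else st[[1L]]
    })
  }
  p5 <- first_start(spec$anchor5)
  end5 <- p5 + nchar(spec$anchor5) - 1L
  p3 <- first_start(spec$anchor3, after = ifelse(is.na(end5), 0L, end5))

  up_len <- spec$umi_length + spec$inline_length
  seq_chr <- reads$sequence
  inline <- substr(seq_chr, p5 - spec$inline_length, p5 - 1L)
  umi <- substr(seq_chr, p5 - up_len, p5 - spec$inline_length - 1L)
  barcode <- substr(seq_chr, end5 + 1L, p3 - 1L)
  inline <- .correct_inline(inline, spec$inline_indices, max_inline_mismatch)

  reason <- dplyr::case_when(
    is.na(p5) | is.na(p3) ~ "missing-anchor",
    p5 - up_len < 1L | p3 <= end5 + 1L ~ "short-read",
    is.na(inline) ~ "bad-index",
    .default = NA_character_
  )
  valid <- is.na(reason)
  dplyr::mutate(
    reads,
    umi = ifelse(valid, umi, NA_character_),
    inline_index = ifelse(valid, inline, NA_character_),
    barcode = ifelse(valid, barcode, NA_character_),
    valid = valid,
    failure_reason = reason
  )
}

# correct observed inline indices to the unique nearest library index within
# the given Hamming distance (indels are penalized out)
.correct_inline <- function(observed, index_set, max_mismatch) {
  uniq <- unique(observed)
  exact <- match(uniq, index_set)
  out <- index_set[exact]
  todo <- which(is.na(exact) & !is.na(uniq))
  if (length(todo) > 0L && max_mismatch > 0L) {
    d <- utils::adist(uniq[todo], index_set,
                      costs = list(ins = 100, del = 100, sub = 1))
    best <- apply(d, 1L, min)
    hit <- apply(d, 1L, which.min)
    ok <- best <= max_mismatch & rowSums(d == best) == 1L
    out[todo[ok]] <- index_set[hit[ok]]
  }
  out[match(observed, uniq)]
}

#' Demultiplex reads by (Illumina, inline) index combination
#'
#' Each sample owns a unique combination of Illumina and inline indices.
#' Reads whose combination appears in the sample sheet are assigned; reads
#' whose combination is absent but whose two indices each occur somewhere in
#' the sheet are the signature of index hopping on the sequencer and are
#' tallied as `"hopped"`; reads with an unknown index component are
#' `"unmatched"`. Invalid reads (see [extract_read_fields()]) keep status
#' `"invalid"`.
#'
#' @param fields Output of [extract_read_fields()] with an `illumina_index`
#'   column.
#' @param sample_sheet Tibble `sample`, `illumina_index`, `inline_index`
#'   with unique combinations.
#' @return `fields` plus `sample` (NA unless assigned) and `status`
#'   (`"assigned"`, `"hopped"`, `"unmatched"`, `"invalid"`).
#' @export
demultiplex <- function(fields, sample_sheet) {
  fields <- tibble::as_tibble(fields)
  sheet <- tibble::as_tibble(sample_sheet)
  stopifnot(all(c("illumina_index", "inline_index") %in% names(fields)))
  if ("sample" %in% names(fields)) {
    fields <- dplyr::rename(fields, sample_truth = "sample")
  }
  if (anyDuplicated(sheet[c("illumina_index", "inline_index")]) > 0L) {
    stop("duplicate index combination in sample sheet", call. = FALSE)
  }
  out <- dplyr::left_join(fields, sheet,
                          by = c("illumina_index", "inline_index"))
  dplyr::mutate(
    out,
    status = dplyr::case_when(
      !.data$valid ~ "invalid",
      !is.na(.data$sample) ~ "assigned",
      .data$illumina_index %in% sheet$illumina_index &
        .data$inline_index %in% sheet$inline_index ~ "hopped",
      .default = "unmatched"
    ),
    sample = dplyr::if_else(.data$status == "assigned", .data$sample,
                            NA_character_)
  )
}

#' Match observed barcodes to a whitelist by edit distance
#'
#' Assigns each observed barcode to its unique nearest whitelist entry within
#' `max_edit_distance` Levenshtein edits (indels allowed: amplicon indels
#' occur and the whitelist is sparse). Ties -- two entries at the same
#' minimal distance -- are discarded (`NA`), as is anything farther than the
#' radius.
#'
#' @param barcodes Character vector of observed barcodes.
#' @param whitelist Character vector of known barcodes (pairwise distinct).
#' @param max_edit_distance Assignment radius (default 2).
#' @return Character vector: the matched whitelist entry or `NA`.
#' @export
match_whitelist <- function(barcodes, whitelist, max_edit_distance = 2L) {
  if (length(whitelist) == 0L) stop("empty whitelist", call. = FALSE)
  if (anyDuplicated(whitelist) > 0L) {
    stop("whitelist entries must be pairwise distinct", call. = FALSE)
  }
  uniq <- unique(barcodes)
  exact <- match(uniq, whitelist)
  todo <- which(is.na(exact))
  assigned <- whitelist[exact]
  if (length(todo) > 0L) {
    d <- utils::adist(uniq[todo], whitelist)
    best <- apply(d, 1L, min)
    hit <- apply(d, 1L, which.min)
    n_best <- rowSums(d == best)
    ok <- best <= max_edit_distance & n_best == 1L
    assigned[todo[ok]] <- whitelist[hit[ok]]
  }
  assigned[match(barcodes, uniq)]
}

#' UMI-deduplicated barcode counts per sample
#'
#' Maps assigned reads' barcodes onto the whitelist (see [match_whitelist()])
#' and counts, per sample and whitelist barcode, the number of distinct UMIs
#' -- so a molecule sequenced many times through PCR duplication counts once.
#' Raw read counts are reported alongside. Optionally, UMIs within Hamming
#' distance 1 of a more abundant UMI are collapsed onto it first
#' (directional collapse), absorbing single sequencing errors in the UMI
#' itself.
#'
#' @param demuxed Output of [demultiplex()] (only `status == "assigned"`
#'   rows are counted).
#' @param whitelist Barcode whitelist.
#' @param max_edit_distance Levenshtein assignment radius (default 2).
#' @param collapse_umis Collapse Hamming-1 UMI neighbours before counting
#'   (default FALSE: exact-match deduplication).
#' @return Tibble `sample`, `barcode`, `reads`, `count` (distinct UMIs),
#'   with attribute `n_discarded`: assigned reads whose barcode matched no
#'   unique whitelist entry.
#' @export
count_barcodes <- function(demuxed, whitelist, max_edit_distance = 2L,
                           collapse_umis = FALSE) {
  demuxed <- tibble::as_tibble(demuxed)
  keep <- dplyr::filter(demuxed, .data$status == "assigned")
  keep$whitelist_barcode <- match_whitelist(keep$barcode, whitelist,
                                            max_edit_distance)
  n_discarded <- sum(is.na(keep$whitelist_barcode))
  keep <- dplyr::filter(keep, !is.na(.data$whitelist_barcode))
  if (collapse_umis) {
    keep <- keep |>
      dplyr::group_by(.data$sample, .data$whitelist_barcode) |>
      dplyr::mutate(umi = .collapse_umis_h1(.data$umi)) |>
      dplyr::ungroup()
  }
  out <- keep |>
    dplyr::group_by(sample = .data$sample, barcode = .data$whitelist_barcode) |>
    dplyr::summarise(reads = dplyr::n(),
                     count = dplyr::n_distinct(.data$umi),
                     .groups = "drop")
  attr(out, "n_discarded") <- n_discarded
  out
}

# directional Hamming-1 collapse: each UMI maps to its most abundant
# Hamming-1 neighbour when that neighbour is strictly more abundant
.collapse_umis_h1 <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  reps <- names(tab)
  mapped <- stats::setNames(reps, reps)
  if (length(reps) > 1L) {
    d <- utils::adist(reps, reps, costs = list(ins = 10, del = 10, sub = 1))
    for (i in seq_along(reps)[-1L]) {
      j <- which(d[i, seq_len(i - 1L)] == 1L & tab[seq_len(i - 1L)] > tab[[i]])
      if (length(j) > 0L) mapped[[reps[[i]]]] <- mapped[[reps[[j[1L]]]]]
    }
  }
  unname(mapped[umis])
}

#' Assign clone barcodes to arrayed wells (metagrid rule)
#'
#' After sorting single clones into plates, each well's barcode is identified
#' from combinatorially indexed well-level sequencing by majority vote: the
#' well's top barcode is assigned provided the well has at least `min_reads`
#' reads, the top barcode is at least `min_frac` of them, and it has more
#' than `min_ratio` times the reads of the second-highest barcode. The
#' thresholds are checked in that order and the status names the first
#' failing rule. Counts are raw reads (pre-UMI) by default, matching the
#' order of operations in the protocol; pass UMI counts to switch.
#'
#' @param well_counts Tibble `plate`, `well`, `barcode`, `count` (reads per
#'   barcode per well; zero-read wells may simply be absent and can be padded
#'   by the caller).
#' @param min_reads Minimum total reads per well (default 200, inclusive).
#' @param min_frac Minimum top-barcode fraction (default 0.60, inclusive).
#' @param min_ratio Required top/second ratio (default 1.5, strict; second
#'   is 0 when only one barcode is present).
#' @return Tibble with one row per well: `plate`, `well`,
#'   `assigned_barcode` (NA unless assigned), `total_reads`, `top_fraction`,
#'   `top_to_second_ratio`, `status` (`"assigned"`, `"low-reads"`,
#'   `"low-majority"`, `"low-ratio"`, `"empty"`).
#' @examples
#' assign_wells(tibble::tibble(plate = 1, well = c("A1", "A1"),
#'                             barcode = c("B1", "B2"), count = c(200, 100)))
#' @export
assign_wells <- function(well_counts, min_reads = 200, min_frac = 0.60,
                         min_ratio = 1.5) {
  well_counts <- tibble::as_tibble(well_counts)
  stopifnot(all(well_counts$count >= 0))
  well_counts |>
    dplyr::group_by(.data$plate, .data$well) |>
    dplyr::summarise(
      total_reads = sum(.data$count),
      top = if (dplyr::n() > 0L) max(.data$count) else 0,
      second = if (dplyr::n() > 1L) sort(.data$count, decreasing = TRUE)[[2L]]
               else 0,
      top_barcode = .data$barcode[which.max(.data$count)][1L],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      top_fraction = ifelse(.data$total_reads > 0,
                            .data$top / .data$total_reads, 0),
      top_to_second_ratio = ifelse(.data$second > 0, .data$top / .data$second,
                                   Inf),
      status = dplyr::case_when(
        .data$total_reads == 0 ~ "empty",
        .data$total_reads < min_reads ~ "low-reads",
        .data$top_fraction < min_frac ~ "low-majority",
        .data$top <= min_ratio * .data$second ~ "low-ratio",
        .default = "assigned"
      ),
      assigned_barcode = dplyr::if_else(.data$status == "assigned",
                                        .data$top_barcode, NA_character_)
    ) |>
    dplyr::select("plate", "well", "assigned_barcode", "total_reads",
                  "top_fraction", "top_to_second_ratio", "status")
}
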