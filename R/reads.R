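#' Amplicon library specification
#'
#' Describes the layout of a barcode amplicon read:
#' `[pad][UMI][inline index][5' anchor][barcode][3' anchor]`, where the pad is
#' 0 or more leading bases of primer diversity, the 8-bp UMI tags the original
#' template molecule, the inline index identifies the sample within a lane
#' (complementing the Illumina index pair), and the constant anchors flank the
#' lineage barcode. Defaults follow the two-step PCR design used for barcode
#' sequencing in this system.
#'
#' @param anchor5,anchor3 Constant sequences flanking the barcode.
#' @param inline_indices Character vector of permitted inline indices (equal
#'   length each).
#' @param umi_length UMI length in bases (default 8).
#' @param barcode_length Barcode length in bases (default 26).
#' @param max_pad Maximum random pad before the UMI (default 3).
#' @param whitelist Optional barcode whitelist to validate: entries must be
#'   pairwise farther than `2 * whitelist_radius` in Levenshtein distance so
#'   nearest-entry assignment within the radius is unambiguous.
#' @param whitelist_radius Edit-distance radius used for that validation
#'   (default 2).
#' @return List of class `library_spec`.
#' @examples
#' library_spec()
#' @export
library_spec <- function(anchor5 = "TAATATGGACTAAAGGAGGCTTTT",
                         anchor3 = "TATCAGATCTAAGCTTGAATTCGA",
                         inline_indices = c("CGATGTT", "ACAGTGT", "TGACCAT",
                                            "GCCAATT", "ATCACGT", "CAGATCT",
                                            "GGCTACT", "TAGCTTT", "TTAGGCT",
                                            "ACTTGAT", "GATCAGT", "CTTGTAT"),
                         umi_length = 8L, barcode_length = 26L, max_pad = 3L,
                         whitelist = NULL, whitelist_radius = 2L) {
  stopifnot(length(unique(nchar(inline_indices))) == 1L,
            umi_length > 0, barcode_length > 0, max_pad >= 0)
  if (!is.null(whitelist)) {
    d <- utils::adist(whitelist)
    diag(d) <- Inf
    if (any(d <= 2L * whitelist_radius)) {
      stop("whitelist entries collide within edit-distance radius ",
           whitelist_radius, call. = FALSE)
    }
  }
  structure(
    list(anchor5 = anchor5, anchor3 = anchor3,
         inline_indices = inline_indices,
         inline_length = nchar(inline_indices[[1L]]),
         umi_length = as.integer(umi_length),
         barcode_length = as.integer(barcode_length),
         max_pad = as.integer(max_pad)),
    class = "library_spec"
  )
}

#' Random barcode whitelist
#'
#' Draws random barcodes and keeps a set whose pairwise Levenshtein distances
#' exceed `2 * radius`, so edit-distance assignment within `radius` is
#' unambiguous (random 26-mers essentially always satisfy this).
#'
#' @param n Number of barcodes.
#' @param length Barcode length (default 26).
#' @param radius Assignment radius the set must support (default 2).
#' @return Character vector of barcodes.
#' @export
random_barcodes <- function(n, length = 26L, radius = 2L) {
  out <- character(0)
  while (base::length(out) < n) {
    cand <- vapply(seq_len(n - base::length(out)), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
    d <- utils::adist(out)
    diag(d) <- Inf
    bad <- unique(which(d <= 2L * radius, arr.ind = TRUE)[, 1L])
    if (base::length(bad) > 0L) out <- out[-bad]
  }
  out[seq_len(n)]
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# n distinct UMIs of the given length (sampled without replacement from the
# 4^len space; duplicate tagging of distinct molecules is not modelled)
.distinct_umis <- function(n, len) {
  space <- 4^len
  stopifnot(n <= space)
  codes <- sample(space, n) - 1
  bases <- c("A", "C", "G", "T")
  out <- rep("", n)
  for (i in seq_len(len)) {
    out <- paste0(bases[codes %% 4 + 1], out)
    codes <- codes %/% 4
  }
  out
}

#' Build a sample sheet of index combinations
#'
#' Assigns each sample a unique (Illumina index, inline index) combination.
#' Using unique combinations (not just unique Illumina indices) lets
#' index-hopped reads -- whose two indices each occur in the sheet but never
#' together -- be recognized and excluded.
#'
#' @param samples Character vector of sample names.
#' @param spec A [library_spec] supplying the inline index set.
#' @param illumina_indices Pool of Illumina index labels; defaults to `i701`,
#'   `i702`, ... as needed.
#' @return Tibble `sample`, `illumina_index`, `inline_index`.
#' @export
build_sample_sheet <- function(samples, spec = library_spec(),
                               illumina_indices = NULL) {
  n <- length(samples)
  n_inline <- length(spec$inline_indices)
  n_illu <- ceiling(n / n_inline)
  if (is.null(illumina_indices)) {
    illumina_indices <- sprintf("i7%02d", seq_len(n_illu))
  }
  combos <- expand.grid(inline_index = spec$inline_indices,
                        illumina_index = illumina_indices,
                        stringsAsFactors = FALSE)
  # stagger so no Illumina index reuses an inline slot pattern trivially
  tibble::tibble(
    sample = samples,
    illumina_index = combos$illumina_index[seq_len(n)],
    inline_index = combos$inline_index[seq_len(n)]
  )
}

#' Generate synthetic amplicon reads from barcode counts
#'
#' Emits one amplicon read per sequenced molecule copy for each (sample,
#' barcode) count: every input count unit is an original template molecule
#' with its own UMI; PCR duplication re-reads a molecule (same UMI) a
#' geometric number of extra times with mean `duplication_rate`; sequencing
#' substitution errors hit each base independently. The Illumina index is
#' carried as a metadata column (it lives in the index read, not the
#' amplicon).
#'
#' @param sample_counts Tibble `sample`, `barcode`, `count` of template
#'   molecules.
#' @param spec A [library_spec].
#' @param sample_sheet Tibble from [build_sample_sheet()] covering every
#'   sample.
#' @param duplication_rate Mean extra PCR copies per molecule (default 0).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @return Tibble `read_id`, `sample` (ground truth), `illumina_index`,
#'   `sequence`.
#' @seealso [write_fastq()] to serialize, [extract_read_fields()] to parse.
#' @export
generate_reads <- function(sample_counts, spec = library_spec(),
                           sample_sheet = NULL, duplication_rate = 0,
                           error_rate = 0, seed = NULL) {
  sample_counts <- tibble::as_tibble(sample_counts)
  stopifnot(all(c("sample", "barcode", "count") %in% names(sample_counts)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_sheet)) {
    sample_sheet <- build_sample_sheet(unique(sample_counts$sample), spec)
  }
  sheet <- tibble::as_tibble(sample_sheet)

  molecules <- sample_counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$sample) |>
    dplyr::reframe(barcode = rep(.data$barcode, .data$count)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(umi = .distinct_umis(dplyr::n(), spec$umi_length)) |>
    dplyr::ungroup() |>
    dplyr::left_join(sheet, by = "sample")
  if (anyNA(molecules$inline_index)) {
    stop("sample sheet does not cover every sample", call. = FALSE)
  }

  copies <- 1L + if (duplication_rate > 0) {
    stats::rgeom(nrow(molecules), prob = 1 / (1 + duplication_rate))
  } else {
    0L
  }
  reads <- molecules[rep(seq_len(nrow(molecules)), copies), ]
  pad_len <- sample.int(spec$max_pad + 1L, nrow(reads), replace = TRUE) - 1L
  pads <- vapply(pad_len, function(k) {
    if (k == 0L) "" else paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                               collapse = "")
  }, character(1))
  seqs <- paste0(pads, reads$umi, reads$inline_index, spec$anchor5,
                 reads$barcode, spec$anchor3)
  if (error_rate > 0) seqs <- .substitute_errors(seqs, error_rate)
  tibble::tibble(
    read_id = sprintf("read%06d", seq_along(seqs)),
    sample = reads$sample,
    illumina_index = reads$illumina_index,
    sequence = seqs
  )
}

# independent per-base substitutions to a different base
.substitute_errors <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read and write FASTQ
#'
#' Thin wrappers around `Biostrings` FASTQ support. `write_fastq()` emits
#' constant placeholder qualities (quality modelling is out of scope).
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path FASTQ file path (".gz" for gzip).
#' @return `write_fastq()`: `path`, invisibly. `read_fastq()`: tibble
#'   `read_id`, `sequence`.
#' @export
write_fastq <- function(reads, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("write_fastq() requires the Biostrings package", call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  quals <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(n) strrep("I", n), character(1))
  )
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fastq() requires the Biostrings package", call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(x), sequence = unname(as.character(x)))
}
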