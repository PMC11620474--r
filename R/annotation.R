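#' Flag preexisting variants shared through lineage ancestry
#'
#' Clones derived from the same low-complexity barcode group, or from the
#' same parental strain, share any mutation that arose during strain
#' construction rather than during the evolution experiment. A variant
#' (exact position key: chrom, pos, ref, alt) is flagged preexisting when it
#' is carried by at least `min_shared` clones of one low-complexity group, or
#' by every sequenced clone of a parental strain. Preexisting variants are
#' excluded from downstream causality calls unless their gene is
#' independently causal.
#'
#' @param variants Tibble with columns `clone_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `low_complexity_group`, `parent_strain` (and typically
#'   `consequence`).
#' @param min_shared Clones of one low-complexity group that must share a
#'   variant for it to count as preexisting (default 2).
#' @return The input with logical `preexisting` appended.
#' @export
flag_preexisting <- function(variants, min_shared = 2L) {
  variants <- tibble::as_tibble(variants)
  key_cols <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(c("clone_id", "low_complexity_group", "parent_strain",
                  key_cols) %in% names(variants)))
  by_group <- variants |>
    dplyr::distinct(dplyr::across(dplyr::all_of(
      c(key_cols, "low_complexity_group", "clone_id")
    ))) |>
    dplyr::count(dplyr::across(dplyr::all_of(
      c(key_cols, "low_complexity_group")
    ))) |>
    dplyr::filter(.data$n >= min_shared) |>
    dplyr::mutate(pre_group = TRUE) |>
    dplyr::select(-"n")
  clones_per_parent <- variants |>
    dplyr::distinct(.data$parent_strain, .data$clone_id) |>
    dplyr::count(.data$parent_strain, name = "n_clones")
  by_parent <- variants |>
    dplyr::distinct(dplyr::across(dplyr::all_of(
      c(key_cols, "parent_strain", "clone_id")
    ))) |>
    dplyr::count(dplyr::across(dplyr::all_of(c(key_cols, "parent_strain")))) |>
    dplyr::left_join(clones_per_parent, by = "parent_strain") |>
    dplyr::filter(.data$n == .data$n_clones) |>
    dplyr::mutate(pre_parent = TRUE) |>
    dplyr::select(-"n", -"n_clones")
  variants |>
    dplyr::left_join(by_group, by = c(key_cols, "low_complexity_group")) |>
    dplyr::left_join(by_parent, by = c(key_cols, "parent_strain")) |>
    dplyr::mutate(
      preexisting = dplyr::coalesce(.data$pre_group, FALSE) |
        dplyr::coalesce(.data$pre_parent, FALSE)
    ) |>
    dplyr::select(-"pre_group", -"pre_parent")
}

#' Call putatively causal genes by recurrence and pathway membership
#'
#' A gene hit by non-preexisting variants in at least `min_hits` distinct
#' clones across all mutants is called causal by recurrence
#' (adaptation-driving); distinct clones, not distinct variants, are counted.
#' Genes sharing a pathway with a recurrence-causal gene are additionally
#' called causal with basis `"pathway"`.
#'
#' @param variants Output of [flag_preexisting()] (must have `preexisting`).
#' @param pathway_map Tibble `gene`, `pathway`; defaults to the curated map
#'   shipped with the package ([default_pathways()]).
#' @param min_hits Recurrence threshold in clones (default 4).
#' @return Tibble `gene`, `n_hits`, `causal`, `causal_basis`
#'   (`"recurrence"`, `"pathway"` or `NA`), `pathway`.
#' @export
classify_recurrent_genes <- function(variants, pathway_map = default_pathways(),
                                     min_hits = 4L) {
  variants <- tibble::as_tibble(variants)
  stopifnot("preexisting" %in% names(variants))
  pathway_map <- tibble::as_tibble(pathway_map)
  hits <- variants |>
    dplyr::filter(!.data$preexisting, !is.na(.data$gene)) |>
    dplyr::distinct(.data$gene, .data$clone_id) |>
    dplyr::count(.data$gene, name = "n_hits")
  out <- hits |>
    dplyr::left_join(pathway_map, by = "gene") |>
    dplyr::mutate(recurrent = .data$n_hits >= min_hits)
  causal_pathways <- unique(out$pathway[out$recurrent & !is.na(out$pathway)])
  out |>
    dplyr::mutate(
      causal = .data$recurrent |
        (!is.na(.data$pathway) & .data$pathway %in% causal_pathways),
      causal_basis = dplyr::case_when(
        .data$recurrent ~ "recurrence",
        .data$causal ~ "pathway",
        .default = NA_character_
      )
    ) |>
    dplyr::select("gene", "n_hits", "causal", "causal_basis", "pathway")
}

#' Classify a gene's putative functional effect from its variant types
#'
#' A gene harbouring any stop-gained or frameshift variant (non-preexisting)
#' is classified as loss-of-function; a gene with only missense or nearby
#' non-genic/regulatory variants as modification-of-function; genes with only
#' synonymous or other consequences get `NA`.
#'
#' @param variants Tibble with `gene`, `consequence` (one of `stop-gained`,
#'   `frameshift`, `missense`, `non-genic`, `synonymous`, `other`) and,
#'   if present, `preexisting` (preexisting variants are ignored).
#' @return Tibble `gene`, `effect_class`.
#' @export
classify_gene_effect <- function(variants) {
  variants <- tibble::as_tibble(variants)
  if ("preexisting" %in% names(variants)) {
    variants <- dplyr::filter(variants, !.data$preexisting)
  }
  variants |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      effect_class = dplyr::case_when(
        any(.data$consequence %in% c("stop-gained", "frameshift")) ~
          "loss-of-function",
        any(.data$consequence %in% c("missense", "non-genic")) ~
          "modification-of-function",
        .default = NA_character_
      ),
      .groups = "drop"
    )
}

#' Curated gene-to-pathway map
#'
#' The pathway groupings used to extend recurrence-based causality calls:
#' Ras/PKA and TOR/Sch9 nutrient-sensing pathways, the RTG retrograde
#' pathway, TCA-cycle enzymes, regulators of mitochondrial biogenesis, and
#' the HOG pathway. Shipped as a plain CSV in `extdata`; supply your own
#' mapping to override.
#'
#' @return Tibble `gene`, `pathway`.
#' @export
default_pathways <- function() {
  path <- system.file("extdata", "pathways.csv", package = "barwalk",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
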