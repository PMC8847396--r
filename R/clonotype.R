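# Clone definition (paired CDR3 nucleotide key), frequencies, expansion.

#' Group cells into clones by paired CDR3 nucleotide identity
#'
#' A clone is the set of cells sharing identical TRB and TRA CDR3 nucleotide
#' sequences; the clone id is `cdr3b_nt + "_" + cdr3a_nt`. V/J genes are
#' recorded per member cell but are not part of the key.
#'
#' @param cells Cell tibble from [assemble_cells()] (one sample).
#' @param group_label Group label for the sample (e.g. infection type).
#' @return A clone tibble (one row per clone) with columns `sample_id`,
#'   `group_label`, `clone_id`, CDR3 nt/aa sequences for both chains,
#'   `size` (number of distinct member barcodes), and list-columns
#'   `member_barcodes` and `v_pairs` (per-cell TRBV/TRAV calls).
#' @export
build_clones <- function(cells, group_label) {
  assert_cols(cells, c("barcode", "sample_id", "cdr3b_nt", "cdr3a_nt",
                       "cdr3b_aa", "cdr3a_aa", "trbv", "trav"),
              "cell table")
  if (nrow(cells) == 0) {
    return(tibble::tibble(
      sample_id = character(), group_label = character(),
      clone_id = character(), cdr3b_nt = character(),
      cdr3a_nt = character(), cdr3b_aa = character(),
      cdr3a_aa = character(), size = integer(),
      member_barcodes = list(), v_pairs = list()
    ))
  }
  if (dplyr::n_distinct(cells$sample_id) > 1) {
    abort("build_clones expects cells from a single sample")
  }
  cells |>
    dplyr::group_by(.data$sample_id, .data$cdr3b_nt, .data$cdr3a_nt,
                    .data$cdr3b_aa, .data$cdr3a_aa) |>
    dplyr::summarise(
      size = dplyr::n_distinct(.data$barcode),
      member_barcodes = list(sort(unique(.data$barcode))),
      v_pairs = {
        bc <- .data$barcode
        vb <- .data$trbv
        va <- .data$trav
        list(tibble::tibble(barcode = bc, trbv = vb, trav = va))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      clone_id = paste(.data$cdr3b_nt, .data$cdr3a_nt, sep = "_"),
      group_label = group_label
    ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$clone_id) |>
    dplyr::select("sample_id", "group_label", "clone_id", "cdr3b_nt",
                  "cdr3a_nt", "cdr3b_aa", "cdr3a_aa", "size",
                  "member_barcodes", "v_pairs")
}

#' Classify clones as expanded or lowly expanded
#'
#' Clones supported by two or more cells are `expanded`; clones supported by
#' a single cell barcode are `lowly_expanded`.
#'
#' @param clones Clone tibble from [build_clones()].
#' @return The clone tibble with an `expansion_class` column added.
#' @export
classify_expansion <- function(clones) {
  assert_clone_tbl(clones)
  dplyr::mutate(clones, expansion_class = dplyr::if_else(
    .data$size >= 2L, "expanded", "lowly_expanded"
  ))
}

#' Select the most expanded clones of each repertoire
#'
#' Clones are ordered by size descending with ties broken by clone id
#' (lexicographic ascending) so the selection is deterministic. When the
#' table holds several samples, the top `n` are taken per sample.
#'
#' @param clones Clone tibble (one or more samples).
#' @param n Number of clones to keep per sample (`>= 1`).
#' @return Clone tibble restricted to at most `n` clones per sample, in rank
#'   order.
#' @export
top_clones <- function(clones, n) {
  assert_clone_tbl(clones)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("n must be a single integer >= 1")
  }
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$clone_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = as.integer(n)) |>
    dplyr::ungroup()
}

#' Clonal frequency table
#'
#' Adds each clone's fraction of the repertoire (size over total cells of
#' the sample). Fractions sum to 1 per sample.
#'
#' @param clones Clone tibble.
#' @return Tibble of `sample_id`, `clone_id`, `size`, `fraction`.
#' @export
clone_fraction_table <- function(clones) {
  assert_clone_tbl(clones)
  if (nrow(clones) == 0) abort("empty repertoire: no clones")
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$size / sum(.data$size)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "clone_id", "size", "fraction")
}

#' Flatten a clone table into a per-cell table
#'
#' One row per member cell, carrying the clone id, size and (if present)
#' expansion class; used by the phenotype-integration stage.
#'
#' @param clones Clone tibble.
#' @return Tibble with one row per cell (`sample_id`, `barcode`, `clone_id`,
#'   `size`, and `expansion_class` when available).
#' @export
clone_cells <- function(clones) {
  assert_clone_tbl(clones)
  keep <- intersect(
    c("sample_id", "group_label", "clone_id", "size", "expansion_class",
      "member_barcodes"),
    names(clones)
  )
  clones |>
    dplyr::select(dplyr::all_of(keep)) |>
    tidyr::unnest_longer("member_barcodes", values_to = "barcode")
}

#' Export a per-repertoire clone table
#'
#' Writes the flat TSV used by downstream tooling: clone id, CDR3 amino-acid
#' sequences, majority V genes, size, fraction and expansion class.
#'
#' @param clones Clone tibble with expansion classes.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  assert_clone_tbl(clones, need_expansion = TRUE)
  tab <- clones |>
    dplyr::mutate(
      TRBV = purrr::map_chr(.data$v_pairs, ~ majority_gene(.x$trbv)),
      TRAV = purrr::map_chr(.data$v_pairs, ~ majority_gene(.x$trav))
    ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$size / sum(.data$size)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "group_label", "clone_id", "cdr3b_aa",
                  "cdr3a_aa", "TRBV", "TRAV", "size", "fraction",
                  "expansion_class")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

# majority vote with lexicographic tie-break
majority_gene <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1]]
  sort(winners)[1]
}
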