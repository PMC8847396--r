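# Reading/writing single-cell V(D)J tables and assembling QC-passed cells.

TENX_REQUIRED <- c(
  "barcode", "chain", "cdr3", "cdr3_nt", "v_gene", "j_gene",
  "productive", "is_cell", "high_confidence", "umis"
)
AIRR_REQUIRED <- c(
  "cell_id", "locus", "junction", "junction_aa", "v_call", "j_call",
  "productive"
)

#' Read single-cell V(D)J contig annotations
#'
#' Parses either the 10x Genomics `filtered_contig_annotations.csv` dialect
#' or an AIRR Rearrangement TSV into a tibble of chain records, keeping only
#' TRA/TRB contigs (other loci are dropped with a message).
#'
#' @param path Path to the contig table.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @param sample_id Sample identifier attached to every record; barcodes are
#'   only unique within a sample.
#' @return A tibble with one row per TRA/TRB contig and columns `barcode`,
#'   `sample_id`, `locus`, `cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`,
#'   `j_gene`, `productive`, `is_cell`, `high_confidence`, `umis`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "barcode,chain,cdr3,cdr3_nt,v_gene,j_gene,productive,is_cell,high_confidence,umis",
#'   "b1-1,TRB,CASSF,TGTGCCAGCAGCTTT,TRBV19,TRBJ2-7,True,True,True,4"
#' ), f)
#' read_contigs(f, "tenx_csv", sample_id = "m1")
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv"), sample_id) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("contig file not found: %s", path))
  if (missing(sample_id) || !nzchar(sample_id)) abort("sample_id is required")

  if (dialect == "tenx_csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    assert_cols(raw, TENX_REQUIRED, "10x contig CSV")
    rec <- tibble::tibble(
      barcode = raw$barcode,
      sample_id = sample_id,
      locus = raw$chain,
      cdr3_nt = raw$cdr3_nt,
      cdr3_aa = raw$cdr3,
      v_gene = raw$v_gene,
      d_gene = if ("d_gene" %in% names(raw)) raw$d_gene else NA_character_,
      j_gene = raw$j_gene,
      productive = parse_flag(raw$productive, default = FALSE),
      is_cell = parse_flag(raw$is_cell, default = FALSE),
      high_confidence = parse_flag(raw$high_confidence, default = FALSE),
      umis = as.integer(raw$umis)
    )
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    assert_cols(raw, AIRR_REQUIRED, "AIRR Rearrangement TSV")
    umis <- if ("duplicate_count" %in% names(raw)) {
      as.integer(raw$duplicate_count)
    } else {
      rep(NA_integer_, nrow(raw))
    }
    rec <- tibble::tibble(
      barcode = raw$cell_id,
      sample_id = sample_id,
      locus = raw$locus,
      cdr3_nt = toupper(stringr::str_remove_all(raw$junction, "[^A-Za-z]")),
      cdr3_aa = raw$junction_aa,
      v_gene = raw$v_call,
      d_gene = if ("d_call" %in% names(raw)) raw$d_call else NA_character_,
      j_gene = raw$j_call,
      productive = parse_flag(raw$productive, default = TRUE),
      # AIRR has no cellranger-style cell/confidence flags; absent -> TRUE
      is_cell = if ("is_cell" %in% names(raw)) {
        parse_flag(raw$is_cell, default = TRUE)
      } else TRUE,
      high_confidence = if ("high_confidence" %in% names(raw)) {
        parse_flag(raw$high_confidence, default = TRUE)
      } else TRUE,
      umis = dplyr::coalesce(umis, 0L)
    )
  }
  if (nrow(rec) == 0) return(rec)

  keep <- rec$locus %in% c("TRA", "TRB")
  if (any(!keep)) {
    inform(sprintf(
      "read_contigs: dropped %d contig(s) from non-TRA/TRB loci (%s)",
      sum(!keep), paste(unique(rec$locus[!keep]), collapse = ", ")
    ))
  }
  rec[keep, , drop = FALSE]
}

#' Assemble quality-filtered cells with exactly one TRA and one TRB chain
#'
#' Applies the contig-level retention predicates, then keeps only barcodes
#' carrying exactly one retained TRA and one retained TRB contig. All other
#' barcodes are discarded and counted by reason in the filter report
#' (retrievable with [filter_report()]).
#'
#' @param contigs Tibble from [read_contigs()] (one sample).
#' @param require_productive,require_cell,require_high_confidence Contig
#'   retention predicates; each independently toggleable.
#' @return A tibble of cells (one row per barcode) with paired-chain columns
#'   `cdr3b_nt`, `cdr3a_nt`, `cdr3b_aa`, `cdr3a_aa`, `trbv`, `trbj`, `trav`,
#'   `traj`, `umis_trb`, `umis_tra`, carrying the filter report as the
#'   `"filter_report"` attribute.
#' @export
assemble_cells <- function(contigs,
                           require_productive = TRUE,
                           require_cell = TRUE,
                           require_high_confidence = TRUE) {
  assert_cols(contigs, c("barcode", "sample_id", "locus", "cdr3_nt",
                         "cdr3_aa", "v_gene", "j_gene", "productive",
                         "is_cell", "high_confidence", "umis"),
              "contig table")
  if (nrow(contigs) > 0 && dplyr::n_distinct(contigs$sample_id) > 1) {
    abort("assemble_cells expects contigs from a single sample")
  }

  # identical (barcode, locus, cdr3_nt) rows are duplicates, not multi-chain
  contigs <- dplyr::distinct(contigs, .data$barcode, .data$locus,
                             .data$cdr3_nt, .keep_all = TRUE)

  all_barcodes <- unique(contigs$barcode)
  retained <- contigs |>
    dplyr::filter(
      (!require_productive | .data$productive),
      (!require_cell | .data$is_cell),
      (!require_high_confidence | .data$high_confidence)
    )

  counts <- retained |>
    dplyr::count(.data$barcode, .data$locus) |>
    tidyr::pivot_wider(names_from = "locus", values_from = "n",
                       values_fill = 0L)
  for (loc in c("TRA", "TRB")) {
    if (!loc %in% names(counts)) counts[[loc]] <- 0L
  }
  counts <- tibble::tibble(barcode = all_barcodes) |>
    dplyr::left_join(counts, by = "barcode") |>
    dplyr::mutate(
      TRA = dplyr::coalesce(.data$TRA, 0L),
      TRB = dplyr::coalesce(.data$TRB, 0L)
    )

  # one reason per discarded barcode, so retained + discards == barcodes
  reason <- with(counts, dplyr::case_when(
    TRA == 1L & TRB == 1L ~ "retained",
    TRA == 0L & TRB == 0L ~ "failed_predicates",
    TRA >= 2L ~ "multi_tra",
    TRB >= 2L ~ "multi_trb",
    TRA == 0L ~ "no_tra",
    TRB == 0L ~ "no_trb"
  ))
  ok_barcodes <- counts$barcode[reason == "retained"]

  if (length(ok_barcodes) == 0) {
    cells <- tibble::tibble(
      barcode = character(), sample_id = character(),
      cdr3b_nt = character(), cdr3a_nt = character(),
      cdr3b_aa = character(), cdr3a_aa = character(),
      trbv = character(), trbj = character(),
      trav = character(), traj = character(),
      umis_trb = integer(), umis_tra = integer()
    )
    attr(cells, "filter_report") <- list(
      n_barcodes = length(all_barcodes), retained = 0L,
      failed_predicates = sum(reason == "failed_predicates"),
      no_tra = sum(reason == "no_tra"),
      multi_tra = sum(reason == "multi_tra"),
      no_trb = sum(reason == "no_trb"),
      multi_trb = sum(reason == "multi_trb")
    )
    return(cells)
  }

  wide <- retained |>
    dplyr::filter(.data$barcode %in% ok_barcodes) |>
    dplyr::group_by(.data$barcode, .data$sample_id)
  cells <- wide |>
    dplyr::summarise(
      cdr3b_nt = .data$cdr3_nt[.data$locus == "TRB"],
      cdr3a_nt = .data$cdr3_nt[.data$locus == "TRA"],
      cdr3b_aa = .data$cdr3_aa[.data$locus == "TRB"],
      cdr3a_aa = .data$cdr3_aa[.data$locus == "TRA"],
      trbv = .data$v_gene[.data$locus == "TRB"],
      trbj = .data$j_gene[.data$locus == "TRB"],
      trav = .data$v_gene[.data$locus == "TRA"],
      traj = .data$j_gene[.data$locus == "TRA"],
      umis_trb = .data$umis[.data$locus == "TRB"],
      umis_tra = .data$umis[.data$locus == "TRA"],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$barcode)

  report <- list(
    n_barcodes = length(all_barcodes),
    retained = sum(reason == "retained"),
    failed_predicates = sum(reason == "failed_predicates"),
    no_tra = sum(reason == "no_tra"),
    multi_tra = sum(reason == "multi_tra"),
    no_trb = sum(reason == "no_trb"),
    multi_trb = sum(reason == "multi_trb")
  )
  attr(cells, "filter_report") <- report
  cells
}

#' Retrieve the QC filter report attached by [assemble_cells()]
#'
#' @param cells A cell tibble produced by [assemble_cells()].
#' @return Named list of barcode counts: total, retained, and per-reason
#'   discards (`failed_predicates`, `no_tra`, `multi_tra`, `no_trb`,
#'   `multi_trb`).
#' @export
filter_report <- function(cells) {
  rep <- attr(cells, "filter_report")
  if (is.null(rep)) abort("no filter report attached; use assemble_cells()")
  rep
}

#' Read per-cell annotations (group label and transcriptional cluster)
#'
#' @param path CSV or TSV with columns `barcode`, `sample_id`, `group_label`,
#'   `cluster_id`. Cluster ids are kept verbatim as character.
#' @return Tibble of annotations; duplicate `(barcode, sample_id)` keys are
#'   an error.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  ann <- readr::read_delim(path, delim = delim, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  assert_cols(ann, c("barcode", "sample_id", "group_label", "cluster_id"),
              "annotation table")
  dup <- ann |>
    dplyr::count(.data$barcode, .data$sample_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (barcode, sample_id) annotation key(s): %s",
      paste(head(paste(dup$sample_id, dup$barcode, sep = "/"), 10),
            collapse = ", ")
    ))
  }
  dplyr::select(ann, "barcode", "sample_id", "group_label", "cluster_id")
}

#' Write assembled cells as an AIRR Rearrangement TSV
#'
#' Emits two rows per cell (one per locus). The output round-trips through
#' [read_contigs()] + [assemble_cells()] to an identical cell set.
#'
#' @param cells Cell tibble from [assemble_cells()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(cells, path) {
  assert_cols(cells, c("barcode", "sample_id", "cdr3b_nt", "cdr3a_nt",
                       "cdr3b_aa", "cdr3a_aa", "trbv", "trbj", "trav",
                       "traj"), "cell table")
  bad <- !nzchar(cells$cdr3b_nt) | !nzchar(cells$cdr3a_nt) |
    is.na(cells$cdr3b_nt) | is.na(cells$cdr3a_nt)
  if (any(bad)) {
    abort(sprintf("%d cell(s) have an empty CDR3 nucleotide sequence",
                  sum(bad)))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(
      cell_id = cells$barcode, locus = "TRB",
      junction = cells$cdr3b_nt, junction_aa = cells$cdr3b_aa,
      v_call = cells$trbv, j_call = cells$trbj,
      duplicate_count = cells$umis_trb %||% NA_integer_
    ),
    tibble::tibble(
      cell_id = cells$barcode, locus = "TRA",
      junction = cells$cdr3a_nt, junction_aa = cells$cdr3a_aa,
      v_call = cells$trav, j_call = cells$traj,
      duplicate_count = cells$umis_tra %||% NA_integer_
    )
  ) |>
    dplyr::arrange(.data$cell_id, .data$locus) |>
    dplyr::mutate(
      sequence_id = paste(.data$cell_id, .data$locus, sep = "_"),
      productive = "true",
      .before = 1
    )
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}
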