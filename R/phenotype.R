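# Integration of clonal structure with per-cell transcriptional cluster
# labels, plus CDR3 positional motif matrices.

# join member cells to annotations; drops unannotated cells with a message
annotated_clone_cells <- function(clones, annotations) {
  assert_clone_tbl(clones)
  assert_cols(annotations, c("barcode", "sample_id", "cluster_id"),
              "annotation table")
  cells <- clone_cells(clones) |>
    dplyr::left_join(
      dplyr::select(annotations, "barcode", "sample_id", "cluster_id"),
      by = c("sample_id", "barcode")
    )
  n_un <- sum(is.na(cells$cluster_id))
  if (n_un > 0) {
    inform(sprintf("dropped %d cell(s) without a cluster annotation", n_un))
    cells <- dplyr::filter(cells, !is.na(.data$cluster_id))
  }
  cells
}

#' Per-clone transcriptional cluster composition
#'
#' For each clone (optionally restricted to the `top_n` most expanded clones
#' per sample), the fraction of its annotated member cells in each
#' transcriptional cluster.
#'
#' @param clones Clone tibble.
#' @param annotations Annotation tibble from [read_annotations()] (columns
#'   `barcode`, `sample_id`, `cluster_id`).
#' @param top_n Optional restriction to the most expanded clones per sample.
#' @return Tibble of `sample_id`, `clone_id`, `size`, `cluster_id`, `n`,
#'   `fraction`, `n_cells` (annotated cells of the clone); fractions sum to
#'   1 per clone. Clones with no annotated cells are omitted with a message.
#' @export
clone_cluster_composition <- function(clones, annotations, top_n = NULL) {
  if (!is.null(top_n)) clones <- top_clones(clones, top_n)
  cells <- annotated_clone_cells(clones, annotations)
  omitted <- setdiff(clones$clone_id, cells$clone_id)
  if (length(omitted) > 0) {
    inform(sprintf("%d clone(s) omitted: no annotated cells",
                   length(omitted)))
  }
  cells |>
    dplyr::count(.data$sample_id, .data$clone_id, .data$size,
                 .data$cluster_id, name = "n") |>
    dplyr::group_by(.data$sample_id, .data$clone_id) |>
    dplyr::mutate(n_cells = sum(.data$n),
                  fraction = .data$n / .data$n_cells) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$size),
                   .data$clone_id, .data$cluster_id)
}

#' Cluster composition of an expansion stratum
#'
#' Pools all annotated cells of the clones in one expansion stratum
#' (expanded: size >= 2; lowly expanded: singletons) and reports per-sample
#' cluster fractions.
#'
#' @param clones Clone tibble with expansion classes
#'   ([classify_expansion()]).
#' @param annotations Annotation tibble.
#' @param stratum `"expanded"` or `"lowly_expanded"`.
#' @return Tibble of `sample_id`, `cluster_id`, `n`, `fraction`, `n_cells`;
#'   fractions sum to 1 per sample.
#' @export
stratum_composition <- function(clones, annotations,
                                stratum = c("expanded", "lowly_expanded")) {
  stratum <- match.arg(stratum)
  assert_clone_tbl(clones, need_expansion = TRUE)
  sel <- dplyr::filter(clones, .data$expansion_class == stratum)
  if (nrow(sel) == 0) {
    abort(sprintf("stratum '%s' is empty", stratum))
  }
  annotated_clone_cells(sel, annotations) |>
    dplyr::count(.data$sample_id, .data$cluster_id, name = "n") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(n_cells = sum(.data$n),
                  fraction = .data$n / .data$n_cells) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$cluster_id)
}

#' Association between clonal expansion and cluster membership
#'
#' For each transcriptional cluster, builds the 2x2 table of cells
#' (expanded vs lowly expanded stratum, in vs out of the cluster), computes
#' the odds ratio (closed form `ad/bc`, with a Haldane-Anscombe 0.5
#' continuity correction when any count is zero), tests the association
#' (Fisher's exact test by default, or a chi-squared test), and adjusts
#' p-values with Benjamini-Hochberg across clusters within each sample.
#'
#' The association unit is the cell; set `unit = "clone"` to let each clone
#' vote its majority cluster instead (guards against pseudo-replication).
#'
#' @param clones Clone tibble with expansion classes.
#' @param annotations Annotation tibble.
#' @param method `"fisher"` (default) or `"chi2"`.
#' @param unit `"cell"` (default) or `"clone"`.
#' @return Tibble with one row per (sample, cluster): the 2x2 counts
#'   (`expanded_in`, `expanded_out`, `lowly_in`, `lowly_out`),
#'   `odds_ratio`, `log_odds_ratio`, `p_value`, `adjusted_p`.
#' @export
expansion_cluster_association <- function(clones, annotations,
                                          method = c("fisher", "chi2"),
                                          unit = c("cell", "clone")) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  assert_clone_tbl(clones, need_expansion = TRUE)
  cells <- annotated_clone_cells(clones, annotations)
  if (unit == "clone") {
    cells <- cells |>
      dplyr::group_by(.data$sample_id, .data$clone_id,
                      .data$expansion_class) |>
      dplyr::summarise(cluster_id = majority_gene(.data$cluster_id),
                       .groups = "drop")
  }
  strata <- unique(cells$expansion_class)
  if (!all(c("expanded", "lowly_expanded") %in% strata)) {
    abort("both expansion strata must be non-empty for association testing")
  }

  cells |>
    tidyr::nest(.by = "sample_id") |>
    dplyr::mutate(res = purrr::map(.data$data, function(d) {
      exp_cl <- d$cluster_id[d$expansion_class == "expanded"]
      low_cl <- d$cluster_id[d$expansion_class == "lowly_expanded"]
      clusters <- sort(unique(d$cluster_id))
      purrr::map_dfr(clusters, function(cl) {
        a <- sum(exp_cl == cl); b <- length(exp_cl) - a
        c_ <- sum(low_cl == cl); d_ <- length(low_cl) - c_
        tab <- matrix(c(a, b, c_, d_), nrow = 2, byrow = TRUE)
        or <- if (any(tab == 0)) {
          ((a + 0.5) * (d_ + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        } else {
          (a * d_) / (b * c_)
        }
        p <- if (method == "fisher") {
          fisher.test(tab)$p.value
        } else {
          suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
        }
        tibble::tibble(
          cluster_id = cl, expanded_in = a, expanded_out = b,
          lowly_in = c_, lowly_out = d_,
          odds_ratio = or, log_odds_ratio = log(or), p_value = p
        )
      }) |>
        dplyr::mutate(adjusted_p = p.adjust(.data$p_value, method = "BH"))
    })) |>
    dplyr::select("sample_id", "res") |>
    tidyr::unnest("res")
}

#' Positional residue frequency matrix of CDR3 sequences
#'
#' Builds a position-by-residue frequency matrix (rows: positions 1..L from
#' the N-terminal cysteine; columns: the 20 amino acids) from the CDR3
#' amino-acid sequences of one chain, stratified by exact length. The data
#' behind a sequence logo.
#'
#' @param clones Clone tibble.
#' @param chain `"TRB"` or `"TRA"`.
#' @param length CDR3 amino-acid length to analyze. `NULL` picks the most
#'   common length.
#' @param unique_sequences If `TRUE` (default), duplicate sequences are
#'   collapsed before counting.
#' @return A `motif_matrix`: numeric matrix (`length` x 20) whose rows each
#'   sum to 1, with attributes `chain`, `cdr3_length` and `n_sequences`.
#' @export
motif_matrix <- function(clones, chain = c("TRB", "TRA"), length = NULL,
                         unique_sequences = TRUE) {
  chain <- match.arg(chain)
  assert_clone_tbl(clones)
  seqs <- if (chain == "TRB") clones$cdr3b_aa else clones$cdr3a_aa
  seqs <- seqs[!is.na(seqs) & nzchar(seqs)]
  if (base::length(seqs) == 0) abort("no CDR3 sequences available")
  assert_aa_strings(seqs, "cdr3_aa")
  lens <- nchar(seqs)
  if (is.null(length)) {
    tab <- sort(table(lens), decreasing = TRUE)
    length <- as.integer(names(tab)[1])
  }
  sel <- seqs[lens == length]
  if (base::length(sel) == 0) {
    abort(sprintf("no CDR3 sequences of length %d; available lengths: %s",
                  length, paste(sort(unique(lens)), collapse = ", ")))
  }
  if (unique_sequences) sel <- unique(sel)
  chars <- matrix(unlist(strsplit(sel, "", fixed = TRUE)),
                  nrow = base::length(sel), byrow = TRUE)
  m <- t(apply(chars, 2, function(col) {
    table(factor(col, levels = AA_ALPHABET)) / base::length(col)
  }))
  dimnames(m) <- list(position = seq_len(length), residue = AA_ALPHABET)
  structure(m, chain = chain, cdr3_length = length,
            n_sequences = base::length(sel),
            class = c("motif_matrix", "matrix", "array"))
}

#' Contrast two motif matrices
#'
#' Entrywise difference `m1 - m2`; each position row sums to 0. Both
#' matrices must describe the same chain and CDR3 length.
#'
#' @param m1,m2 `motif_matrix` objects.
#' @return A `motif_contrast` matrix of frequency differences.
#' @export
motif_contrast <- function(m1, m2) {
  stopifnot(inherits(m1, "motif_matrix"), inherits(m2, "motif_matrix"))
  if (attr(m1, "chain") != attr(m2, "chain")) {
    abort("motif matrices describe different chains")
  }
  if (attr(m1, "cdr3_length") != attr(m2, "cdr3_length")) {
    abort(sprintf("CDR3 length mismatch: %d vs %d",
                  attr(m1, "cdr3_length"), attr(m2, "cdr3_length")))
  }
  structure(unclass(m1) - unclass(m2),
            chain = attr(m1, "chain"),
            cdr3_length = attr(m1, "cdr3_length"),
            class = c("motif_contrast", "matrix", "array"))
}

#' Tidy a motif matrix into long form
#'
#' @param x A `motif_matrix` or `motif_contrast`.
#' @param ... Unused.
#' @return Tibble of `position`, `residue`, `frequency`.
#' @export
tidy.motif_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "position") |>
    tidyr::pivot_longer(-"position", names_to = "residue",
                        values_to = "frequency") |>
    dplyr::mutate(position = as.integer(.data$position))
}

#' @export
tidy.motif_contrast <- tidy.motif_matrix
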