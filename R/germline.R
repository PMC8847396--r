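# TRBV/TRAV germline gene usage, pairing, and inter-repertoire correlation.

#' V-gene usage vector(s)
#'
#' Counts variable-gene usage per repertoire, either per cell (each member
#' cell counts once; the default, matching cell-level displays) or per clone
#' (each clone contributes one count via the majority V gene of its member
#' cells, ties broken lexicographically). Gene names are canonicalized with
#' [normalize_gene_name()].
#'
#' @param clones Clone tibble (one or more samples).
#' @param gene_space `"TRBV"`, `"TRAV"`, or `"both"` (both chains stacked
#'   into one frequency vector).
#' @param weighting `"per_cell"` (default) or `"per_clone"`.
#' @param gene_universe Optional character vector of gene names over which
#'   frequencies are normalized; genes never observed get frequency 0.
#' @return Tibble of `sample_id`, `gene`, `count`, `freq` (frequencies sum
#'   to 1 per sample), with attributes `gene_space` and `weighting`.
#' @export
usage_vector <- function(clones, gene_space = c("TRBV", "TRAV", "both"),
                         weighting = c("per_cell", "per_clone"),
                         gene_universe = NULL) {
  gene_space <- match.arg(gene_space)
  weighting <- match.arg(weighting)
  assert_clone_tbl(clones)
  if (nrow(clones) == 0) abort("empty repertoire: no clones")

  if (weighting == "per_cell") {
    cells <- clones |>
      dplyr::select("sample_id", "v_pairs") |>
      tidyr::unnest("v_pairs")
    long <- switch(gene_space,
      TRBV = dplyr::transmute(cells, .data$sample_id, gene = .data$trbv),
      TRAV = dplyr::transmute(cells, .data$sample_id, gene = .data$trav),
      both = dplyr::bind_rows(
        dplyr::transmute(cells, .data$sample_id, gene = .data$trbv),
        dplyr::transmute(cells, .data$sample_id, gene = .data$trav)
      )
    )
  } else {
    per_clone <- clones |>
      dplyr::mutate(
        trbv = purrr::map_chr(.data$v_pairs, ~ majority_vpair(.x)[1]),
        trav = purrr::map_chr(.data$v_pairs, ~ majority_vpair(.x)[2])
      )
    long <- switch(gene_space,
      TRBV = dplyr::transmute(per_clone, .data$sample_id, gene = .data$trbv),
      TRAV = dplyr::transmute(per_clone, .data$sample_id, gene = .data$trav),
      both = dplyr::bind_rows(
        dplyr::transmute(per_clone, .data$sample_id, gene = .data$trbv),
        dplyr::transmute(per_clone, .data$sample_id, gene = .data$trav)
      )
    )
  }

  out <- long |>
    dplyr::mutate(gene = normalize_gene_name(.data$gene)) |>
    dplyr::count(.data$sample_id, .data$gene, name = "count")
  if (!is.null(gene_universe)) {
    gene_universe <- normalize_gene_name(gene_universe)
    out <- out |>
      tidyr::complete(
        sample_id = unique(out$sample_id),
        gene = union(gene_universe, unique(out$gene)),
        fill = list(count = 0L)
      )
  }
  out <- out |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$gene)
  attr(out, "gene_space") <- gene_space
  attr(out, "weighting") <- weighting
  out
}

# majority (TRBV, TRAV) pair of a clone's member cells, ties -> smallest pair
majority_vpair <- function(vp) {
  key <- paste(vp$trbv, vp$trav, sep = "\r")
  tab <- sort(table(key), decreasing = TRUE)
  winners <- sort(names(tab)[tab == tab[1]])
  strsplit(winners[1], "\r", fixed = TRUE)[[1]]
}

#' TRBV x TRAV pairing counts
#'
#' Counts cells (or clones) using each observed combination of beta- and
#' alpha-chain variable genes; the underlying table for chord/circos
#' displays. Pairs with at least `label_threshold` counts are flagged as
#' labeled.
#'
#' @param clones Clone tibble.
#' @param weighting `"per_cell"` (default) or `"per_clone"` (majority pair).
#' @param label_threshold Minimum count for a pair to be labeled in a chord
#'   diagram (default 5).
#' @return Tibble of `sample_id`, `trbv`, `trav`, `count`, `labeled`. Row
#'   and column marginals equal the corresponding [usage_vector()] counts
#'   under the same weighting.
#' @export
pairing_matrix <- function(clones, weighting = c("per_cell", "per_clone"),
                           label_threshold = 5L) {
  weighting <- match.arg(weighting)
  assert_clone_tbl(clones)
  if (nrow(clones) == 0) abort("empty repertoire: no clones")
  pairs <- if (weighting == "per_cell") {
    clones |>
      dplyr::select("sample_id", "v_pairs") |>
      tidyr::unnest("v_pairs") |>
      dplyr::select("sample_id", "trbv", "trav")
  } else {
    clones |>
      dplyr::mutate(
        trbv = purrr::map_chr(.data$v_pairs, ~ majority_vpair(.x)[1]),
        trav = purrr::map_chr(.data$v_pairs, ~ majority_vpair(.x)[2])
      ) |>
      dplyr::select("sample_id", "trbv", "trav")
  }
  pairs |>
    dplyr::mutate(trbv = normalize_gene_name(.data$trbv),
                  trav = normalize_gene_name(.data$trav)) |>
    dplyr::count(.data$sample_id, .data$trbv, .data$trav, name = "count") |>
    dplyr::mutate(labeled = .data$count >= label_threshold) |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$count))
}

#' Pairwise correlation of germline usage across repertoires
#'
#' Aligns usage vectors to the union gene set (missing genes contribute 0),
#' computes pairwise Pearson (default) or Spearman correlations of the
#' frequency vectors, and orders samples by average-linkage hierarchical
#' clustering on distance `1 - r`.
#'
#' @param usage Usage tibble from [usage_vector()] covering >= 2 samples
#'   (or an externally supplied table with the same columns).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `usage_correlation` object: list with `correlation` (symmetric
#'   matrix, unit diagonal; `NA` where a vector has zero variance), `order`
#'   (dendrogram leaf order, sample ids) and `hclust` (or `NULL` when the
#'   correlation matrix is incomplete).
#' @export
usage_correlation <- function(usage, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_cols(usage, c("sample_id", "gene", "freq"), "usage table")
  samples <- sort(unique(usage$sample_id))
  if (length(samples) < 2) abort("usage correlation requires >= 2 samples")
  wide <- usage |>
    dplyr::select("sample_id", "gene", "freq") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "freq",
                       values_fill = 0) |>
    dplyr::arrange(.data$gene)
  mat <- as.matrix(wide[, samples, drop = FALSE])
  r <- suppressWarnings(cor(mat, method = method))
  diag(r) <- 1

  hc <- NULL
  ord <- samples
  if (!anyNA(r)) {
    hc <- hclust(as.dist(1 - r), method = "average")
    ord <- samples[hc$order]
  } else {
    warn("zero-variance usage vector: correlation NA for some pairs; no dendrogram")
  }
  structure(list(correlation = r, order = ord, hclust = hc, method = method),
            class = "usage_correlation")
}

#' @export
print.usage_correlation <- function(x, ...) {
  cat(sprintf("Germline usage correlation (%s) over %d samples\n",
              x$method, nrow(x$correlation)))
  print(round(x$correlation, 3))
  invisible(x)
}

#' Tidy a usage correlation into a long tibble
#'
#' @param x A `usage_correlation`.
#' @param ... Unused.
#' @return Tibble of `sample_i`, `sample_j`, `correlation` over unordered
#'   pairs.
#' @export
tidy.usage_correlation <- function(x, ...) {
  r <- x$correlation
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  tibble::tibble(
    sample_i = rownames(r)[pairs[, 1]],
    sample_j = colnames(r)[pairs[, 2]],
    correlation = r[pairs]
  )
}

#' Correlate sample usage against external reference usage tables
#'
#' Combines the repertoires' usage vectors with externally supplied usage
#' tables (e.g. published naive or CD4 repertoire profiles), normalizes gene
#' name dialects, re-normalizes frequencies over the union gene set, and
#' returns the combined correlation structure.
#'
#' @param usage Usage tibble from [usage_vector()].
#' @param external Tibble of `sample_id`, `gene` and `freq` (or `count`).
#' @param method Correlation estimator, as in [usage_correlation()].
#' @return A `usage_correlation` over the combined sample set. Gene names
#'   that cannot be interpreted as TR loci are reported with a warning.
#' @export
compare_external_usage <- function(usage, external,
                                   method = c("pearson", "spearman")) {
  assert_cols(external, c("sample_id", "gene"), "external usage table")
  if (!"freq" %in% names(external)) {
    assert_cols(external, "count", "external usage table")
    external <- external |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(freq = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
  }
  external <- dplyr::mutate(external, gene = normalize_gene_name(.data$gene))
  unresolved <- unique(external$gene[!grepl("^TR[ABGD][VDJC]", external$gene)])
  if (length(unresolved) > 0) {
    warn(sprintf("external gene name(s) not recognized as TR loci: %s",
                 paste(head(unresolved, 10), collapse = ", ")))
  }
  overlap_ids <- intersect(unique(usage$sample_id),
                           unique(external$sample_id))
  if (length(overlap_ids) > 0) {
    abort(sprintf("external sample id(s) collide with repertoire ids: %s",
                  paste(overlap_ids, collapse = ", ")))
  }
  combined <- dplyr::bind_rows(
    dplyr::select(usage, "sample_id", "gene", "freq"),
    dplyr::select(external, "sample_id", "gene", "freq")
  )
  # re-normalize per sample over the union gene set
  combined <- combined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(freq = .data$freq / sum(.data$freq)) |>
    dplyr::ungroup()
  usage_correlation(combined, method = method)
}
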