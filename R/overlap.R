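# Public (shared) clone quantification across repertoires by exact
# clonotype-key matching.

#' Pairwise clonal overlap matrix
#'
#' Counts exact clonotype-key matches (paired CDR3 nucleotide identity, or
#' optionally amino-acid identity) between every pair of repertoires. The
#' diagonal (a sample against itself) is set to `NA`.
#'
#' @param clones Clone tibble holding at least two samples.
#' @param restriction `"all"` (every clone), `"expanded_only"` (size >= 2) or
#'   `"top_n"` (the `n` most expanded clones per sample).
#' @param n Number of clones per sample; required iff
#'   `restriction == "top_n"`.
#' @param level `"nt"` (default, matches the clonotype key) or `"aa"` for
#'   amino-acid-level sharing.
#' @return A symmetric integer matrix with sample ids as dimnames, `NA`
#'   diagonal, and attributes `restriction` and `level`; class
#'   `"overlap_matrix"`.
#' @export
overlap_matrix <- function(clones,
                           restriction = c("all", "expanded_only", "top_n"),
                           n = NULL, level = c("nt", "aa")) {
  restriction <- match.arg(restriction)
  level <- match.arg(level)
  assert_clone_tbl(clones)
  samples <- sort(unique(clones$sample_id))
  if (length(samples) < 2) abort("overlap requires at least 2 repertoires")
  if (restriction == "top_n" && is.null(n)) {
    abort("n is required when restriction == 'top_n'")
  }
  if (restriction != "top_n" && !is.null(n)) {
    abort("n is only meaningful when restriction == 'top_n'")
  }

  restricted <- switch(restriction,
    all = clones,
    expanded_only = dplyr::filter(clones, .data$size >= 2L),
    top_n = top_clones(clones, n)
  )
  key <- if (level == "nt") restricted$clone_id else
    paste(restricted$cdr3b_aa, restricted$cdr3a_aa, sep = "_")
  keys <- split(key, factor(restricted$sample_id, levels = samples))

  m <- matrix(NA_integer_, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (i < j) {
        shared <- length(intersect(keys[[i]], keys[[j]]))
        m[i, j] <- shared
        m[j, i] <- shared
      }
    }
  }
  structure(m, restriction = restriction, level = level,
            class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Clonal overlap matrix (%d samples, restriction = %s, %s level)\n",
              nrow(x), attr(x, "restriction"), attr(x, "level")))
  print(unclass(x))
  invisible(x)
}

#' Tidy an overlap matrix into a long tibble
#'
#' @param x An `overlap_matrix`.
#' @param ... Unused.
#' @return Tibble of `sample_i`, `sample_j`, `shared` for each unordered
#'   pair.
#' @export
tidy.overlap_matrix <- function(x, ...) {
  samples <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    sample_i = samples[pairs[, 1]],
    sample_j = samples[pairs[, 2]],
    shared = as.integer(x[pairs])
  )
}

#' Table of public clones
#'
#' Lists every clonotype key found in two or more samples, with the number
#' of sharing samples and distinct group labels.
#'
#' @param clones Clone tibble holding at least two samples.
#' @return Tibble of `clone_id`, `samples_sharing`, `groups_sharing`
#'   (possibly empty).
#' @export
public_clone_table <- function(clones) {
  assert_clone_tbl(clones)
  if (dplyr::n_distinct(clones$sample_id) < 2) {
    abort("public clones require at least 2 repertoires")
  }
  clones |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      samples_sharing = dplyr::n_distinct(.data$sample_id),
      groups_sharing = dplyr::n_distinct(.data$group_label),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$samples_sharing >= 2) |>
    dplyr::arrange(dplyr::desc(.data$samples_sharing), .data$clone_id)
}

#' Write an overlap matrix as TSV with an NA diagonal
#'
#' @param x An `overlap_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "sample_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}
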