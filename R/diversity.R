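# Shannon entropy / Pielou evenness of clone-size distributions.

#' Shannon entropy of a clone-size distribution
#'
#' `H = -sum(p_i log p_i)` with `p_i = size_i / sum(sizes)`. Natural log by
#' default (nats); the base is configurable but evenness is
#' base-independent.
#'
#' @param sizes Vector of positive clone sizes (cells per clone).
#' @param base Logarithm base (default `exp(1)`).
#' @return Entropy in `[0, log(S)]` where `S = length(sizes)`.
#' @export
#' @examples
#' shannon_entropy(c(1, 1, 1, 1)) # log(4)
shannon_entropy <- function(sizes, base = exp(1)) {
  check_sizes(sizes)
  p <- sizes / sum(sizes)
  -sum(p * log(p, base = base))
}

#' Shannon (Pielou) evenness of a clone-size distribution
#'
#' `J = H / log(S)`: 1 for a perfectly even repertoire, approaching 0 when a
#' few clones dominate. A monoclonal repertoire (`S == 1`) is defined as 0
#' (with a warning), avoiding 0/0.
#'
#' @inheritParams shannon_entropy
#' @return Evenness in `[0, 1]`.
#' @export
shannon_evenness <- function(sizes) {
  check_sizes(sizes)
  s <- length(sizes)
  if (s == 1L) {
    warn("monoclonal repertoire: evenness defined as 0")
    return(0)
  }
  shannon_entropy(sizes) / log(s)
}

#' Fraction of singleton clones
#'
#' Share of clones supported by a single cell barcode.
#'
#' @inheritParams shannon_entropy
#' @return Fraction in `[0, 1]`.
#' @export
singleton_fraction <- function(sizes) {
  check_sizes(sizes)
  mean(sizes == 1)
}

check_sizes <- function(sizes) {
  if (length(sizes) == 0) abort("sizes must be non-empty")
  if (any(is.na(sizes)) || any(sizes < 1)) {
    abort("all clone sizes must be >= 1")
  }
  invisible(sizes)
}

#' Per-sample diversity summary
#'
#' Computes richness (clone count), Shannon entropy, Pielou evenness and the
#' singleton-clone fraction for each repertoire in a clone table.
#'
#' @param clones Clone tibble (one or more samples).
#' @return Tibble with one row per sample: `sample_id`, `group_label`,
#'   `n_cells`, `richness`, `shannon_entropy`, `shannon_evenness`,
#'   `fraction_singletons`.
#' @export
diversity_summary <- function(clones) {
  assert_clone_tbl(clones)
  if (nrow(clones) == 0) abort("empty repertoire: no clones")
  clones |>
    dplyr::group_by(.data$sample_id, .data$group_label) |>
    dplyr::summarise(
      n_cells = sum(.data$size),
      richness = dplyr::n(),
      shannon_entropy = shannon_entropy(.data$size),
      shannon_evenness = if (dplyr::n() == 1L) 0 else
        shannon_entropy(.data$size) / log(dplyr::n()),
      fraction_singletons = singleton_fraction(.data$size),
      .groups = "drop"
    )
}
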