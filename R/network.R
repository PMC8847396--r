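# CDR3 amino-acid edit-distance similarity networks across clones.

#' Levenshtein edit distance between amino-acid sequences
#'
#' Unit-cost insertion/deletion/substitution distance, vectorized over pairs
#' (arguments are recycled). Inputs must be strings over the 20-letter
#' amino-acid alphabet (empty strings allowed).
#'
#' @param a,b Character vectors of amino-acid sequences.
#' @return Integer vector of distances.
#' @export
#' @examples
#' edit_distance("CASSDAGGRNTLYF", "CASSDAGGANTLYF") # 1
edit_distance <- function(a, b) {
  assert_aa_strings(a, "a")
  assert_aa_strings(b, "b")
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- adist(a[i], b[i])
  out
}

#' Build a CDR3 similarity network over clones from all samples
#'
#' One node per (clone, sample); identical clonotypes in different samples
#' are distinct nodes connected at distance 0. Edit distances are computed
#' separately for the TRB and TRA CDR3 amino-acid sequences, then edges are
#' drawn under the threshold rule: `sum` mode connects clones with
#' `dist_b + dist_a <= threshold`; `per_chain` mode requires each chain's
#' distance to satisfy the threshold.
#'
#' @param clones Clone tibble (any number of samples).
#' @param threshold Non-negative integer edit-distance threshold
#'   (inclusive); default 7.
#' @param mode `"sum"` (default) or `"per_chain"`.
#' @param dedupe If `TRUE`, collapse nodes sharing identical paired
#'   amino-acid CDR3s within a sample (synonymous clonotypes) before
#'   computing edges.
#' @return A `tcr_network`: list with `nodes` (tibble: `node`, `clone_id`,
#'   `sample_id`, `group_label`, `cdr3b_aa`, `cdr3a_aa`, `size`), `edges`
#'   (tibble: `node_i`, `node_j`, `dist_b`, `dist_a`, `dist_total`),
#'   `threshold` and `mode`.
#' @export
build_network <- function(clones, threshold = 7L,
                          mode = c("sum", "per_chain"), dedupe = FALSE) {
  mode <- match.arg(mode)
  assert_clone_tbl(clones)
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    abort("threshold must be a single integer >= 0")
  }
  nodes <- clones |>
    dplyr::select("clone_id", "sample_id", "group_label",
                  "cdr3b_aa", "cdr3a_aa", "size")
  if (dedupe) {
    nodes <- dplyr::distinct(nodes, .data$sample_id, .data$cdr3b_aa,
                             .data$cdr3a_aa, .keep_all = TRUE)
  }
  nodes <- nodes |>
    dplyr::arrange(.data$sample_id, .data$clone_id) |>
    dplyr::mutate(node = paste(.data$sample_id, .data$clone_id, sep = ":"),
                  .before = 1)

  edges <- network_edges(nodes, threshold, mode)
  structure(
    list(nodes = nodes, edges = edges,
         threshold = as.integer(threshold), mode = mode),
    class = "tcr_network"
  )
}

# all-pairs chain distances via adist, thresholded
network_edges <- function(nodes, threshold, mode) {
  empty <- tibble::tibble(
    node_i = character(), node_j = character(),
    dist_b = integer(), dist_a = integer(), dist_total = integer()
  )
  n <- nrow(nodes)
  if (n < 2) return(empty)
  assert_aa_strings(nodes$cdr3b_aa, "cdr3b_aa")
  assert_aa_strings(nodes$cdr3a_aa, "cdr3a_aa")
  db <- adist(nodes$cdr3b_aa)
  da <- adist(nodes$cdr3a_aa)
  pass <- if (mode == "sum") (db + da) <= threshold else
    db <= threshold & da <= threshold
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    node_i = nodes$node[idx[, 1]],
    node_j = nodes$node[idx[, 2]],
    dist_b = as.integer(db[idx]),
    dist_a = as.integer(da[idx]),
    dist_total = as.integer(db[idx] + da[idx])
  )
}

#' @export
print.tcr_network <- function(x, ...) {
  cat(sprintf(
    "CDR3 similarity network: %d nodes, %d edges (threshold %d, mode %s)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, x$mode
  ))
  invisible(x)
}

#' Tidy a similarity network into its edge table
#'
#' @param x A `tcr_network`.
#' @param ... Unused.
#' @return The edge tibble, annotated with the endpoint group labels and an
#'   `edge_type` of `"within_group"` or `"between_group"`.
#' @export
tidy.tcr_network <- function(x, ...) {
  grp <- setNames(x$nodes$group_label, x$nodes$node)
  x$edges |>
    dplyr::mutate(
      group_i = unname(grp[.data$node_i]),
      group_j = unname(grp[.data$node_j]),
      edge_type = dplyr::if_else(.data$group_i == .data$group_j,
                                 "within_group", "between_group")
    )
}

#' One-row summary of a similarity network
#'
#' @param x A `tcr_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts and the within/between-group edge
#'   partition.
#' @export
glance.tcr_network <- function(x, ...) {
  ed <- tidy(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    within_group_edges = sum(ed$edge_type == "within_group"),
    between_group_edges = sum(ed$edge_type == "between_group"),
    threshold = x$threshold,
    mode = x$mode
  )
}

#' Partition network edges by endpoint group labels
#'
#' @param net A `tcr_network` whose nodes carry group labels.
#' @return List with `within_group_edges`, `between_group_edges`,
#'   `group_pair_counts` (tibble, symmetric canonical ordering) and
#'   `degrees` (per-node degree tibble).
#' @export
edge_group_summary <- function(net) {
  stopifnot(inherits(net, "tcr_network"))
  ed <- tidy(net)
  pair_counts <- ed |>
    dplyr::mutate(
      g1 = pmin(.data$group_i, .data$group_j),
      g2 = pmax(.data$group_i, .data$group_j)
    ) |>
    dplyr::count(.data$g1, .data$g2, name = "n_edges")
  degrees <- tibble::tibble(node = c(ed$node_i, ed$node_j)) |>
    dplyr::count(.data$node, name = "degree") |>
    dplyr::right_join(dplyr::select(net$nodes, "node", "sample_id",
                                    "group_label"), by = "node") |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0L)) |>
    dplyr::arrange(.data$node)
  list(
    within_group_edges = sum(ed$edge_type == "within_group"),
    between_group_edges = sum(ed$edge_type == "between_group"),
    group_pair_counts = pair_counts,
    degrees = degrees
  )
}

#' Edge counts across a range of thresholds
#'
#' Recomputes the network at each threshold (distances are computed once)
#' and reports total, within-group and between-group edge counts.
#'
#' @param clones Clone tibble.
#' @param thresholds Non-empty vector of non-negative integers.
#' @param mode `"sum"` or `"per_chain"`.
#' @return Tibble of `threshold`, `n_edges`, `within_group_edges`,
#'   `between_group_edges`; edge counts are monotone non-decreasing in the
#'   threshold.
#' @export
threshold_sweep <- function(clones, thresholds, mode = c("sum", "per_chain")) {
  mode <- match.arg(mode)
  if (length(thresholds) == 0) abort("thresholds must be non-empty")
  assert_clone_tbl(clones)
  if (nrow(clones) == 0) {
    return(tibble::tibble(threshold = integer(), n_edges = integer(),
                          within_group_edges = integer(),
                          between_group_edges = integer()))
  }
  purrr::map_dfr(sort(as.integer(thresholds)), function(t) {
    g <- glance(build_network(clones, threshold = t, mode = mode))
    tibble::tibble(threshold = t, n_edges = g$n_edges,
                   within_group_edges = g$within_group_edges,
                   between_group_edges = g$between_group_edges)
  })
}

#' Convert a similarity network to an igraph object
#'
#' @param net A `tcr_network`.
#' @return An `igraph` graph with node attributes from the node table and
#'   edge distance attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "tcr_network"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the igraph package is required for graph export")
  }
  igraph::graph_from_data_frame(
    d = net$edges,
    directed = FALSE,
    vertices = dplyr::rename(net$nodes, name = "node")
  )
}

#' Write a similarity network as GraphML (plus node/edge TSVs)
#'
#' @param net A `tcr_network`.
#' @param path Output GraphML path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
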