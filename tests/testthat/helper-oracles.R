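# Independent oracles and programmatic fixtures shared across tests.

# Memoized recursive Levenshtein distance: an implementation independent of
# the production path (which is based on utils::adist).
lev_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (av[i] == bv[j]) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# brute-force edge set using the independent recursive distance oracle
brute_edges <- function(nodes, threshold, mode) {
  out <- list()
  n <- nrow(nodes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      db <- lev_oracle(nodes$cdr3b_aa[i], nodes$cdr3b_aa[j])
      da <- lev_oracle(nodes$cdr3a_aa[i], nodes$cdr3a_aa[j])
      ok <- if (mode == "sum") db + da <= threshold else
        db <= threshold && da <= threshold
      if (ok) out[[length(out) + 1]] <-
          sort(c(nodes$node[i], nodes$node[j]))
    }
  }
  if (length(out) == 0) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  sort(apply(cbind(net$edges$node_i, net$edges$node_j), 1,
             function(r) paste(sort(r), collapse = "|")))
}

# deterministic distinct pseudo-nucleotide string for fixture rows
fake_nt <- function(i, len = 15L) {
  withr::with_seed(10000L + i, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""
  ))
}

rand_aa <- function(n, min_len = 8L, max_len = 16L) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    paste(sample(clonoscope:::AA_ALPHABET, len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# contig tibble in the in-memory format read_contigs() produces
contig_fixture <- function(barcode, locus, cdr3_nt = NULL, cdr3_aa = "CASSF",
                           v_gene = NULL, productive = TRUE, is_cell = TRUE,
                           high_confidence = TRUE, umis = 1L,
                           sample_id = "s1") {
  n <- length(barcode)
  if (is.null(cdr3_nt)) cdr3_nt <- vapply(seq_len(n), fake_nt, character(1))
  if (is.null(v_gene)) {
    v_gene <- ifelse(locus == "TRB", "TRBV13-1", "TRAV14-1")
  }
  tibble::tibble(
    barcode = barcode, sample_id = sample_id, locus = locus,
    cdr3_nt = rep_len(cdr3_nt, n), cdr3_aa = rep_len(cdr3_aa, n),
    v_gene = rep_len(v_gene, n), d_gene = NA_character_,
    j_gene = ifelse(locus == "TRB", "TRBJ2-7", "TRAJ33"),
    productive = rep_len(productive, n), is_cell = rep_len(is_cell, n),
    high_confidence = rep_len(high_confidence, n),
    umis = rep_len(as.integer(umis), n)
  )
}

# clone tibble with all required columns, keys taken from the aa sequences
fake_clone_tbl <- function(sample_id, group_label, cdr3b_aa, cdr3a_aa,
                           size = 1L, trbv = "TRBV1", trav = "TRAV1",
                           cdr3b_nt = NULL, cdr3a_nt = NULL) {
  n <- max(length(cdr3b_aa), length(cdr3a_aa), length(size))
  cdr3b_aa <- rep_len(cdr3b_aa, n)
  cdr3a_aa <- rep_len(cdr3a_aa, n)
  size <- rep_len(as.integer(size), n)
  sample_id <- rep_len(sample_id, n)
  group_label <- rep_len(group_label, n)
  trbv <- rep_len(trbv, n)
  trav <- rep_len(trav, n)
  cdr3b_nt <- if (is.null(cdr3b_nt)) cdr3b_aa else rep_len(cdr3b_nt, n)
  cdr3a_nt <- if (is.null(cdr3a_nt)) cdr3a_aa else rep_len(cdr3a_nt, n)
  tibble::tibble(
    sample_id = sample_id, group_label = group_label,
    clone_id = paste(cdr3b_nt, cdr3a_nt, sep = "_"),
    cdr3b_nt = cdr3b_nt, cdr3a_nt = cdr3a_nt,
    cdr3b_aa = cdr3b_aa, cdr3a_aa = cdr3a_aa, size = size,
    member_barcodes = purrr::map2(seq_len(n), size, function(i, s) {
      sprintf("%s_%s.%s_bc%d", sample_id[i], cdr3b_nt[i], cdr3a_nt[i],
              seq_len(s))
    }),
    v_pairs = purrr::pmap(list(seq_len(n), size, trbv, trav),
                          function(i, s, vb, va) {
      tibble::tibble(
        barcode = sprintf("%s_%s.%s_bc%d", sample_id[i], cdr3b_nt[i],
                          cdr3a_nt[i], seq_len(s)),
        trbv = vb, trav = va
      )
    })
  )
}

# clones + annotations realizing a given 2x2 expansion-by-cluster table
assoc_fixture <- function(expanded_in, expanded_out, lowly_in, lowly_out,
                          cluster_in = "A", cluster_out = "B",
                          sample_id = "s1") {
  n_exp <- expanded_in + expanded_out
  n_low <- lowly_in + lowly_out
  clones <- dplyr::bind_rows(
    fake_clone_tbl(sample_id, "g", "CASSEXPF", "CAEXPF", size = n_exp),
    fake_clone_tbl(sample_id, "g",
                   sprintf("CASSL%dF", seq_len(n_low)), "CALOWF",
                   size = 1L)
  ) |> classify_expansion()
  cells <- clone_cells(clones)
  exp_bc <- cells$barcode[cells$expansion_class == "expanded"]
  low_bc <- cells$barcode[cells$expansion_class == "lowly_expanded"]
  ann <- tibble::tibble(
    barcode = c(exp_bc, low_bc),
    sample_id = sample_id,
    group_label = "g",
    cluster_id = c(rep(cluster_in, expanded_in),
                   rep(cluster_out, expanded_out),
                   rep(cluster_in, lowly_in),
                   rep(cluster_out, lowly_out))
  )
  list(clones = clones, annotations = ann)
}

# write a contig tibble as a 10x-dialect CSV file
write_tenx_csv <- function(contigs_10x, path) {
  readr::write_csv(contigs_10x, path, progress = FALSE)
  path
}

# ingest a generated cohort back through the pipeline surface
cohort_clones <- function(cohort) {
  cfg <- cohort$config
  td <- withr::local_tempdir(.local_envir = parent.frame())
  purrr::map2_dfr(
    cfg$samples$sample_id, cfg$samples$group_label,
    function(sid, grp) {
      f <- file.path(td, paste0(sid, ".csv"))
      readr::write_csv(cohort$contigs[[sid]], f, progress = FALSE)
      cells <- assemble_cells(read_contigs(f, "tenx_csv", sid))
      classify_expansion(build_clones(cells, grp))
    }
  )
}
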