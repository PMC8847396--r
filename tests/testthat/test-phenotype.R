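test_that("clone cluster composition computes per-clone fractions", {
  clones <- classify_expansion(
    fake_clone_tbl("m1", "g", c("A", "B"), "X", size = c(4L, 1L))
  )
  cells <- clone_cells(clones)
  ann <- tibble::tibble(
    barcode = cells$barcode, sample_id = "m1", group_label = "g",
    cluster_id = c("1", "1", "3", "3", "7")
  )
  comp <- clone_cluster_composition(clones, ann)
  a <- comp[comp$clone_id == "A_X", ]
  expect_equal(sort(a$fraction), c(0.5, 0.5))
  expect_setequal(a$cluster_id, c("1", "3"))
  b <- comp[comp$clone_id == "B_X", ]
  expect_equal(b$fraction, 1.0)
  expect_equal(b$cluster_id, "7")
})

test_that("top_n restricts composition to the most expanded clones", {
  clones <- classify_expansion(fake_clone_tbl(
    "m1", "g", sprintf("C%02d", 1:40), "X", size = rep(c(5L, 1L), 20)
  ))
  cells <- clone_cells(clones)
  ann <- tibble::tibble(barcode = cells$barcode, sample_id = "m1",
                        group_label = "g", cluster_id = "0")
  comp <- clone_cluster_composition(clones, ann, top_n = 15)
  expect_equal(dplyr::n_distinct(comp$clone_id), 15)
  expect_true(all(comp$size == 5L))
})

test_that("unannotated cells are dropped and empty clones omitted with messages", {
  clones <- classify_expansion(
    fake_clone_tbl("m1", "g", c("A", "B"), "X", size = c(2L, 1L))
  )
  cells <- clone_cells(clones)
  ann <- tibble::tibble(
    barcode = cells$barcode[cells$clone_id == "A_X"][1],
    sample_id = "m1", group_label = "g", cluster_id = "2"
  )
  expect_message(
    expect_message(comp <- clone_cluster_composition(clones, ann),
                   "without a cluster annotation"),
    "omitted"
  )
  expect_equal(comp$clone_id, "A_X")
  expect_equal(comp$fraction, 1.0)
})

test_that("stratum composition pools cells across clones of one stratum", {
  fx <- assoc_fixture(6, 4, 3, 7, cluster_in = "5", cluster_out = "7")
  comp_e <- stratum_composition(fx$clones, fx$annotations, "expanded")
  expect_equal(comp_e$fraction[comp_e$cluster_id == "5"], 0.6)
  expect_equal(comp_e$fraction[comp_e$cluster_id == "7"], 0.4)
  expect_equal(unique(comp_e$n_cells), 10)
  comp_l <- stratum_composition(fx$clones, fx$annotations, "lowly_expanded")
  expect_equal(sum(comp_l$fraction), 1, tolerance = 1e-12)
  # every lowly expanded clone is one cell
  expect_equal(unique(comp_l$n_cells),
               sum(fx$clones$expansion_class == "lowly_expanded"))

  all_exp <- classify_expansion(fake_clone_tbl("m1", "g", "A", "X",
                                               size = 3L))
  expect_error(
    stratum_composition(all_exp, tibble::tibble(
      barcode = character(), sample_id = character(),
      cluster_id = character()
    ), "lowly_expanded"),
    "lowly_expanded"
  )
})

test_that("association odds ratios match the closed form, with continuity correction at zeros", {
  fx <- assoc_fixture(30, 10, 10, 30)
  res <- expansion_cluster_association(fx$clones, fx$annotations)
  a_row <- res[res$cluster_id == "A", ]
  expect_equal(a_row$odds_ratio, 9.0, tolerance = 1e-12)
  expect_lt(a_row$p_value, 0.001)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))

  # zero cell: [[5,0],[5,5]] -> OR on [[5.5,0.5],[5.5,5.5]]
  fx0 <- assoc_fixture(5, 0, 5, 5)
  res0 <- expansion_cluster_association(fx0$clones, fx0$annotations)
  expect_equal(res0$odds_ratio[res0$cluster_id == "A"],
               (5.5 * 5.5) / (0.5 * 5.5), tolerance = 1e-12)

  # identical composition in both strata: OR 1, p ~ 1
  fx1 <- assoc_fixture(10, 10, 10, 10)
  res1 <- expansion_cluster_association(fx1$clones, fx1$annotations)
  expect_equal(res1$odds_ratio, c(1, 1), tolerance = 1e-12)
  expect_gt(min(res1$p_value), 0.99)

  # chi-squared route agrees directionally
  res_chi <- expansion_cluster_association(fx$clones, fx$annotations,
                                           method = "chi2")
  expect_lt(res_chi$p_value[res_chi$cluster_id == "A"], 0.001)
})

test_that("cell conservation: stratum cluster counts sum to stratum cell counts", {
  fx <- assoc_fixture(12, 8, 5, 15)
  res <- expansion_cluster_association(fx$clones, fx$annotations)
  expect_equal(unique(res$expanded_in + res$expanded_out), 20)
  expect_equal(unique(res$lowly_in + res$lowly_out), 20)
  comp <- stratum_composition(fx$clones, fx$annotations, "expanded")
  expect_equal(sum(comp$n), unique(comp$n_cells))
})

test_that("motif matrices count positional residue frequencies over unique sequences", {
  clones <- fake_clone_tbl("m1", "g", c("CASSF", "CASSF"), "CAVF",
                           cdr3b_nt = c("nt1", "nt2"))
  m <- motif_matrix(clones, "TRB", length = 5)
  expect_equal(attr(m, "n_sequences"), 1) # deduplicated
  expect_equal(unname(m[1, "C"]), 1.0)
  expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)

  m_all <- motif_matrix(clones, "TRB", length = 5, unique_sequences = FALSE)
  expect_equal(attr(m_all, "n_sequences"), 2)

  clones2 <- fake_clone_tbl("m1", "g", c("CAAAF", "CTTTF"), "CAVF")
  m2 <- motif_matrix(clones2, "TRB", length = 5)
  expect_equal(unname(m2[2, "A"]), 0.5)
  expect_equal(unname(m2[2, "T"]), 0.5)

  expect_error(motif_matrix(clones2, "TRB", length = 9), "available lengths")
})

test_that("motif contrasts subtract entrywise with zero row sums", {
  c1 <- fake_clone_tbl("m1", "g", c("CAAAF", "CARNF"), "CAVF")
  c2 <- fake_clone_tbl("m2", "g", c("CTTTF", "CTQSF"), "CAVF")
  m1 <- motif_matrix(c1, "TRB", 5)
  m2 <- motif_matrix(c2, "TRB", 5)
  d <- motif_contrast(m1, m2)
  expect_equal(unname(rowSums(d)), rep(0, 5), tolerance = 1e-12)
  expect_equal(max(abs(motif_contrast(m1, m1))), 0)
  # disjoint residue usage at position 2: +/-1 entries
  expect_equal(unname(d[2, "A"]), 1)
  expect_equal(unname(d[2, "T"]), -1)

  c3 <- fake_clone_tbl("m3", "g", "CAAATTF", "CAVF")
  expect_error(motif_contrast(m1, motif_matrix(c3, "TRB", 7)),
               "length mismatch")
})
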