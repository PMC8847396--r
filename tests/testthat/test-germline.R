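test_that("per-cell usage counts each cell once and normalizes to 1", {
  clones <- fake_clone_tbl("m1", "g", c("A", "B", "C", "D"), "X",
                           trbv = "TRBV19")
  uv <- usage_vector(clones, "TRBV")
  expect_equal(uv$freq, 1.0)
  expect_equal(uv$gene, "TRBV19")

  clones2 <- fake_clone_tbl("m1", "g", c("A", "B", "C"), "X",
                            trbv = c("TRBV13-1", "TRBV13-1", "TRBV29"))
  uv2 <- usage_vector(clones2, "TRBV")
  expect_equal(uv2$freq[uv2$gene == "TRBV13-1"], 2 / 3, tolerance = 1e-12)
  expect_equal(uv2$freq[uv2$gene == "TRBV29"], 1 / 3, tolerance = 1e-12)
  expect_equal(sum(uv2$freq), 1, tolerance = 1e-12)
})

test_that("per-clone weighting uses the majority V gene with lexicographic ties", {
  clone <- fake_clone_tbl("m1", "g", "A", "X", size = 5L)
  clone$v_pairs[[1]]$trbv <- c("TRBV19", "TRBV19", "TRBV19", "TRBV29",
                               "TRBV29")
  uv <- usage_vector(clone, "TRBV", weighting = "per_clone")
  expect_equal(uv$gene[uv$count == 1], "TRBV19")
  expect_equal(sum(uv$count), 1) # one count per clone

  tie <- fake_clone_tbl("m1", "g", "A", "X", size = 2L)
  tie$v_pairs[[1]]$trbv <- c("TRBV29", "TRBV19")
  uv_tie <- usage_vector(tie, "TRBV", weighting = "per_clone")
  expect_equal(uv_tie$gene[uv_tie$count == 1], "TRBV19")
})

test_that("pairing matrix marginals equal usage counts and labeling obeys the threshold", {
  clones <- dplyr::bind_rows(
    fake_clone_tbl("m1", "g", "A", "X", size = 7L,
                   trbv = "TRBV19", trav = "TRAV14-1"),
    fake_clone_tbl("m1", "g", "B", "Y", size = 4L,
                   trbv = "TRBV19", trav = "TRAV2")
  )
  pm <- pairing_matrix(clones, label_threshold = 5)
  expect_equal(nrow(pm), 2)
  expect_equal(sum(pm$labeled), 1)
  expect_equal(pm$count[pm$labeled], 7)

  uv <- usage_vector(clones, "TRBV")
  marg <- pm |> dplyr::group_by(trbv) |>
    dplyr::summarise(count = sum(count))
  expect_equal(marg$count[marg$trbv == "TRBV19"],
               uv$count[uv$gene == "TRBV19"])
  uva <- usage_vector(clones, "TRAV")
  marg_a <- pm |> dplyr::group_by(trav) |>
    dplyr::summarise(count = sum(count))
  expect_equal(
    dplyr::arrange(marg_a, trav)$count,
    dplyr::arrange(uva, gene)$count
  )
})

test_that("usage correlation hits the closed-form extremes", {
  u <- dplyr::bind_rows(
    tibble::tibble(sample_id = "m1", gene = c("TRBV1", "TRBV2"),
                   count = c(3L, 1L), freq = c(0.75, 0.25)),
    tibble::tibble(sample_id = "m2", gene = c("TRBV1", "TRBV2"),
                   count = c(6L, 2L), freq = c(0.75, 0.25)),
    tibble::tibble(sample_id = "m3", gene = c("TRBV1", "TRBV2"),
                   count = c(0L, 5L), freq = c(0, 1))
  )
  uc <- usage_correlation(u)
  expect_equal(uc$correlation["m1", "m2"], 1.0, tolerance = 1e-12)
  expect_equal(uc$correlation["m1", "m3"], -1.0, tolerance = 1e-12)
  expect_equal(diag(uc$correlation), c(m1 = 1, m2 = 1, m3 = 1))
  expect_setequal(uc$order, c("m1", "m2", "m3"))
  expect_equal(nrow(tidy(uc)), 3)
})

test_that("zero-variance usage vectors give NA correlations with a warning", {
  u <- dplyr::bind_rows(
    tibble::tibble(sample_id = "m1", gene = "TRBV1", freq = 1),
    tibble::tibble(sample_id = "m2", gene = "TRBV1", freq = 1)
  )
  expect_warning(uc <- usage_correlation(u), "zero-variance")
  expect_true(is.na(uc$correlation["m1", "m2"]))
})

test_that("external usage is aligned over the union gene set with name normalization", {
  clones <- fake_clone_tbl("m1", "g", c("A", "B", "C"), "X",
                           trbv = c("TRBV13-1", "TRBV13-1", "TRBV29"))
  uv <- usage_vector(clones, "TRBV")

  # identical external profile, dotted-dialect names + allele suffixes
  ext_same <- tibble::tibble(
    sample_id = "ref_same", gene = c("TRBV13.1*01", "TRBV29*02"),
    freq = c(2 / 3, 1 / 3)
  )
  uc <- compare_external_usage(uv, ext_same)
  expect_equal(uc$correlation["m1", "ref_same"], 1.0, tolerance = 1e-12)

  # exactly uniform external profile: zero variance, Pearson undefined
  ext_unif <- tibble::tibble(
    sample_id = "ref_unif",
    gene = c("TRBV13-1", "TRBV29", "TRBV1", "TRBV2"),
    freq = rep(0.25, 4)
  )
  expect_warning(uc2 <- compare_external_usage(uv, ext_unif),
                 "zero-variance")
  expect_true(is.na(uc2$correlation["m1", "ref_unif"]))

  # near-uniform external profile vs the concentrated sample: r < 1
  ext_flat <- tibble::tibble(
    sample_id = "ref_flat",
    gene = c("TRBV13-1", "TRBV29", "TRBV1", "TRBV2"),
    freq = c(0.26, 0.26, 0.24, 0.24)
  )
  uc2b <- compare_external_usage(uv, ext_flat)
  expect_lt(uc2b$correlation["m1", "ref_flat"], 1)

  # disjoint support over 6 genes: equals the hand Pearson computation
  ua <- c(0.5, 0.3, 0.2, 0, 0, 0)
  ub <- c(0, 0, 0, 0.6, 0.3, 0.1)
  ext_disj <- tibble::tibble(
    sample_id = "ref_disj",
    gene = paste0("TRBV", 1:6), freq = ub
  )
  u6 <- tibble::tibble(sample_id = "m6", gene = paste0("TRBV", 1:6),
                       freq = ua, count = 1L)
  uc3 <- compare_external_usage(u6, ext_disj)
  hand <- sum((ua - mean(ua)) * (ub - mean(ub))) /
    sqrt(sum((ua - mean(ua))^2) * sum((ub - mean(ub))^2))
  expect_equal(uc3$correlation["m6", "ref_disj"], hand, tolerance = 1e-12)

  expect_warning(
    compare_external_usage(uv, tibble::tibble(
      sample_id = "bad", gene = c("IGHV1-2", "TRBV29"), freq = c(0.5, 0.5)
    )),
    "not recognized"
  )
})

test_that("samples from the same germline base profile cluster together", {
  cfg <- generator_config(
    seed = 5,
    samples = default_cohort_samples(n_clones = 200L, max_size = 20L),
    p_drop_tra = 0, p_drop_trb = 0, p_extra_chain = 0,
    public_clone_rate = 0
  )
  clones <- cohort_clones(generate_cohort(cfg))
  uc <- usage_correlation(usage_vector(clones, "both"))
  part <- stats::cutree(uc$hclust, k = 3)
  planted <- sub("_m[12]$", "", names(part))
  # every planted group maps to exactly one dendrogram branch
  expect_equal(length(unique(paste(planted, part))), 3)
})
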