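test_that("10x dialect parses fields and keeps only TRA/TRB loci", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "barcode,chain,cdr3,cdr3_nt,v_gene,j_gene,productive,is_cell,high_confidence,umis",
    "b1-1,TRB,CASSF,TGTGCCAGCAGCTTT,TRBV19,TRBJ2-7,True,True,True,4",
    "b2-1,TRB,CASRF,TGTGCCAGCAGGTTT,TRBV13-1,TRBJ1-1,True,True,True,2",
    "b3-1,TRG,CATWF,TGTGCCACCTGGTTT,TRGV2,TRGJ1,True,True,True,1"
  ), f)
  rec <- suppressMessages(read_contigs(f, "tenx_csv", sample_id = "m1"))
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$locus, "TRB")
  expect_equal(rec$cdr3_aa[rec$barcode == "b1-1"], "CASSF")
  expect_equal(rec$umis[rec$barcode == "b1-1"], 4L)
  expect_true(all(rec$sample_id == "m1"))
})

test_that("AIRR dialect maps junction fields; missing flags default true", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("cell_id", "locus", "junction", "junction_aa", "v_call", "j_call",
          "productive", sep = "\t"),
    paste("b1", "TRB", "TGTGCCAGCAGCTTT", "CASSF", "TRBV19", "TRBJ2-7",
          "true", sep = "\t")
  ), f)
  rec <- read_contigs(f, "airr_tsv", sample_id = "m1")
  expect_equal(nchar(rec$cdr3_aa), 5L)
  expect_equal(nchar(rec$cdr3_nt), 15L)
  expect_true(rec$is_cell)
  expect_true(rec$high_confidence)
  expect_equal(rec$umis, 0L)
})

test_that("header-only files yield empty records; missing columns are named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(clonoscope:::TENX_REQUIRED, collapse = ","), f)
  expect_equal(nrow(read_contigs(f, "tenx_csv", "m1")), 0)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,chain,cdr3", "b1,TRB,CASSF"), g)
  expect_error(read_contigs(g, "tenx_csv", "m1"), "cdr3_nt")
})

test_that("assemble_cells keeps exactly one TRA + one TRB and the report reconciles", {
  contigs <- dplyr::bind_rows(
    contig_fixture("b1", "TRA", cdr3_nt = "TGTGCTAAATTT"),
    contig_fixture("b1", "TRB", cdr3_nt = "TGTGCCAAATTC"),
    contig_fixture(c("b2", "b2"), "TRB", cdr3_nt = c("TGTAAA", "TGTCCC")),
    contig_fixture("b2", "TRA", cdr3_nt = "TGTGGG"),
    contig_fixture("b3", "TRA", cdr3_nt = "TGTTTT")
  )
  cells <- assemble_cells(contigs)
  expect_equal(cells$barcode, "b1")
  rep <- filter_report(cells)
  expect_equal(rep$retained, 1)
  expect_equal(rep$multi_trb, 1) # b2
  expect_equal(rep$no_trb, 1)    # b3
  # conservation: every barcode accounted for exactly once
  expect_equal(
    rep$retained + rep$failed_predicates + rep$no_tra + rep$multi_tra +
      rep$no_trb + rep$multi_trb,
    rep$n_barcodes
  )
})

test_that("retention predicates are applied before chain counting", {
  # b4: 1 productive TRB + 1 non-productive TRB + 1 TRA
  base <- dplyr::bind_rows(
    contig_fixture("b4", "TRB", cdr3_nt = "TGTAAA", productive = TRUE),
    contig_fixture("b4", "TRB", cdr3_nt = "TGTCCC", productive = FALSE),
    contig_fixture("b4", "TRA", cdr3_nt = "TGTGGG")
  )
  expect_equal(assemble_cells(base, require_productive = TRUE)$barcode, "b4")
  expect_equal(nrow(assemble_cells(base, require_productive = FALSE)), 0)
  expect_equal(
    filter_report(assemble_cells(base, require_productive = FALSE))$multi_trb,
    1
  )

  # enumerate all 8 predicate-flag combinations on a contig failing each one
  for (fail_field in c("productive", "is_cell", "high_confidence")) {
    for (req_p in c(TRUE, FALSE)) for (req_c in c(TRUE, FALSE)) {
      for (req_h in c(TRUE, FALSE)) {
        extra <- contig_fixture("bx", "TRB", cdr3_nt = "TGTCCC")
        extra[[fail_field]] <- FALSE
        contigs <- dplyr::bind_rows(
          contig_fixture("bx", "TRB", cdr3_nt = "TGTAAA"),
          contig_fixture("bx", "TRA", cdr3_nt = "TGTGGG"),
          extra
        )
        cells <- assemble_cells(contigs, require_productive = req_p,
                                require_cell = req_c,
                                require_high_confidence = req_h)
        dropped <- switch(fail_field, productive = req_p,
                          is_cell = req_c, high_confidence = req_h)
        # if the failing contig is dropped, bx has 1 TRB + 1 TRA; else 2 TRB
        expect_equal(nrow(cells), as.integer(dropped),
                     info = paste(fail_field, req_p, req_c, req_h))
      }
    }
  }
})

test_that("identical (barcode, locus, cdr3_nt) rows are deduplicated", {
  contigs <- dplyr::bind_rows(
    contig_fixture(c("b1", "b1"), "TRB", cdr3_nt = "TGTAAA"),
    contig_fixture("b1", "TRA", cdr3_nt = "TGTGGG")
  )
  expect_equal(assemble_cells(contigs)$barcode, "b1")
})

test_that("empty input assembles to an empty cell set with an all-zero report", {
  cells <- assemble_cells(contig_fixture(character(0), character(0)))
  expect_equal(nrow(cells), 0)
  expect_true(all(unlist(filter_report(cells)) == 0))
})

test_that("annotations parse, preserve cluster ids, and reject duplicate keys", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    barcode = c("b1", "b2", "b3", "b4"), sample_id = "m1",
    group_label = "acute", cluster_id = c("0", "7", "03", "7")
  ), f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 4)
  expect_equal(sort(unique(ann$cluster_id)), c("0", "03", "7"))

  g <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    barcode = c("b1", "b1"), sample_id = "m1",
    group_label = "acute", cluster_id = c("0", "1")
  ), g)
  expect_error(read_annotations(g), "b1")
})

test_that("write_airr round-trips through read+assemble to the same cells", {
  cfg <- generator_config(
    seed = 11,
    samples = tibble::tibble(
      sample_id = "m1", group_label = "acute", n_clones = 40L,
      law = "powerlaw", alpha = 2.5, q = NA_real_, max_size = 5L
    ),
    p_drop_tra = 0, p_drop_trb = 0, p_extra_chain = 0,
    public_clone_rate = 0
  )
  gen <- generate_repertoire(cfg, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gen$contigs, f)
  cells <- assemble_cells(read_contigs(f, "tenx_csv", "m1"))
  expect_gte(nrow(cells), 40)

  airr <- withr::local_tempfile(fileext = ".tsv")
  write_airr(cells, airr)
  cells2 <- assemble_cells(read_contigs(airr, "airr_tsv", "m1"))
  common <- c("barcode", "sample_id", "cdr3b_nt", "cdr3a_nt", "cdr3b_aa",
              "cdr3a_aa", "trbv", "trbj", "trav", "traj")
  expect_equal(as.data.frame(cells2[common]), as.data.frame(cells[common]))
})

test_that("write_airr refuses cells with an empty CDR3", {
  cells <- assemble_cells(dplyr::bind_rows(
    contig_fixture("b1", "TRB", cdr3_nt = "TGTAAA"),
    contig_fixture("b1", "TRA", cdr3_nt = "TGTGGG")
  ))
  cells$cdr3b_nt <- ""
  expect_error(write_airr(cells, tempfile()), "empty CDR3")
})
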