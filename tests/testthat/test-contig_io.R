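# Contig parsing, filtering, cell assembly and population gating.

write_contig_lines <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- paste(c("barcode", "is_cell", "contig_id", "high_confidence",
                    "length", "chain", "v_gene", "d_gene", "j_gene", "c_gene",
                    "full_length", "productive", "cdr3", "cdr3_nt", "reads",
                    "umis", "raw_clonotype_id", "raw_consensus_id"),
                  collapse = ",")
  writeLines(c(header, rows), path)
  path
}

contig_line <- function(bc, chain = "TRA", v = "TRAV1-2", j = "TRAJ33",
                        cdr3 = "CAVMDSNYQLIW", nt = "TGTGCAGTC",
                        hc = "True", fl = "True", prod = "True", umis = "3") {
  paste(bc, "True", paste0(bc, "_contig_1"), hc, "500", chain, v, "None", j,
        "TRAC", fl, prod, cdr3, nt, "100", umis, "clonotype1", "None",
        sep = ",")
}

test_that("contig tables parse row-for-row with dialect booleans", {
  path <- write_contig_lines(c(
    contig_line("bc1", chain = "TRA"),
    contig_line("bc2", chain = "TRB", v = "TRBV6-4", j = "TRBJ2-1"),
    contig_line("bc2", chain = "TRB", v = "TRBV20-1", j = "TRBJ2-7",
                hc = "true", fl = "false")))
  tab <- read_contig_table(path)
  expect_equal(nrow(tab), 3L)
  expect_type(tab$high_confidence, "logical")
  expect_equal(tab$full_length, c(TRUE, TRUE, FALSE))
  expect_equal(tab$umis, c(3, 3, 3))
  expect_true(is.na(tab$d_gene[1L]))

  empty <- write_contig_lines(character())
  expect_equal(nrow(read_contig_table(empty)), 0L)
})

test_that("missing columns and bad booleans are hard errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("barcode,chain,v_gene", "bc1,TRA,TRAV1-2"), path)
  expect_error(read_contig_table(path), "j_gene")

  bad <- write_contig_lines(contig_line("bc1", prod = "maybe"))
  expect_error(read_contig_table(bad), "row 1")
})

test_that("contig filter equals the per-record predicate and is idempotent", {
  rows <- c(
    contig_line("k1"),                                   # keep
    contig_line("k2", chain = "TRB", v = "TRBV9"),       # keep
    contig_line("d1", hc = "False"),                     # fails one flag
    contig_line("d2", fl = "False"),
    contig_line("d3", prod = "False"),
    contig_line("d4", chain = "IGH", v = "IGHV1-2"),     # not a TCR chain
    contig_line("k3"), contig_line("k4"), contig_line("k5"),
    contig_line("d5", prod = "None"))
  tab <- read_contig_table(write_contig_lines(rows))
  kept <- filter_contigs(tab)
  predicate <- function(i) {
    isTRUE(tab$high_confidence[i]) && isTRUE(tab$full_length[i]) &&
      isTRUE(tab$productive[i]) && tab$chain[i] %in% c("TRA", "TRB")
  }
  expect_equal(kept$barcode, tab$barcode[vapply(seq_len(nrow(tab)), predicate,
                                                logical(1L))])
  expect_equal(nrow(kept), 5L)
  expect_identical(filter_contigs(kept), kept)
})

test_that("doublet rule matches full enumeration over chain counts", {
  rows <- list()
  meta_rows <- list()
  for (a in 0:3) {
    for (b in 0:3) {
      if (a + b == 0) next
      bc <- sprintf("bc_a%d_b%d", a, b)
      for (i in seq_len(a)) {
        rows[[length(rows) + 1L]] <- chain_row(bc, "TRA", "TRAV1-2", "TRAJ33",
                                               sprintf("CAV%d%sF", i, bc))
      }
      for (i in seq_len(b)) {
        rows[[length(rows) + 1L]] <- chain_row(bc, "TRB", "TRBV6-4", "TRBJ2-1",
                                               sprintf("CASS%d%sF", i, bc))
      }
      meta_rows[[length(meta_rows) + 1L]] <-
        tibble::tibble(barcode = bc, donor = "d1", tissue = "blood")
    }
  }
  chains <- do.call(rbind, rows)
  contigs <- tibble::tibble(
    barcode = chains$barcode, chain = chains$locus, v_gene = chains$v_gene,
    d_gene = NA_character_, j_gene = chains$j_gene, cdr3 = chains$cdr3_aa,
    cdr3_nt = chains$cdr3_nt, high_confidence = TRUE, full_length = TRUE,
    productive = TRUE, umis = 1)
  cs <- assemble_cells(contigs, do.call(rbind, meta_rows))
  kept <- cs$cells$barcode
  for (a in 0:3) {
    for (b in 0:3) {
      if (a + b == 0) next
      bc <- sprintf("bc_a%d_b%d", a, b)
      expected_keep <- !((a == 2 && b == 2) || a > 2 || b > 2)
      expect_equal(bc %in% kept, expected_keep, label = bc)
    }
  }
  # discarded: (2,2); a=3 with b in 0..3; b=3 with a in 0..2
  expect_equal(attr(cs, "n_doublets"), 8L)
})

test_that("duplicate contigs collapse to the highest-UMI copy", {
  contigs <- tibble::tibble(
    barcode = "bc1", chain = c("TRA", "TRA", "TRB"),
    v_gene = c("TRAV1-2", "TRAV1-2", "TRBV9"), d_gene = NA_character_,
    j_gene = c("TRAJ33", "TRAJ33", "TRBJ2-1"),
    cdr3 = c("CAVF", "CAVF", "CASSF"), cdr3_nt = c("TGT", "TGT", "TGC"),
    high_confidence = TRUE, full_length = TRUE, productive = TRUE,
    umis = c(2, 9, 4))
  cs <- assemble_cells(contigs)
  expect_equal(nrow(cs$chains), 2L)
  expect_equal(cs$chains$umis[cs$chains$locus == "TRA"], 9)
})

test_that("barcodes absent from metadata are flagged unassigned", {
  contigs <- tibble::tibble(
    barcode = c("bc1", "bc2"), chain = c("TRA", "TRA"),
    v_gene = "TRAV1-2", d_gene = NA_character_, j_gene = "TRAJ33",
    cdr3 = c("CAVF", "CAVG"), cdr3_nt = c("TGT", "TGC"),
    high_confidence = TRUE, full_length = TRUE, productive = TRUE, umis = 1)
  meta <- tibble::tibble(barcode = "bc1", donor = "d1", tissue = "blood")
  expect_warning(cs <- assemble_cells(contigs, meta), "unassigned")
  expect_equal(cs$cells$population[cs$cells$barcode == "bc2"], "unassigned")
})

test_that("population gates follow the chain-usage rules", {
  specs <- list(
    mait_ok = list(alpha = "TRAV1-2/TRAJ33/CAVMDSNYQLIF",
                   beta = "TRBV6-4/TRBJ2-1/CASSALATGELFF"),
    mait_allele = list(alpha = "TRAV1-2*01/TRAJ12/CAVMDSSYKLIF",
                       beta = "TRBV9/TRBJ2-3/CASSVDTQYF"),
    no_beta = list(alpha = "TRAV1-2/TRAJ33/CAVRDSNYQLIF"),
    not_trav12 = list(alpha = "TRAV8-2/TRAJ33/CAVKDSNYQLIF",
                      beta = "TRBV9/TRBJ2-3/CASSVETQYF"),
    tmem_contam = list(alpha = "TRAV1-2/TRAJ33/CAVMDSNYQLIG",   # 12 aa
                       beta = "TRBV19/TRBJ2-1/CASSIRSSYEQYF"),
    tmem_13aa = list(alpha = "TRAV1-2/TRAJ33/CAVMDSSNYQLIF",    # 13 aa
                     beta = "TRBV19/TRBJ2-1/CASSIRSTYEQYF"))
  cells <- cells_from_specs(specs)

  mait <- gate_cells(cells, "MAIT")
  # any TRAV1-2 alpha plus a beta passes the MAIT gate, including the
  # 13-aa-CDR3 cell (it merely escapes the Tmem contamination filter)
  expect_setequal(mait$cells$barcode,
                  c("mait_ok", "mait_allele", "tmem_contam", "tmem_13aa"))

  tmem <- gate_cells(cells, "Tmem")
  # 12-aa TRAV1-2/TRAJ33|12|20 alphas are removed as contaminating MAIT
  expect_setequal(tmem$cells$barcode, c("not_trav12", "tmem_13aa"))
  # a 12-aa TRAV1-2/TRAJ33 alpha is removed as contaminating; 13 aa retained
  expect_false("tmem_contam" %in% tmem$cells$barcode)
  expect_true("tmem_13aa" %in% tmem$cells$barcode)

  expect_error(gate_cells(cells, "NKT"), "unknown population")
})

test_that("generated contig files round-trip losslessly", {
  cfg <- repertoire_config(donors = 1, cells_per_sample = 60,
                           public_alpha_count = 2, seed = 42)
  sim <- generate_repertoire(cfg)
  path <- tempfile(fileext = ".csv")
  write_contig_csv(sim$contigs, path)
  back <- read_contig_table(path)
  for (col in c("barcode", "chain", "v_gene", "d_gene", "j_gene", "cdr3",
                "cdr3_nt", "high_confidence", "full_length", "productive",
                "umis")) {
    expect_equal(back[[col]], sim$contigs[[col]], label = col)
  }
})

test_that("MAIT and Tmem gates are disjoint and filtering feeds gating", {
  # canonical-TRAJ repertoire: every alpha is a 12-aa TRAV1-2 chain with
  # TRAJ33/12/20, so the Tmem contamination filter removes every MAIT cell
  cfg <- repertoire_config(donors = 1, cells_per_sample = 150,
                           public_alpha_count = 2,
                           traj_probs = c(TRAJ33 = 0.87, TRAJ12 = 0.07,
                                          TRAJ20 = 0.06, other = 0),
                           seed = 9)
  sim <- generate_repertoire(cfg)
  cs <- assemble_cells(filter_contigs(sim$contigs), sim$meta)
  mait <- gate_cells(cs, "MAIT")
  tmem <- gate_cells(cs, "Tmem")
  expect_length(intersect(mait$cells$barcode, tmem$cells$barcode), 0L)
})
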