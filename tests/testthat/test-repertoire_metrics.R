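# Diversity, clonality, pairing, sharing, publicness and downsampling.

test_that("Shannon index matches the direct formula and its extremes", {
  expect_equal(shannon_index(7), 0)
  expect_equal(shannon_index(c(1, 1)), log(2), tolerance = 1e-12)
  direct <- function(s) { p <- s / sum(s); -sum(p * log(p)) }
  expect_equal(shannon_index(c(5, 3, 2)), direct(c(5, 3, 2)),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    s <- sample(1:40, sample(2:25, 1), replace = TRUE)
    expect_equal(shannon_index(s), direct(s), tolerance = 1e-12)
    expect_equal(shannon_index(s), shannon_index(rev(s)))  # relabeling
  }
  expect_equal(shannon_index(rep(4, 9)), log(9), tolerance = 1e-12)
  expect_error(shannon_index(numeric()), "empty")
})

test_that("clonality curves are sorted cumulative fractions ending at 1", {
  expect_equal(clonality_curve(c(1, 1, 1, 1))$cum_fraction,
               c(0.25, 0.5, 0.75, 1))
  expect_equal(clonality_curve(c(1, 9))$cum_fraction, c(0.9, 1))
  set.seed(3)
  for (i in 1:25) {
    s <- sample(1:50, sample(2:30, 1), replace = TRUE)
    curve <- clonality_curve(s)
    expect_true(all(diff(curve$cum_fraction) >= 0))
    expect_true(all(diff(diff(curve$cum_fraction)) <= 1e-12))  # sorted sense
    expect_equal(curve$cum_fraction[nrow(curve)], 1)
  }
})

promiscuity_fixture <- function() {
  # one alpha chain reused by three clones with distinct betas, plus a
  # private pair
  specs <- list(
    p1 = list(alpha = "TRAV1-2/TRAJ33/CAVS", beta = "TRBV6-1/TRBJ2-1/CASB1"),
    p2 = list(alpha = "TRAV1-2/TRAJ33/CAVS", beta = "TRBV6-4/TRBJ2-1/CASB2"),
    p3 = list(alpha = "TRAV1-2/TRAJ33/CAVS", beta = "TRBV20-1/TRBJ2-7/CASB3"),
    q1 = list(alpha = "TRAV1-2/TRAJ12/CAVT", beta = "TRBV9/TRBJ2-3/CASB4"))
  cells_from_specs(specs)
}

test_that("pairing promiscuity counts unique partner chains", {
  cells <- promiscuity_fixture()
  out <- chain_pairing_promiscuity(cells, "a", scope = "donor")
  prom <- stats::setNames(out$n_partners, sub(".*CAV", "CAV", out$chain))
  expect_equal(unname(prom[grep("CAVS", names(prom))]), 3L)
  expect_equal(unname(prom[grep("CAVT", names(prom))]), 1L)
  # every beta pairs with a single alpha here
  beta_out <- chain_pairing_promiscuity(cells, "b", scope = "donor")
  expect_true(all(beta_out$n_partners == 1L))
})

test_that("a dual-alpha cell contributes a pairing for each alpha", {
  specs <- list(
    c1 = list(alpha = c("TRAV1-2/TRAJ33/CAVA", "TRAV1-2/TRAJ12/CAVB"),
              beta = "TRBV20-1/TRBJ2-1/CASB1"))
  tab <- traj_trbv_pairing_table(cells_from_specs(specs))
  bd <- tab$by_donor
  expect_setequal(unique(bd$traj), c("TRAJ33", "TRAJ12"))
  for (tj in c("TRAJ33", "TRAJ12")) {
    expect_equal(bd$pct[bd$traj == tj & bd$trbv == "TRBV20-1"], 100)
  }
})

test_that("pairing rows are percentages summing to 100 with missing rows absent", {
  specs <- list(
    c1 = list(alpha = "TRAV1-2/TRAJ12/CAVA", beta = "TRBV6-4/TRBJ2-1/CASB1"),
    c2 = list(alpha = "TRAV1-2/TRAJ12/CAVB", beta = "TRBV6-4/TRBJ2-1/CASB2"))
  tab <- traj_trbv_pairing_table(cells_from_specs(specs))
  bd <- tab$by_donor
  expect_equal(unique(bd$traj), "TRAJ12")  # TRAJ33/TRAJ20 rows missing
  expect_equal(bd$pct[bd$trbv == "TRBV6-4"], 100)
  expect_equal(sum(bd$pct), 100)
})

test_that("segment usage sums to one and ignores cell order", {
  cfg <- repertoire_config(donors = 1, cells_per_sample = 200,
                           public_alpha_count = 3, seed = 5)
  cells <- ingest_simulation(generate_repertoire(cfg))
  u <- segment_usage(cells, "TRAJ")
  expect_equal(sum(u$prop), 1, tolerance = 1e-12)
  shuffled <- cells
  perm <- sample(nrow(shuffled$chains))
  shuffled$chains <- shuffled$chains[perm, , drop = FALSE]
  u2 <- segment_usage(shuffled, "TRAJ")
  expect_equal(u[order(u$gene), ]$prop, u2[order(u2$gene), ]$prop)

  single <- make_cell_set(rbind(
    chain_row("c1", "TRA", "TRAV1-2", "TRAJ33", "CAVA"),
    chain_row("c1", "TRB", "TRBV9", "TRBJ2-1", "CASB")))
  expect_equal(segment_usage(single, "TRAJ")$prop, 1)
})

test_that("cross-sample sharing spans the identical and disjoint extremes", {
  cfg <- repertoire_config(donors = 1, cells_per_sample = 200,
                           public_alpha_count = 3, seed = 6)
  cells <- ingest_simulation(generate_repertoire(cfg))
  tab <- call_nucleotide_clonotypes(cells, "ab")
  self <- cross_sample_sharing(tab, tab)
  expect_equal(self$pct_a, 100)
  expect_equal(self$pct_b, 100)

  specsA <- list(a1 = list(alpha = "TRAV1-2/TRAJ33/CAVA",
                           beta = "TRBV9/TRBJ2-1/CASA"))
  specsB <- list(b1 = list(alpha = "TRAV1-2/TRAJ12/CAVB",
                           beta = "TRBV9/TRBJ2-1/CASB"))
  ta <- call_nucleotide_clonotypes(cells_from_specs(specsA), "ab")
  tb <- call_nucleotide_clonotypes(cells_from_specs(specsB), "ab")
  disjoint <- cross_sample_sharing(ta, tb)
  expect_equal(disjoint$pct_a, 0)
  expect_equal(disjoint$pct_b, 0)

  fn <- call_functional_clonotypes(cells, "ab")
  expect_error(cross_sample_sharing(tab, fn), "different definition levels")
})

test_that("shared-clonotype frequency correlation matches the closed form", {
  make_table <- function(sizes, level = "nt-ab") {
    ids <- paste0("ct", seq_along(sizes))
    structure(list(
      level = level,
      assignment = tibble::tibble(
        barcode = paste0("b", seq_len(sum(sizes))),
        clonotype_id = rep(ids, sizes), ambiguous = FALSE),
      clonotypes = tibble::tibble(clonotype_id = ids,
                                  signature = paste0("sig", seq_along(sizes)),
                                  size = as.integer(sizes),
                                  number = NA_integer_, rank = NA_integer_)),
      class = "clonotype_table")
  }
  ta <- make_table(c(10, 5, 3, 2))
  tb <- make_table(c(8, 6, 4, 1))
  out <- shared_clonotype_frequency_correlation(ta, tb)
  fa <- log10(c(10, 5, 3, 2) / 20)
  fb <- log10(c(8, 6, 4, 1) / 19)
  closed <- sum((fa - mean(fa)) * (fb - mean(fb))) /
    sqrt(sum((fa - mean(fa))^2) * sum((fb - mean(fb))^2))
  expect_equal(out$r, closed, tolerance = 1e-12)

  expect_equal(shared_clonotype_frequency_correlation(ta, ta)$r, 1,
               tolerance = 1e-12)
  small <- make_table(c(3, 2))
  expect_true(shared_clonotype_frequency_correlation(small, small)$undefined)
})

test_that("publicness spectrum bins cells by donor occupancy", {
  shared_spec <- list(s = list(alpha = "TRAV1-2/TRAJ33/CAVP",
                               beta = "TRBV9/TRBJ2-1/CASP"))
  tabs <- lapply(1:4, function(d) {
    specs <- shared_spec
    names(specs) <- paste0("cell_d", d)
    call_functional_clonotypes(cells_from_specs(specs, donor = paste0("d", d)),
                               "ab")
  })
  names(tabs) <- paste0("d", 1:4)
  spec <- publicness_spectrum(tabs)
  expect_equal(spec$n_cells[spec$k == 4], rep(1L, 4L))
  expect_equal(sum(spec$n_cells), 4L)

  private_tabs <- lapply(1:3, function(d) {
    specs <- list(x = list(alpha = sprintf("TRAV1-2/TRAJ33/CAVD%d", d),
                           beta = sprintf("TRBV9/TRBJ2-1/CASD%d", d)))
    names(specs) <- paste0("cell_d", d)
    call_functional_clonotypes(cells_from_specs(specs), "ab")
  })
  names(private_tabs) <- paste0("d", 1:3)
  pspec <- publicness_spectrum(private_tabs)
  expect_equal(pspec$n_cells[pspec$k == 1], rep(1L, 3L))

  nt_tabs <- lapply(private_tabs, function(t) { t$level <- "nt-ab"; t })
  expect_error(publicness_spectrum(nt_tabs), "functional")

  # per-donor bins sum to the donor's assigned cells on real-sized data
  cfg <- repertoire_config(donors = 3, cells_per_sample = 150, seed = 8,
                           public_alpha_count = 3, tissues = "blood")
  sim <- generate_repertoire(cfg)
  cells <- ingest_simulation(sim)
  by_donor <- split(cells$cells$barcode, cells$cells$donor)
  tabs2 <- lapply(by_donor, function(bcs)
    call_functional_clonotypes(clonolink:::subset_cell_set(cells, bcs), "ab"))
  spec2 <- publicness_spectrum(tabs2)
  sums <- tapply(spec2$n_cells, spec2$donor, sum)
  expect_equal(as.integer(sums[names(by_donor)]),
               unname(lengths(by_donor)))
})

test_that("downsampling compares equal-sized groups fairly", {
  # equal sizes: no resampling, metrics equal direct computation
  a <- tibble::tibble(stratum = "d1", clonotype_id = rep(c("x", "y"), c(6, 4)))
  b <- tibble::tibble(stratum = "d1", clonotype_id = rep(c("u", "v"), c(5, 5)))
  out <- downsampled_comparison(a, b, n_reps = 5, seed = 1)
  expect_equal(out$summary$mean_unique, c(2, 2))
  expect_equal(out$summary$mean_shannon[1], shannon_index(c(6, 4)))
  expect_equal(out$summary$mean_shannon[2], shannon_index(c(5, 5)))

  # a subset with identical clone structure shows ~no unique-count difference
  set.seed(20)
  big <- tibble::tibble(stratum = "d1",
                        clonotype_id = sample(paste0("c", 1:30), 400,
                                              replace = TRUE, prob = 30:1))
  small <- big[sample(400, 200), ]
  out2 <- downsampled_comparison(big, small, n_reps = 100, seed = 2)
  diff_unique <- diff(out2$summary$mean_unique)
  expect_lt(abs(diff_unique), 1.5)

  # planted higher evenness in A shows up as higher mean Shannon
  even <- tibble::tibble(stratum = "d1",
                         clonotype_id = rep(paste0("e", 1:20), each = 10))
  skew <- tibble::tibble(stratum = "d1",
                         clonotype_id = rep(paste0("s", 1:20), c(181, rep(1, 19))))
  out3 <- downsampled_comparison(even, skew, n_reps = 20, seed = 3)
  expect_gt(out3$summary$mean_shannon[out3$summary$group == "A"],
            out3$summary$mean_shannon[out3$summary$group == "B"])

  # empty stratum is skipped with a warning
  b2 <- rbind(b, tibble::tibble(stratum = "d2", clonotype_id = "z"))
  expect_warning(downsampled_comparison(a, b2, n_reps = 2, seed = 4),
                 "skipped")
})

test_that("capture rate is a guarded ratio", {
  expect_equal(tcr_capture_rate(10, 0), 0)
  expect_equal(tcr_capture_rate(10, 10), 1)
  expect_equal(tcr_capture_rate(20, 7), 0.35)
  expect_true(is.na(tcr_capture_rate(0, 0)))
  expect_error(tcr_capture_rate(5, 6), "counts")
})
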