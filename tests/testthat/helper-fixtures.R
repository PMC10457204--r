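# Fixture builders and independent oracles used across the suite.

# Build a chain row in the internal representation.
chain_row <- function(barcode, locus, v, j, aa, nt = NULL, umis = 1) {
  tibble::tibble(barcode = barcode, locus = locus, v_gene = v, j_gene = j,
                 cdr3_nt = nt %||% paste0("NT_", aa), cdr3_aa = aa,
                 umis = umis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble a cell_set directly from a chains tibble (bypassing CSV parsing).
make_cell_set <- function(chains, donor = "d1", tissue = "blood",
                          population = "MAIT") {
  barcodes <- unique(chains$barcode)
  cells <- tibble::tibble(
    barcode = barcodes,
    n_alpha = vapply(barcodes, function(b)
      sum(chains$barcode == b & chains$locus == "TRA"), integer(1L)),
    n_beta = vapply(barcodes, function(b)
      sum(chains$barcode == b & chains$locus == "TRB"), integer(1L)),
    donor = donor, tissue = tissue, condition = "unstimulated",
    timepoint = 0, population = population)
  structure(list(cells = cells, chains = chains), class = "cell_set")
}

# Shorthand: cells described as list(barcode = list(alpha_aa, beta_aa)) where
# each chain is "V/J/CDR3aa" (alpha) or "V/J/CDR3aa" (beta).
parse_chain_spec <- function(barcode, spec, locus) {
  parts <- strsplit(spec, "/", fixed = TRUE)[[1L]]
  chain_row(barcode, locus, parts[1L], parts[2L], parts[3L])
}

cells_from_specs <- function(specs, ...) {
  rows <- list()
  for (bc in names(specs)) {
    for (a in specs[[bc]]$alpha %||% character()) {
      rows[[length(rows) + 1L]] <- parse_chain_spec(bc, a, "TRA")
    }
    for (b in specs[[bc]]$beta %||% character()) {
      rows[[length(rows) + 1L]] <- parse_chain_spec(bc, b, "TRB")
    }
  }
  make_cell_set(do.call(rbind, rows), ...)
}

# Independent brute-force multinomial oracle: enumerate every composition
# with expand-style recursion and sum dmultinom masses.
bf_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (i in 0:n) {
    sub <- bf_compositions(n - i, k - 1L)
    out <- rbind(out, cbind(rep(i, nrow(sub)), sub))
  }
  out
}

bf_multinom_p <- function(observed, probs) {
  comps <- bf_compositions(sum(observed), length(observed))
  pr <- apply(comps, 1L, stats::dmultinom, prob = probs)
  p_obs <- stats::dmultinom(observed, prob = probs)
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Competition-rank oracle: stable sort then first-index rank per size.
bf_competition_rank <- function(sizes) {
  vapply(sizes, function(s) sum(sizes > s) + 1L, integer(1L))
}

# Brute-force recovery-curve score for one cell.
bf_aucell <- function(x, in_set, top_fraction) {
  G <- length(x)
  max_rank <- ceiling(top_fraction * G)
  r <- rank(-x, ties.method = "first")
  cum <- vapply(seq_len(max_rank), function(rr) sum(in_set & r <= rr),
                numeric(1L))
  auc <- sum(cum)
  m <- min(sum(in_set), max_rank)
  best <- vapply(seq_len(max_rank), function(rr) min(rr, m), numeric(1L))
  auc / sum(best)
}

# Per-cell amino-acid signatures of a cell set at the paired level.
bf_cell_signatures <- function(cells) {
  ch <- cells$chains
  keys <- paste(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_aa, sep = "|")
  sp <- split(keys, ch$barcode)
  vapply(sp, function(k) paste(sort(unique(k)), collapse = "+"), character(1L))
}

bf_is_subset <- function(sig_a, sig_b) {
  a <- strsplit(sig_a, "+", fixed = TRUE)[[1L]]
  b <- strsplit(sig_b, "+", fixed = TRUE)[[1L]]
  all(a %in% b)
}

# run the standard ingest pipeline on a generated study
ingest_simulation <- function(sim, population = "MAIT") {
  gate_cells(assemble_cells(filter_contigs(sim$contigs), sim$meta), population)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
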