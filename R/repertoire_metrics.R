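# Repertoire-level summaries: diversity, clonality, chain pairing,
# cross-tissue sharing, publicness and downsampled comparisons.

#' Shannon diversity index of a clone size vector
#'
#' H = -sum(p_i log p_i) in nats, with p_i the clonotype frequencies.
#' Computed with the standard community-diversity routine.
#'
#' @param sizes Positive clone sizes (cells per clonotype).
#' @return The Shannon index in nats.
#' @export
shannon_index <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L) stop("empty clone size vector")
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("clone sizes must be positive and finite")
  }
  as.numeric(vegan::diversity(sizes, index = "shannon"))
}

#' Cumulative clonality curve
#'
#' Clonotypes are sorted by descending size; point r is the cumulative
#' fraction of cells contained in the r largest clonotypes. The curve is
#' non-decreasing and ends at 1.
#'
#' @inheritParams shannon_index
#' @return A tibble with columns `rank` and `cum_fraction`.
#' @export
clonality_curve <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L) stop("empty clone size vector")
  s <- sort(sizes, decreasing = TRUE)
  tibble::tibble(rank = seq_along(s), cum_fraction = cumsum(s) / sum(s))
}

# cell-level alpha-beta co-occurrence pairs at nucleotide chain identity
alpha_beta_pairs <- function(cells) {
  ch <- cells$chains
  key <- chain_key(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_nt)
  by_bc <- split(seq_len(nrow(ch)), ch$barcode)
  pairs <- lapply(by_bc, function(idx) {
    a <- idx[ch$locus[idx] == "TRA"]
    b <- idx[ch$locus[idx] == "TRB"]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    expand.grid(alpha = a, beta = b, KEEP.OUT.ATTRS = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    return(tibble::tibble(barcode = character(), alpha_key = character(),
                          beta_key = character(), alpha_j = character(),
                          beta_v = character(), donor = character(),
                          tissue = character()))
  }
  bc <- ch$barcode[pairs$alpha]
  meta_idx <- match(bc, cells$cells$barcode)
  tibble::tibble(
    barcode = bc,
    alpha_key = key[pairs$alpha],
    beta_key = key[pairs$beta],
    alpha_j = strip_allele(ch$j_gene[pairs$alpha]),
    beta_v = strip_allele(ch$v_gene[pairs$beta]),
    donor = cells$cells$donor[meta_idx],
    tissue = cells$cells$tissue[meta_idx]
  )
}

#' Chain-pairing promiscuity
#'
#' For every unique focal chain (nucleotide identity), the number of unique
#' partner-locus chains it co-occurs with within cells of the scope group. A
#' cell with two alpha chains and one beta chain contributes one
#' co-occurrence per alpha-beta combination.
#'
#' @param cells A gated `cell_set`.
#' @param focal_locus `"a"` (count unique beta partners per alpha chain) or
#'   `"b"`.
#' @param scope `"donor_tissue"` (per donor and tissue) or `"donor"`
#'   (tissues combined).
#' @return A tibble with the scope columns, `chain` (focal chain key) and
#'   `n_partners`.
#' @export
chain_pairing_promiscuity <- function(cells, focal_locus = c("a", "b"),
                                      scope = c("donor_tissue", "donor")) {
  focal_locus <- normalise_level(match.arg(normalise_level(focal_locus[1L]),
                                           c("a", "b")))
  scope <- match.arg(scope)
  pr <- alpha_beta_pairs(cells)
  if (focal_locus == "a") {
    focal <- pr$alpha_key; partner <- pr$beta_key
  } else {
    focal <- pr$beta_key; partner <- pr$alpha_key
  }
  grp <- if (scope == "donor_tissue") paste(pr$donor, pr$tissue, sep = "\r") else as.character(pr$donor)
  key <- paste(grp, focal, sep = "\n")
  counts <- tapply(partner, key, function(x) length(unique(x)))
  parts <- strsplit(names(counts), "\n", fixed = TRUE)
  grp_out <- vapply(parts, `[`, character(1L), 1L)
  chain_out <- vapply(parts, `[`, character(1L), 2L)
  out <- tibble::tibble(chain = chain_out, n_partners = as.integer(counts))
  if (scope == "donor_tissue") {
    gp <- strsplit(grp_out, "\r", fixed = TRUE)
    out$donor <- vapply(gp, `[`, character(1L), 1L)
    out$tissue <- vapply(gp, `[`, character(1L), 2L)
    out <- out[, c("donor", "tissue", "chain", "n_partners")]
  } else {
    out$donor <- grp_out
    out <- out[, c("donor", "chain", "n_partners")]
  }
  out
}

#' TRAJ x TRBV pairing table
#'
#' Percentage of alpha chains using each of the canonical MAIT TRAJ genes
#' that pair (cell-level co-occurrence) with each focal TRBV gene or any
#' other TRBV. Rows sum to 100 within each donor; a donor with no chains of
#' a TRAJ yields a missing row. The summary reports the mean and s.e.m.
#' across donors.
#'
#' @param cells A MAIT-gated `cell_set`.
#' @param traj_genes TRAJ genes of interest.
#' @param trbv_focus TRBV genes reported individually; all others are pooled
#'   as `"other"`.
#' @return A list with `by_donor` (donor, traj, trbv, pct) and `summary`
#'   (traj, trbv, mean_pct, sem) tibbles.
#' @export
traj_trbv_pairing_table <- function(cells,
                                    traj_genes = c("TRAJ33", "TRAJ12", "TRAJ20"),
                                    trbv_focus = c("TRBV6-1", "TRBV6-4", "TRBV20-1")) {
  pr <- alpha_beta_pairs(cells)
  pr <- pr[pr$alpha_j %in% traj_genes, , drop = FALSE]
  trbv_levels <- c(trbv_focus, "other")
  pr$trbv <- ifelse(pr$beta_v %in% trbv_focus, pr$beta_v, "other")
  donors <- unique(cells$cells$donor)
  rows <- list()
  for (d in donors) {
    sub <- pr[pr$donor %in% d, , drop = FALSE]
    for (tj in traj_genes) {
      sj <- sub[sub$alpha_j == tj, , drop = FALSE]
      if (nrow(sj) == 0L) next  # missing row, not zero
      counts <- table(factor(sj$trbv, levels = trbv_levels))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        donor = d, traj = tj, trbv = trbv_levels,
        pct = 100 * as.numeric(counts) / sum(counts))
    }
  }
  by_donor <- if (length(rows) > 0L) do.call(rbind, rows) else
    tibble::tibble(donor = character(), traj = character(),
                   trbv = character(), pct = numeric())
  key <- paste(by_donor$traj, by_donor$trbv, sep = "\r")
  mean_pct <- tapply(by_donor$pct, key, mean)
  sem <- tapply(by_donor$pct, key, function(x)
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_)
  parts <- strsplit(names(mean_pct), "\r", fixed = TRUE)
  summary <- tibble::tibble(
    traj = vapply(parts, `[`, character(1L), 1L),
    trbv = vapply(parts, `[`, character(1L), 2L),
    mean_pct = as.numeric(mean_pct),
    sem = as.numeric(sem)
  )
  list(by_donor = by_donor, summary = summary)
}

#' Gene segment usage proportions
#'
#' Proportion of chains (not cells) using each gene segment; TRAJ usage is
#' computed over alpha chains, TRBV usage over beta chains.
#'
#' @param cells A gated `cell_set`.
#' @param segment `"TRAJ"` or `"TRBV"`.
#' @param by `"overall"`, `"donor"` or `"sample"` (donor and tissue).
#' @return A tibble with grouping columns, `gene` and `prop` (proportions sum
#'   to 1 within each group).
#' @export
segment_usage <- function(cells, segment = c("TRAJ", "TRBV"),
                          by = c("overall", "donor", "sample")) {
  segment <- match.arg(segment)
  by <- match.arg(by)
  ch <- cells$chains
  if (segment == "TRAJ") {
    ch <- ch[ch$locus == "TRA", , drop = FALSE]
    gene <- strip_allele(ch$j_gene)
  } else {
    ch <- ch[ch$locus == "TRB", , drop = FALSE]
    gene <- strip_allele(ch$v_gene)
  }
  meta_idx <- match(ch$barcode, cells$cells$barcode)
  grp <- switch(by,
                overall = rep("all", nrow(ch)),
                donor = as.character(cells$cells$donor[meta_idx]),
                sample = paste(cells$cells$donor[meta_idx],
                               cells$cells$tissue[meta_idx], sep = "/"))
  key <- paste(grp, gene, sep = "\r")
  counts <- table(key)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- tibble::tibble(
    group = vapply(parts, `[`, character(1L), 1L),
    gene = vapply(parts, `[`, character(1L), 2L),
    n = as.integer(counts)
  )
  totals <- tapply(out$n, out$group, sum)
  out$prop <- out$n / as.numeric(totals[out$group])
  out
}

#' Cross-sample clonotype sharing
#'
#' Percentage of cells in each sample whose clonotype chain-set signature
#' also occurs in the other sample (for example matched blood and liver from
#' one donor).
#'
#' @param table_a,table_b `clonotype_table`s at the same definition level.
#' @return A list with `shared_signatures`, `pct_a`, `pct_b` and cell counts.
#' @export
cross_sample_sharing <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "clonotype_table"),
            inherits(table_b, "clonotype_table"))
  if (table_a$level != table_b$level) {
    stop("clonotype tables are at different definition levels")
  }
  shared <- intersect(table_a$clonotypes$signature, table_b$clonotypes$signature)
  cells_in <- function(tab) {
    ids <- tab$clonotypes$clonotype_id[tab$clonotypes$signature %in% shared]
    sum(tab$assignment$clonotype_id %in% ids)
  }
  n_a <- nrow(table_a$assignment)
  n_b <- nrow(table_b$assignment)
  list(shared_signatures = shared,
       n_shared = length(shared),
       pct_a = if (n_a > 0L) 100 * cells_in(table_a) / n_a else NA_real_,
       pct_b = if (n_b > 0L) 100 * cells_in(table_b) / n_b else NA_real_,
       n_cells_a = n_a, n_cells_b = n_b)
}

#' Frequency correlation of shared clonotypes
#'
#' Pearson correlation of log10 within-sample clonotype frequencies, over
#' clonotypes present in both samples (restricting to shared clonotypes
#' avoids log of zero).
#'
#' @inheritParams cross_sample_sharing
#' @return A list with `r`, `p`, `n_shared` and `undefined` (fewer than three
#'   shared clonotypes).
#' @export
shared_clonotype_frequency_correlation <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "clonotype_table"),
            inherits(table_b, "clonotype_table"))
  if (table_a$level != table_b$level) {
    stop("clonotype tables are at different definition levels")
  }
  shared <- intersect(table_a$clonotypes$signature, table_b$clonotypes$signature)
  if (length(shared) < 3L) {
    return(list(r = NA_real_, p = NA_real_, n_shared = length(shared),
                undefined = TRUE))
  }
  freq_of <- function(tab) {
    f <- tab$clonotypes$size / sum(tab$clonotypes$size)
    f[match(shared, tab$clonotypes$signature)]
  }
  fa <- log10(freq_of(table_a))
  fb <- log10(freq_of(table_b))
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_shared = length(shared),
                undefined = TRUE))
  }
  ct <- stats::cor.test(fa, fb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = length(shared),
       undefined = FALSE)
}

#' Publicness spectrum across donors
#'
#' For functional clonotype tables from D donors, the occupancy k of a
#' signature is the number of donors in which it occurs. Each donor's cells
#' are binned by the occupancy of their clonotype; per donor the bins sum to
#' the donor's assigned cells.
#'
#' @param tables_by_donor Named list of functional-level `clonotype_table`s,
#'   one per donor (tissues combined).
#' @return A tibble with columns `donor`, `k` (1..D) and `n_cells`.
#' @export
publicness_spectrum <- function(tables_by_donor) {
  stopifnot(length(tables_by_donor) >= 1L)
  levels_seen <- unique(vapply(tables_by_donor, function(t) t$level, character(1L)))
  if (length(levels_seen) != 1L) stop("all tables must share one definition level")
  if (!startsWith(levels_seen, "fn")) {
    stop("publicness is defined on functional (amino-acid) clonotypes")
  }
  donors <- names(tables_by_donor) %||% as.character(seq_along(tables_by_donor))
  D <- length(donors)
  sig_donor <- unique(do.call(rbind, lapply(seq_along(tables_by_donor), function(i) {
    data.frame(sig = tables_by_donor[[i]]$clonotypes$signature, donor = i)
  })))
  occupancy <- table(sig_donor$sig)
  rows <- lapply(seq_along(tables_by_donor), function(i) {
    tab <- tables_by_donor[[i]]
    k_of_clone <- as.integer(occupancy[tab$clonotypes$signature])
    k_of_cell <- k_of_clone[match(tab$assignment$clonotype_id,
                                  tab$clonotypes$clonotype_id)]
    counts <- table(factor(k_of_cell, levels = seq_len(D)))
    tibble::tibble(donor = donors[i], k = seq_len(D),
                   n_cells = as.integer(counts))
  })
  do.call(rbind, rows)
}

#' Shared signatures found in all donors
#'
#' @inheritParams publicness_spectrum
#' @return Character vector of signatures present in every donor.
#' @export
fully_public_signatures <- function(tables_by_donor) {
  Reduce(intersect, lapply(tables_by_donor, function(t) t$clonotypes$signature))
}

#' Downsampled repertoire comparison between two cell groups
#'
#' Within each stratum (typically donor), the larger group is repeatedly
#' sampled without replacement down to the size of the smaller group; the
#' number of unique clonotypes and the Shannon index are computed per
#' replicate and averaged.
#'
#' @param assign_a,assign_b Tibbles with one row per cell and columns
#'   `stratum` and `clonotype_id`.
#' @param n_reps Number of downsampling replicates.
#' @param seed RNG seed.
#' @return A list with `summary` (stratum, group, n_cells, mean_unique,
#'   mean_shannon) and `replicates` (per-replicate values).
#' @export
downsampled_comparison <- function(assign_a, assign_b, n_reps = 100, seed = NULL) {
  assert_cols(assign_a, c("stratum", "clonotype_id"), "group A assignment")
  assert_cols(assign_b, c("stratum", "clonotype_id"), "group B assignment")
  strata <- union(unique(assign_a$stratum), unique(assign_b$stratum))
  reps <- list()
  with_seed(seed, {
    for (s in strata) {
      a <- assign_a$clonotype_id[assign_a$stratum == s]
      b <- assign_b$clonotype_id[assign_b$stratum == s]
      if (length(a) == 0L || length(b) == 0L) {
        warning(sprintf("stratum '%s' empty in one group; skipped", s))
        next
      }
      m <- min(length(a), length(b))
      for (r in seq_len(n_reps)) {
        xa <- if (length(a) > m) sample(a, m) else a
        xb <- if (length(b) > m) sample(b, m) else b
        reps[[length(reps) + 1L]] <- tibble::tibble(
          stratum = s, rep = r, group = c("A", "B"),
          n_cells = m,
          n_unique = c(length(unique(xa)), length(unique(xb))),
          shannon = c(shannon_index(table(xa)), shannon_index(table(xb))))
      }
    }
  })
  replicates <- if (length(reps) > 0L) do.call(rbind, reps) else
    tibble::tibble(stratum = character(), rep = integer(), group = character(),
                   n_cells = integer(), n_unique = integer(), shannon = numeric())
  key <- paste(replicates$stratum, replicates$group, sep = "\r")
  if (nrow(replicates) > 0L) {
    mean_unique <- tapply(replicates$n_unique, key, mean)
    mean_shannon <- tapply(replicates$shannon, key, mean)
    n_cells <- tapply(replicates$n_cells, key, function(x) x[1L])
    parts <- strsplit(names(mean_unique), "\r", fixed = TRUE)
    summary <- tibble::tibble(
      stratum = vapply(parts, `[`, character(1L), 1L),
      group = vapply(parts, `[`, character(1L), 2L),
      n_cells = as.integer(n_cells),
      mean_unique = as.numeric(mean_unique),
      mean_shannon = as.numeric(mean_shannon))
  } else {
    summary <- tibble::tibble(stratum = character(), group = character(),
                              n_cells = integer(), mean_unique = numeric(),
                              mean_shannon = numeric())
  }
  list(summary = summary, replicates = replicates)
}

#' TCR capture rate
#'
#' Fraction of cells for which a clonotype could be called.
#'
#' @param n_cells_total Total cells in the sample.
#' @param n_cells_with_clonotype Cells with an assigned clonotype.
#' @return The capture fraction, or `NA` (flagged undefined) when
#'   `n_cells_total` is zero.
#' @export
tcr_capture_rate <- function(n_cells_total, n_cells_with_clonotype) {
  if (n_cells_total < 0 || n_cells_with_clonotype < 0 ||
      n_cells_with_clonotype > n_cells_total) {
    stop("counts must satisfy 0 <= with_clonotype <= total")
  }
  if (n_cells_total == 0) return(NA_real_)
  n_cells_with_clonotype / n_cells_total
}
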