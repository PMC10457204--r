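# Synthetic paired scTCR-seq study generator with recorded ground truth.
#
# The generator emulates the structure of a multi-donor MAIT-cell study:
# semi-invariant TRAV1-2 alpha chains with 12-amino-acid CDR3s carrying the
# canonical tyrosine, TRAJ usage concentrated on TRAJ33/TRAJ12/TRAJ20,
# diverse beta chains biased toward a few TRBV genes with TRAJ-dependent
# pairing, log-series (oligoclonal) clone sizes, matched blood/liver tissue
# overlap, within-donor alpha-chain reuse, cross-donor public alpha chains,
# per-chain dropout, barcode doublets and incomplete TCR capture. Every
# planted quantity is recorded so downstream modules can be validated by
# parameter recovery.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CODONS <- list(
  A = c("GCT", "GCC", "GCA"), C = c("TGT", "TGC"), D = c("GAT", "GAC"),
  E = c("GAA", "GAG"), F = c("TTT", "TTC"), G = c("GGT", "GGC", "GGA"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("CTT", "CTC", "CTG", "TTA"), M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA"), Q = c("CAA", "CAG"), R = c("CGT", "CGC", "AGA"),
  S = c("TCT", "TCC", "AGT"), T = c("ACT", "ACC", "ACA"),
  V = c("GTT", "GTC", "GTG"), W = "TGG", Y = c("TAT", "TAC"))

reverse_translate <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1L]], function(a) {
    cod <- CODONS[[a]]
    if (length(cod) == 1L) cod else sample(cod, 1L)
  }, character(1L)), collapse = "")
}

# 12-aa CDR3 alpha with the canonical tyrosine at the eighth position
random_cdr3a <- function() {
  paste0("CA", paste(sample(AA20, 5L, replace = TRUE), collapse = ""),
         "Y", paste(sample(AA20, 3L, replace = TRUE), collapse = ""), "F")
}

random_cdr3b <- function(len_aa) {
  paste0("C", paste(sample(AA20, len_aa - 2L, replace = TRUE), collapse = ""), "F")
}

# log-series clone-size sampler (truncated at smax)
rlogseries <- function(n, p, smax = 2000L) {
  s <- seq_len(smax)
  w <- p^s / s
  sample.int(smax, n, replace = TRUE, prob = w)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

random_barcodes <- function(n, existing = character()) {
  out <- character(0L)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i) {
      paste0(paste(sample(c("A", "C", "G", "T"), 16L, replace = TRUE),
                   collapse = ""), "-1")
    }, character(1L))
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out
}

default_trbv_vocab <- function() {
  c("TRBV6-1", "TRBV6-4", "TRBV20-1", "TRBV4-1", "TRBV5-1", "TRBV6-2",
    "TRBV7-2", "TRBV9", "TRBV19", "TRBV25-1", "TRBV28", "TRBV15")
}

default_trbv_probs <- function(vocab) {
  p <- rep(0.55 / (length(vocab) - 3L), length(vocab))
  names(p) <- vocab
  p[c("TRBV6-1", "TRBV6-4", "TRBV20-1")] <- c(0.16, 0.16, 0.13)
  p / sum(p)
}

default_pairing_bias <- function(trbv_probs) {
  traj <- c("TRAJ33", "TRAJ12", "TRAJ20", "other")
  mat <- matrix(rep(trbv_probs, each = length(traj)), nrow = length(traj),
                dimnames = list(traj, names(trbv_probs)))
  # TRAJ12/TRAJ20 alphas preferentially pair with TRBV6-4; TRAJ33 with TRBV20-1
  mat[c("TRAJ12", "TRAJ20"), "TRBV6-4"] <- mat[c("TRAJ12", "TRAJ20"), "TRBV6-4"] * 3
  mat["TRAJ33", "TRBV20-1"] <- mat["TRAJ33", "TRBV20-1"] * 2
  mat / rowSums(mat)
}

#' Configuration for the synthetic repertoire generator
#'
#' Defaults emulate the structure of a matched blood/liver multi-donor MAIT
#' cell study: TRAJ33/TRAJ12/TRAJ20 used by 87%/6%/6% of alpha chains (1%
#' other), beta usage biased toward TRBV6-1/TRBV6-4/TRBV20-1 with
#' TRAJ-dependent pairing, 27 public alpha chains present in every donor,
#' ~72% of cells in clonotypes shared between matched tissues, log-series
#' clone sizes, 30% within-donor alpha-chain reuse, 10% dual-alpha and 5%
#' dual-beta clones, 10% per-chain dropout, 2% doublets and 90% TCR capture.
#'
#' @param donors Number of donors.
#' @param cells_per_sample Cells per donor-tissue sample.
#' @param tissues Tissue labels (one or two).
#' @param logseries_p Log-series parameter for clone sizes (closer to 1 =
#'   heavier tail).
#' @param traj_probs Named probabilities over TRAJ33, TRAJ12, TRAJ20, other.
#' @param trbv_vocab,trbv_probs Beta V-gene vocabulary and marginal usage.
#' @param pairing_bias Row-stochastic matrix of P(TRBV | TRAJ of the clone's
#'   primary alpha); rows TRAJ33/TRAJ12/TRAJ20/other.
#' @param public_alpha_count Number of alpha-chain amino-acid signatures
#'   planted in every donor.
#' @param alpha_sharing Probability that a new clone reuses an existing
#'   alpha chain of its donor (generates promiscuous alpha pairing).
#' @param dual_alpha_rate,dual_beta_rate Probability that a clone carries a
#'   secondary alpha/beta chain.
#' @param tissue_overlap Probability that a clone (of size >= 2, adjusted so
#'   the expected cell-weighted overlap matches) is present in both tissues.
#' @param dropout Per-chain dropout probability per cell; a chain is only
#'   dropped if the cell still retains a TRAV1-2 alpha and a beta chain.
#' @param doublet_rate Fraction of emitted barcodes that merge two cells.
#' @param capture Probability that a cell's TCR is recovered at all.
#' @param noise_contig_rate Rate of decoy non-productive contig rows.
#' @param condition,timepoint Sample metadata values.
#' @param seed RNG seed; all outputs are deterministic given the seed.
#' @return A validated config list of class `repertoire_config`.
#' @export
repertoire_config <- function(donors = 6, cells_per_sample = 2000,
                              tissues = c("blood", "liver"),
                              logseries_p = 0.99,
                              traj_probs = c(TRAJ33 = 0.87, TRAJ12 = 0.06,
                                             TRAJ20 = 0.06, other = 0.01),
                              trbv_vocab = default_trbv_vocab(),
                              trbv_probs = NULL,
                              pairing_bias = NULL,
                              public_alpha_count = 27,
                              alpha_sharing = 0.3,
                              dual_alpha_rate = 0.10,
                              dual_beta_rate = 0.05,
                              tissue_overlap = 0.72,
                              dropout = 0.10,
                              doublet_rate = 0.02,
                              capture = 0.9,
                              noise_contig_rate = 0.02,
                              condition = "unstimulated",
                              timepoint = 0,
                              seed = 1) {
  if (is.null(trbv_probs)) trbv_probs <- default_trbv_probs(trbv_vocab)
  if (is.null(pairing_bias)) pairing_bias <- default_pairing_bias(trbv_probs)
  stopifnot(donors >= 1, cells_per_sample >= 1,
            length(tissues) %in% c(1L, 2L),
            logseries_p > 0, logseries_p < 1)
  if (abs(sum(traj_probs) - 1) > 1e-8) stop("traj_probs must sum to 1")
  if (abs(sum(trbv_probs) - 1) > 1e-8) stop("trbv_probs must sum to 1")
  if (any(abs(rowSums(pairing_bias) - 1) > 1e-8)) {
    stop("pairing_bias rows must sum to 1")
  }
  rates <- c(alpha_sharing, dual_alpha_rate, dual_beta_rate, tissue_overlap,
             dropout, doublet_rate, capture, noise_contig_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(
    donors = donors, cells_per_sample = cells_per_sample, tissues = tissues,
    logseries_p = logseries_p, traj_probs = traj_probs,
    trbv_vocab = trbv_vocab, trbv_probs = trbv_probs,
    pairing_bias = pairing_bias, public_alpha_count = public_alpha_count,
    alpha_sharing = alpha_sharing, dual_alpha_rate = dual_alpha_rate,
    dual_beta_rate = dual_beta_rate, tissue_overlap = tissue_overlap,
    dropout = dropout, doublet_rate = doublet_rate, capture = capture,
    noise_contig_rate = noise_contig_rate, condition = condition,
    timepoint = timepoint, seed = seed), class = "repertoire_config")
}

new_alpha <- function(traj_probs) {
  traj_name <- sample(names(traj_probs), 1L, prob = traj_probs)
  traj <- if (traj_name == "other") "TRAJ42" else traj_name
  aa <- random_cdr3a()
  # the nucleotide sequence belongs to the chain: clones reusing this alpha
  # share it verbatim, so nucleotide-level pairing analyses see the reuse
  list(locus = "TRA", v_gene = "TRAV1-2", j_gene = traj,
       cdr3_aa = aa, cdr3_nt = reverse_translate(aa))
}

cell_is_viable <- function(chains, keep) {
  any(keep & chains$locus == "TRA" & chains$v_gene == "TRAV1-2") &&
    any(keep & chains$locus == "TRB")
}

#' Generate a synthetic paired scTCR-seq study
#'
#' Emits a 10x-dialect contig annotation table, per-cell metadata and a
#' ground-truth record of the planted clonal partition.
#'
#' @param config A [repertoire_config()].
#' @return A list with `contigs` (tibble in the contig-annotation dialect,
#'   typed as returned by [read_contig_table()]), `meta` (per-cell metadata
#'   for every emitted barcode, captured or not) and `truth` (ground truth:
#'   `cells`, `clones`, `doublets` tibbles, realized per-donor cell-weighted
#'   tissue overlap and the generating parameters).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "repertoire_config"))
  with_seed(config$seed, generate_repertoire_impl(config))
}

generate_repertoire_impl <- function(config) {
  tissues <- config$tissues
  two_tissue <- length(tissues) == 2L
  used_beta_aa <- new.env(parent = emptyenv())

  # cross-donor public alpha-chain signatures
  m_public <- config$public_alpha_count
  public_alphas <- lapply(seq_len(m_public), function(i) new_alpha(config$traj_probs))

  clone_rows <- list()
  cell_rows <- list()
  clone_chain_sets <- list()

  for (d in seq_len(config$donors)) {
    donor <- sprintf("donor%02d", d)
    n_target <- config$cells_per_sample * length(tissues)
    sizes <- integer(0L)
    while (sum(sizes) < n_target) {
      sizes <- c(sizes, rlogseries(256L, config$logseries_p))
    }
    cum <- cumsum(sizes)
    n_clones <- which(cum >= n_target)[1L]
    sizes <- sizes[seq_len(n_clones)]
    sizes[n_clones] <- sizes[n_clones] - (cum[n_clones] - n_target)
    if (sizes[n_clones] == 0L) {
      sizes <- sizes[-n_clones]
      n_clones <- n_clones - 1L
    }
    if (m_public > n_clones) {
      stop(sprintf(
        "infeasible config: %d public alpha chains but donor %s has only %d clones",
        m_public, donor, n_clones))
    }
    # public alphas are planted on the donor's largest clones (public MAIT
    # alpha chains dominate repertoires), in a seeded random arrangement
    public_slot <- rep(NA_integer_, n_clones)
    if (m_public > 0L) {
      largest <- order(-sizes)[seq_len(m_public)]
      public_slot[largest] <- sample.int(m_public)
    }

    alpha_pool <- list()
    for (i in seq_len(n_clones)) {
      clone_id <- sprintf("%s_c%04d", donor, i)
      # primary alpha: public, reused or new
      if (!is.na(public_slot[i])) {
        a1 <- public_alphas[[public_slot[i]]]
        # public sharing is at the amino-acid level; each donor rearranges
        # its own nucleotide junction
        a1$cdr3_nt <- reverse_translate(a1$cdr3_aa)
        alpha_pool[[length(alpha_pool) + 1L]] <- a1
      } else if (length(alpha_pool) > 0L &&
                 stats::runif(1L) < config$alpha_sharing) {
        a1 <- alpha_pool[[sample.int(length(alpha_pool), 1L)]]
      } else {
        a1 <- new_alpha(config$traj_probs)
        alpha_pool[[length(alpha_pool) + 1L]] <- a1
      }
      chains <- list(a1)
      dual_alpha <- stats::runif(1L) < config$dual_alpha_rate
      if (dual_alpha) {
        chains[[length(chains) + 1L]] <- new_alpha(config$traj_probs)
      }
      # beta chain(s): TRBV conditional on primary alpha's TRAJ, unique CDR3.
      # A clone never carries both a second alpha and a second beta: real
      # cells with two alphas and two betas are indistinguishable from
      # doublets and would be discarded by the assembly rule.
      traj_row <- if (a1$j_gene %in% rownames(config$pairing_bias)) a1$j_gene else "other"
      n_beta <- if (dual_alpha) 1L else
        1L + (stats::runif(1L) < config$dual_beta_rate)
      for (b in seq_len(n_beta)) {
        repeat {
          cdr3b <- random_cdr3b(sample(12:16, 1L))
          if (is.null(used_beta_aa[[cdr3b]])) break
        }
        used_beta_aa[[cdr3b]] <- TRUE
        trbv <- sample(colnames(config$pairing_bias), 1L,
                       prob = config$pairing_bias[traj_row, ])
        chains[[length(chains) + 1L]] <- list(
          locus = "TRB", v_gene = trbv,
          j_gene = sample(c("TRBJ1-1", "TRBJ2-1", "TRBJ2-3", "TRBJ2-7"), 1L),
          cdr3_aa = cdr3b, cdr3_nt = reverse_translate(cdr3b))
      }
      chain_tab <- tibble::tibble(
        locus = vapply(chains, `[[`, character(1L), "locus"),
        v_gene = vapply(chains, `[[`, character(1L), "v_gene"),
        j_gene = vapply(chains, `[[`, character(1L), "j_gene"),
        cdr3_aa = vapply(chains, `[[`, character(1L), "cdr3_aa"),
        cdr3_nt = vapply(chains, `[[`, character(1L), "cdr3_nt"))
      clone_chain_sets[[clone_id]] <- chain_tab

      clone_rows[[length(clone_rows) + 1L]] <- tibble::tibble(
        clone = clone_id, donor = donor, size = sizes[i],
        public_id = public_slot[i],
        primary_traj = a1$j_gene,
        primary_trbv = chain_tab$v_gene[chain_tab$locus == "TRB"][1L],
        n_alpha = sum(chain_tab$locus == "TRA"),
        n_beta = sum(chain_tab$locus == "TRB"),
        signature_aa = signature_string(chain_key(
          chain_tab$locus, chain_tab$v_gene, chain_tab$j_gene, chain_tab$cdr3_aa)),
        signature_nt = signature_string(chain_key(
          chain_tab$locus, chain_tab$v_gene, chain_tab$j_gene, chain_tab$cdr3_nt)))
    }
    donor_clones <- do.call(rbind, clone_rows[vapply(clone_rows, function(r)
      r$donor[1L] == donor, logical(1L))])

    # tissue allocation with cell-weighted overlap
    if (two_tissue) {
      eligible <- donor_clones$size >= 2L
      denom <- sum(donor_clones$size[eligible])
      omega_eff <- if (denom > 0) {
        min(1, config$tissue_overlap * sum(donor_clones$size) / denom)
      } else 0
      shared <- eligible & stats::runif(nrow(donor_clones)) < omega_eff
    } else {
      shared <- rep(FALSE, nrow(donor_clones))
    }
    for (i in seq_len(nrow(donor_clones))) {
      sz <- donor_clones$size[i]
      if (two_tissue && shared[i]) {
        n1 <- 1L + stats::rbinom(1L, sz - 2L, 0.5)
        counts <- c(n1, sz - n1)
      } else if (two_tissue) {
        counts <- c(0L, 0L)
        counts[sample.int(2L, 1L)] <- sz
      } else {
        counts <- sz
      }
      for (t in seq_along(tissues)) {
        if (counts[t] == 0L) next
        cell_rows[[length(cell_rows) + 1L]] <- tibble::tibble(
          clone = donor_clones$clone[i], donor = donor,
          tissue = tissues[t], n = counts[t])
      }
    }
    idx <- vapply(clone_rows, function(r) r$donor[1L] == donor, logical(1L))
    clone_rows[idx] <- split(
      transform(donor_clones, shared = shared),
      seq_len(nrow(donor_clones)))
  }

  clones <- tibble::as_tibble(do.call(rbind, clone_rows))
  alloc <- do.call(rbind, cell_rows)
  cells <- alloc[rep(seq_len(nrow(alloc)), alloc$n),
                 c("clone", "donor", "tissue"), drop = FALSE]
  cells$barcode <- random_barcodes(nrow(cells))

  # per-cell chain sets with viability-respecting dropout
  chain_list <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ch <- clone_chain_sets[[cells$clone[i]]]
    keep <- rep(TRUE, nrow(ch))
    if (config$dropout > 0 && nrow(ch) > 2L) {
      for (j in sample.int(nrow(ch))) {
        if (stats::runif(1L) < config$dropout) {
          trial <- keep
          trial[j] <- FALSE
          if (cell_is_viable(ch, trial)) keep <- trial
        }
      }
    }
    chain_list[[i]] <- ch[keep, , drop = FALSE]
  }

  # doublets: merge chain sets of two random cells within a sample
  cells$is_doublet <- FALSE
  doublet_rows <- list()
  drop_cells <- integer(0L)
  if (config$doublet_rate > 0) {
    sample_key <- paste(cells$donor, cells$tissue)
    for (sk in unique(sample_key)) {
      idx <- which(sample_key == sk)
      n_doub <- stats::rbinom(1L, length(idx) %/% 2L, config$doublet_rate)
      if (n_doub == 0L) next
      picked <- sample(idx, 2L * n_doub)
      for (q in seq_len(n_doub)) {
        i1 <- picked[2L * q - 1L]; i2 <- picked[2L * q]
        merged <- unique(rbind(chain_list[[i1]], chain_list[[i2]]))
        chain_list[[i1]] <- merged
        n_a <- sum(merged$locus == "TRA"); n_b <- sum(merged$locus == "TRB")
        doublet_rows[[length(doublet_rows) + 1L]] <- tibble::tibble(
          barcode = cells$barcode[i1], clone_a = cells$clone[i1],
          clone_b = cells$clone[i2],
          detectable = (n_a == 2L && n_b == 2L) || n_a > 2L || n_b > 2L)
        cells$is_doublet[i1] <- TRUE
        drop_cells <- c(drop_cells, i2)
      }
    }
  }
  if (length(drop_cells) > 0L) {
    cells <- cells[-drop_cells, , drop = FALSE]
    chain_list <- chain_list[-drop_cells]
  }
  cells$captured <- stats::runif(nrow(cells)) < config$capture

  # contig rows for captured cells
  n_chains <- vapply(chain_list, nrow, integer(1L))
  emit <- cells$captured
  chain_tab <- do.call(rbind, chain_list[emit])
  bc_rep <- rep(cells$barcode[emit], n_chains[emit])
  n_rows <- nrow(chain_tab)
  contigs <- tibble::tibble(
    barcode = bc_rep,
    is_cell = rep("True", n_rows),
    contig_id = paste0(bc_rep, "_contig_", stats::ave(
      seq_len(n_rows), bc_rep, FUN = seq_along)),
    high_confidence = rep(TRUE, n_rows),
    length = as.character(nchar(chain_tab$cdr3_nt) + 250L),
    chain = chain_tab$locus,
    v_gene = chain_tab$v_gene,
    d_gene = ifelse(chain_tab$locus == "TRB", "TRBD1", NA_character_),
    j_gene = chain_tab$j_gene,
    c_gene = ifelse(chain_tab$locus == "TRB", "TRBC1", "TRAC"),
    full_length = rep(TRUE, n_rows),
    productive = rep(TRUE, n_rows),
    cdr3 = chain_tab$cdr3_aa,
    cdr3_nt = chain_tab$cdr3_nt,
    reads = NA_real_,
    umis = 1 + stats::rpois(n_rows, 3),
    raw_clonotype_id = rep(cells$clone[emit], n_chains[emit]),
    raw_consensus_id = rep("None", n_rows))
  contigs$reads <- contigs$umis * (40 + stats::rpois(n_rows, 10))

  # decoy rows that the contig filter must remove
  n_noise <- stats::rbinom(1L, n_rows, config$noise_contig_rate)
  if (n_noise > 0L) {
    pick <- sample.int(n_rows, n_noise, replace = TRUE)
    noise <- contigs[pick, , drop = FALSE]
    noise$contig_id <- paste0(noise$barcode, "_noise_", seq_len(n_noise))
    noise$productive <- FALSE
    noise$cdr3 <- vapply(seq_len(n_noise), function(i) random_cdr3b(10L),
                         character(1L))
    noise$cdr3_nt <- unname(vapply(noise$cdr3, reverse_translate,
                                   character(1L)))
    noise$umis <- rep(1, n_noise)
    contigs <- rbind(contigs, noise)
  }
  contigs <- contigs[order(contigs$barcode, contigs$chain), , drop = FALSE]

  meta <- tibble::tibble(
    barcode = cells$barcode, donor = cells$donor, tissue = cells$tissue,
    condition = config$condition, timepoint = config$timepoint)

  overlap <- vapply(split(cells, cells$donor), function(cc) {
    sh <- clones$shared[match(cc$clone, clones$clone)] & !cc$is_doublet
    sum(sh) / sum(!cc$is_doublet)
  }, numeric(1L))

  truth <- list(
    cells = tibble::tibble(
      barcode = cells$barcode, donor = cells$donor, tissue = cells$tissue,
      clone = ifelse(cells$is_doublet, NA_character_, cells$clone),
      captured = cells$captured, is_doublet = cells$is_doublet),
    clones = clones,
    doublets = if (length(doublet_rows) > 0L) do.call(rbind, doublet_rows) else
      tibble::tibble(barcode = character(), clone_a = character(),
                     clone_b = character(), detectable = logical()),
    public_alphas = vapply(public_alphas, function(a) chain_key(
      a$locus, a$v_gene, a$j_gene, a$cdr3_aa), character(1L)),
    overlap_cell_weighted = as.list(overlap),
    params = list(
      donors = config$donors, cells_per_sample = config$cells_per_sample,
      tissues = config$tissues, tissue_overlap = config$tissue_overlap,
      dropout = config$dropout, doublet_rate = config$doublet_rate,
      capture = config$capture, public_alpha_count = config$public_alpha_count,
      traj_probs = as.list(config$traj_probs), seed = config$seed))
  list(contigs = contigs, meta = meta, truth = truth)
}

#' Write a contig table in the 10x CSV dialect
#'
#' Boolean columns are written as `"True"`/`"False"` and missing genes as
#' `"None"`, so the file round-trips through [read_contig_table()].
#'
#' @param contigs Contig tibble (as produced by [generate_repertoire()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_contig_csv <- function(contigs, path) {
  out <- as.data.frame(contigs)
  for (col in c("high_confidence", "full_length", "productive")) {
    out[[col]] <- ifelse(out[[col]], "True", "False")
  }
  for (col in intersect(c("v_gene", "d_gene", "j_gene", "c_gene"), names(out))) {
    out[[col]][is.na(out[[col]])] <- "None"
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the ground truth to JSON
#' @param truth Ground-truth list from [generate_repertoire()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a ground-truth JSON file
#' @param path JSON path written by [write_ground_truth()].
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("cells", "clones", "doublets")) {
    tr[[nm]] <- tibble::as_tibble(tr[[nm]])
  }
  tr
}

#' Generate per-cell cluster labels with planted clonotype bias
#'
#' Cells of unbiased clonotypes draw their cluster from the global cluster
#' proportions. Each biased clonotype draws its cells either from a
#' Dirichlet-perturbed proposal centred on the global proportions (smaller
#' `bias_concentration` = stronger bias; as it grows the proposal collapses
#' to the null) or, when `concentrate_in` is given, entirely from one
#' cluster.
#'
#' @param assignment Tibble with `barcode` and `clonotype_id` per cell.
#' @param n_clusters Number of clusters (>= 2).
#' @param cluster_props Global cluster proportions (default uniform).
#' @param biased_clones Clonotype ids to bias.
#' @param bias_concentration Dirichlet concentration for biased proposals.
#' @param concentrate_in Optional cluster index (recycled over
#'   `biased_clones`): place all of a biased clonotype's cells there.
#' @param seed RNG seed.
#' @return A tibble with `barcode` and `cluster`; the planted proposals are
#'   attached as attribute `truth`.
#' @export
generate_cluster_labels <- function(assignment, n_clusters = 8,
                                    cluster_props = NULL,
                                    biased_clones = character(),
                                    bias_concentration = 0.1,
                                    concentrate_in = NULL, seed = NULL) {
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  assert_cols(assignment, c("barcode", "clonotype_id"), "clonotype assignment")
  if (is.null(cluster_props)) cluster_props <- rep(1 / n_clusters, n_clusters)
  stopifnot(length(cluster_props) == n_clusters,
            abs(sum(cluster_props) - 1) < 1e-8)
  with_seed(seed, {
    idx <- sample.int(n_clusters, nrow(assignment), replace = TRUE,
                      prob = cluster_props)
    proposals <- list()
    if (length(biased_clones) > 0L) {
      conc <- if (is.null(concentrate_in)) NULL else
        rep_len(concentrate_in, length(biased_clones))
      for (i in seq_along(biased_clones)) {
        cl <- biased_clones[i]
        rows <- which(assignment$clonotype_id == cl)
        if (length(rows) == 0L) next
        if (!is.null(conc)) {
          idx[rows] <- conc[i]
          proposals[[cl]] <- replace(rep(0, n_clusters), conc[i], 1)
        } else {
          prop <- rdirichlet1(bias_concentration * n_clusters * cluster_props)
          idx[rows] <- sample.int(n_clusters, length(rows), replace = TRUE,
                                  prob = prop)
          proposals[[cl]] <- prop
        }
      }
    }
    out <- tibble::tibble(barcode = assignment$barcode,
                          cluster = paste0("c", idx))
    attr(out, "truth") <- list(cluster_props = cluster_props,
                               proposals = proposals)
    out
  })
}

#' Generate stochastic regulon-inference runs with planted stable regulons
#'
#' Stable transcription factors appear in each run with probability
#' `stable_occ`, carrying each of their core targets with probability
#' `target_occ` plus Poisson noise targets; decoy factors appear with
#' probability `decoy_occ` and draw fresh random target sets each run.
#'
#' @param n_runs Number of runs.
#' @param stable_tfs,decoy_tfs Factor names.
#' @param core_targets Named list of core target genes per stable factor
#'   (default: `n_core` genes sampled from `gene_pool`).
#' @param n_core Core targets per stable factor when `core_targets` is NULL.
#' @param gene_pool Gene universe for targets.
#' @param stable_occ,target_occ,decoy_occ Occurrence probabilities in (0,1].
#' @param noise_mean Mean number of extra noise targets per regulon per run.
#' @param seed RNG seed.
#' @return A list with `runs` (list of named lists tf -> targets) and
#'   `truth` (stable factors and their core targets).
#' @export
generate_regulon_runs <- function(n_runs = 100,
                                  stable_tfs = sprintf("TF%02d", 1:8),
                                  decoy_tfs = sprintf("DTF%02d", 1:5),
                                  core_targets = NULL, n_core = 10,
                                  gene_pool = sprintf("G%04d", 1:300),
                                  stable_occ = 0.9, target_occ = 0.95,
                                  decoy_occ = 0.5, noise_mean = 3,
                                  seed = NULL) {
  stopifnot(all(c(stable_occ, target_occ, decoy_occ) > 0),
            all(c(stable_occ, target_occ, decoy_occ) <= 1))
  with_seed(seed, {
    if (is.null(core_targets)) {
      core_targets <- stats::setNames(lapply(stable_tfs, function(tf)
        sample(gene_pool, n_core)), stable_tfs)
    }
    runs <- lapply(seq_len(n_runs), function(r) {
      run <- list()
      for (tf in stable_tfs) {
        if (stats::runif(1L) >= stable_occ) next
        core <- core_targets[[tf]]
        keep <- core[stats::runif(length(core)) < target_occ]
        noise <- sample(gene_pool, stats::rpois(1L, noise_mean))
        tg <- unique(c(keep, noise))
        if (length(tg) == 0L) tg <- sample(gene_pool, 1L)
        run[[tf]] <- tg
      }
      for (tf in decoy_tfs) {
        if (stats::runif(1L) >= decoy_occ) next
        run[[tf]] <- sample(gene_pool, sample(5:15, 1L))
      }
      run
    })
    list(runs = runs,
         truth = list(stable_tfs = stable_tfs, core_targets = core_targets,
                      decoy_tfs = decoy_tfs,
                      params = list(stable_occ = stable_occ,
                                    target_occ = target_occ,
                                    decoy_occ = decoy_occ)))
  })
}

#' Generate pseudotime values with planted clonotype and TRBV effects
#'
#' Per trajectory, a cell's pseudotime is base + clonotype effect + TRBV
#' effect + Gaussian noise. Effects on the second trajectory are correlated
#' with the first at `effect_corr` (1 = identical effects, 0 =
#' independent redraws of matching spread).
#'
#' @param barcodes Cell barcodes.
#' @param clones Clonotype id per cell.
#' @param trbvs Optional TRBV gene per cell.
#' @param clonotype_effects Named numeric vector of planted per-clonotype
#'   shifts (trajectory 1 scale); missing clonotypes get 0.
#' @param trbv_effects Named numeric vector of planted per-TRBV shifts.
#' @param noise_sd Gaussian noise standard deviation.
#' @param base Baseline pseudotime.
#' @param effect_corr Cross-trajectory effect correlation in [-1, 1].
#' @param trajectories Trajectory labels.
#' @param seed RNG seed.
#' @return A long tibble `barcode`, `trajectory`, `pseudotime`; planted
#'   per-trajectory effects are attached as attribute `truth`.
#' @export
generate_pseudotime <- function(barcodes, clones, trbvs = NULL,
                                clonotype_effects = NULL, trbv_effects = NULL,
                                noise_sd = 1, base = 5, effect_corr = 1,
                                trajectories = c("TCR", "cytokine"),
                                seed = NULL) {
  stopifnot(length(barcodes) == length(clones),
            effect_corr >= -1, effect_corr <= 1)
  with_seed(seed, {
    effect_for <- function(keys, effects) {
      if (is.null(effects)) return(stats::setNames(numeric(0), character(0)))
      e <- effects[unique(keys)]
      e[is.na(e)] <- 0
      names(e) <- unique(keys)
      e
    }
    correlate <- function(e, corr) {
      if (length(e) == 0L) return(e)
      spread <- stats::sd(e)
      if (!is.finite(spread) || spread == 0) return(corr * e)
      corr * e + sqrt(max(0, 1 - corr^2)) * stats::rnorm(length(e), 0, spread)
    }
    ce <- list()
    te <- list()
    ce[[trajectories[1L]]] <- effect_for(clones, clonotype_effects)
    te[[trajectories[1L]]] <- effect_for(trbvs %||% character(length(clones)),
                                         trbv_effects)
    for (tr in trajectories[-1L]) {
      ce[[tr]] <- correlate(ce[[trajectories[1L]]], effect_corr)
      te[[tr]] <- correlate(te[[trajectories[1L]]], effect_corr)
    }
    rows <- lapply(trajectories, function(tr) {
      eff_c <- ce[[tr]][clones]
      eff_c[is.na(eff_c)] <- 0
      eff_t <- if (is.null(trbvs)) 0 else {
        v <- te[[tr]][trbvs]
        v[is.na(v)] <- 0
        v
      }
      tibble::tibble(
        barcode = barcodes, trajectory = tr,
        pseudotime = base + as.numeric(eff_c) + as.numeric(eff_t) +
          stats::rnorm(length(barcodes), 0, noise_sd))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(clonotype_effects = ce, trbv_effects = te,
                               noise_sd = noise_sd, effect_corr = effect_corr)
    out
  })
}

#' Generate an expression matrix with coreceptor channels and planted
#' regulon activity shifts
#'
#' Baseline expression is log-normal noise. Coreceptor channels CD8A, CD8B
#' and CD4 are drawn to satisfy the gene-mode assignment rules for each
#' cell's target label (DN cells have all three at zero). Cells listed in
#' `active_cells` for a regulon have that regulon's target genes up-shifted
#' by `shift`, so recovery-curve scoring separates active from inactive
#' cells by a controlled margin.
#'
#' @param barcodes Cell barcodes (row names of the output).
#' @param coreceptor Optional per-cell target label (`"CD8+"`, `"CD4+"`,
#'   `"DN"`).
#' @param regulon_gene_sets Optional named list of target-gene sets.
#' @param active_cells Optional named list (same names) of barcodes whose
#'   cells are active for that regulon.
#' @param shift Expression up-shift applied to active cells' target genes.
#' @param n_genes Number of background genes.
#' @param seed RNG seed.
#' @return A numeric matrix, cells x genes.
#' @export
generate_expression <- function(barcodes, coreceptor = NULL,
                                regulon_gene_sets = NULL, active_cells = NULL,
                                shift = 2, n_genes = 200, seed = NULL) {
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    set_genes <- unique(unlist(regulon_gene_sets, use.names = FALSE))
    genes <- union(genes, set_genes)
    n <- length(barcodes)
    expr <- matrix(stats::rlnorm(n * length(genes), 0, 1), nrow = n,
                   dimnames = list(barcodes, genes))
    if (!is.null(regulon_gene_sets) && !is.null(active_cells)) {
      for (nm in names(active_cells)) {
        tg <- regulon_gene_sets[[nm]]
        rows <- match(active_cells[[nm]], barcodes)
        rows <- rows[!is.na(rows)]
        if (length(rows) > 0L && length(tg) > 0L) {
          expr[rows, tg] <- expr[rows, tg, drop = FALSE] + shift
        }
      }
    }
    if (!is.null(coreceptor)) {
      stopifnot(length(coreceptor) == n)
      cd8a <- cd8b <- cd4 <- numeric(n)
      is8 <- coreceptor == "CD8+"
      is4 <- coreceptor == "CD4+"
      cd8a[is8] <- stats::runif(sum(is8), 0.5, 3)
      cd8b[is8] <- stats::rbinom(sum(is8), 1L, 0.6) * stats::runif(sum(is8), 0.2, 2)
      cd4[is4] <- stats::runif(sum(is4), 0.5, 3)
      expr <- cbind(expr, CD8A = cd8a, CD8B = cd8b, CD4 = cd4)
    }
    expr
  })
}
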