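# Reading and gating of 10x-style contig annotation tables.
#
# The upstream VDJ assembler emits one row per assembled contig per cell
# barcode. Cells are built by grouping contigs by barcode; barcodes whose
# chain counts imply two captured cells are treated as doublets; population
# gates select MAIT cells (semi-invariant TRAV1-2 alpha plus at least one
# beta chain) or conventional memory T cells.

CONTIG_COLUMNS <- c("barcode", "is_cell", "contig_id", "high_confidence",
                    "length", "chain", "v_gene", "d_gene", "j_gene", "c_gene",
                    "full_length", "productive", "cdr3", "cdr3_nt", "reads",
                    "umis", "raw_clonotype_id", "raw_consensus_id")

MANDATORY_CONTIG_COLUMNS <- c("barcode", "chain", "v_gene", "j_gene", "cdr3",
                              "cdr3_nt", "high_confidence", "full_length",
                              "productive")

MAIT_TRAJ <- c("TRAJ33", "TRAJ12", "TRAJ20")

parse_contig_bool <- function(x, column) {
  out <- rep(NA, length(x))
  x_trim <- trimws(x)
  out[x_trim %in% c("True", "true", "TRUE")] <- TRUE
  out[x_trim %in% c("False", "false", "FALSE")] <- FALSE
  is_none <- x_trim %in% c("None", "", "NA")
  bad <- which(!is_none & is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf("column '%s': unparseable boolean value '%s' at row %d",
                 column, x[bad[1L]], bad[1L]))
  }
  out
}

#' Read a 10x-style filtered contig annotation table
#'
#' Parses a CSV in the `filtered_contig_annotations.csv` dialect: one row per
#' assembled TCR contig per cell barcode, boolean columns written as
#' `"True"`/`"False"` (case-insensitive; `"None"` is accepted as missing) and
#' `"None"` for absent gene calls.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per contig. Boolean columns are logical,
#'   `umis`/`reads` numeric, gene and sequence columns character (`NA` where
#'   the file said `"None"`).
#' @export
read_contig_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("contig file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  assert_cols(raw, MANDATORY_CONTIG_COLUMNS, "contig table")
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(barcode = character(), chain = character(),
                          v_gene = character(), d_gene = character(),
                          j_gene = character(), cdr3 = character(),
                          cdr3_nt = character(),
                          high_confidence = logical(), full_length = logical(),
                          productive = logical(), umis = numeric())
    return(out)
  }
  for (col in c("high_confidence", "full_length", "productive")) {
    raw[[col]] <- parse_contig_bool(raw[[col]], col)
  }
  for (col in intersect(c("v_gene", "d_gene", "j_gene", "c_gene"), names(raw))) {
    raw[[col]][raw[[col]] %in% c("None", "")] <- NA_character_
  }
  if (!"d_gene" %in% names(raw)) raw$d_gene <- NA_character_
  raw$umis <- if ("umis" %in% names(raw)) suppressWarnings(as.numeric(raw$umis)) else 0
  raw$umis[is.na(raw$umis)] <- 0
  if ("reads" %in% names(raw)) {
    raw$reads <- suppressWarnings(as.numeric(raw$reads))
  }
  tibble::as_tibble(raw)
}

#' Filter contigs to high-confidence, full-length, productive TCR chains
#'
#' Retains rows for which `high_confidence`, `full_length` and `productive`
#' are all true and the chain is TRA or TRB, and whose CDR3 nucleotide and
#' amino-acid strings are non-empty. Row order is preserved and the operation
#' is idempotent.
#'
#' @param contigs A contig tibble from [read_contig_table()].
#' @return The retained subset of `contigs`.
#' @export
filter_contigs <- function(contigs) {
  assert_cols(contigs, MANDATORY_CONTIG_COLUMNS, "contig table")
  keep <- !is.na(contigs$high_confidence) & contigs$high_confidence &
    !is.na(contigs$full_length) & contigs$full_length &
    !is.na(contigs$productive) & contigs$productive &
    contigs$chain %in% c("TRA", "TRB") &
    !is.na(contigs$cdr3) & nzchar(contigs$cdr3) & contigs$cdr3 != "None" &
    !is.na(contigs$cdr3_nt) & nzchar(contigs$cdr3_nt) & contigs$cdr3_nt != "None"
  contigs[keep, , drop = FALSE]
}

#' Read per-cell sample metadata
#'
#' @param path CSV with columns `barcode,donor,tissue,condition,timepoint`.
#' @return A tibble of per-cell metadata.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata file not found: %s", path))
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(meta, c("barcode", "donor", "tissue"), "metadata table")
  tibble::as_tibble(meta)
}

#' Assemble per-cell chain sets and discard TCR-defined doublets
#'
#' Groups filtered contigs by barcode, collapses duplicate contigs (same
#' barcode, locus, V/J genes and CDR3 nucleotide sequence) keeping the copy
#' with the most UMIs, and discards barcodes whose chain counts imply two
#' captured cells: exactly two alpha and two beta chains, or more than two
#' chains of either locus.
#'
#' @param contigs Filtered contig tibble.
#' @param meta Per-cell metadata tibble with at least `barcode`, `donor`,
#'   `tissue` columns. Barcodes absent from `meta` are flagged unassigned with
#'   a warning.
#' @return A `cell_set`: a list with a `cells` tibble (one row per retained
#'   barcode) and a `chains` tibble (one row per retained chain). The number
#'   and identity of discarded doublet barcodes are stored in attributes
#'   `n_doublets` and `doublet_barcodes`.
#' @export
assemble_cells <- function(contigs, meta = NULL) {
  assert_cols(contigs, MANDATORY_CONTIG_COLUMNS, "contig table")
  chains <- tibble::tibble(
    barcode = contigs$barcode,
    locus = contigs$chain,
    v_gene = contigs$v_gene,
    j_gene = contigs$j_gene,
    cdr3_nt = contigs$cdr3_nt,
    cdr3_aa = contigs$cdr3,
    umis = contigs$umis
  )
  # collapse duplicate contigs, keeping the highest-UMI copy
  dup_key <- paste(chains$barcode, chains$locus, chains$v_gene, chains$j_gene,
                   chains$cdr3_nt, sep = "\r")
  ord <- order(dup_key, -chains$umis)
  chains <- chains[ord, , drop = FALSE]
  chains <- chains[!duplicated(dup_key[ord]), , drop = FALSE]
  chains <- chains[order(chains$barcode, chains$locus), , drop = FALSE]

  n_alpha <- tapply(chains$locus == "TRA", chains$barcode, sum)
  n_beta <- tapply(chains$locus == "TRB", chains$barcode, sum)
  barcodes <- names(n_alpha)
  is_doublet <- (n_alpha == 2 & n_beta == 2) | n_alpha > 2 | n_beta > 2
  doublet_barcodes <- barcodes[is_doublet]
  keep_barcodes <- barcodes[!is_doublet]
  chains <- chains[chains$barcode %in% keep_barcodes, , drop = FALSE]

  cells <- tibble::tibble(
    barcode = keep_barcodes,
    n_alpha = as.integer(n_alpha[keep_barcodes]),
    n_beta = as.integer(n_beta[keep_barcodes])
  )
  if (!is.null(meta)) {
    assert_cols(meta, c("barcode", "donor", "tissue"), "metadata table")
    idx <- match(cells$barcode, meta$barcode)
    if (anyNA(idx)) {
      warning(sprintf("%d cell barcode(s) absent from metadata; flagged unassigned",
                      sum(is.na(idx))))
    }
    cells$donor <- meta$donor[idx]
    cells$tissue <- meta$tissue[idx]
    cells$condition <- if ("condition" %in% names(meta)) meta$condition[idx] else NA_character_
    cells$timepoint <- if ("timepoint" %in% names(meta)) meta$timepoint[idx] else NA_real_
    cells$population <- ifelse(is.na(idx), "unassigned", NA_character_)
  } else {
    cells$donor <- NA_character_
    cells$tissue <- NA_character_
    cells$condition <- NA_character_
    cells$timepoint <- NA_real_
    cells$population <- NA_character_
  }

  out <- structure(list(cells = cells, chains = chains), class = "cell_set")
  attr(out, "n_doublets") <- length(doublet_barcodes)
  attr(out, "doublet_barcodes") <- doublet_barcodes
  out
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells, %d chains", nrow(x$cells), nrow(x$chains)))
  pop <- unique(stats::na.omit(x$cells$population))
  if (length(pop) > 0L) cat(sprintf(" [%s]", paste(pop, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Number of cells in a cell set
#' @param cells A `cell_set`.
#' @export
n_cells <- function(cells) nrow(cells$cells)

# chains of one barcode subset, used internally
subset_cell_set <- function(cells, barcodes) {
  structure(list(
    cells = cells$cells[cells$cells$barcode %in% barcodes, , drop = FALSE],
    chains = cells$chains[cells$chains$barcode %in% barcodes, , drop = FALSE]
  ), class = "cell_set")
}

#' Gate assembled cells into a T cell population
#'
#' MAIT gating keeps cells with at least one alpha chain using TRAV1-2
#' (allele suffixes ignored) and at least one beta chain. Conventional-memory
#' (`"Tmem"`) gating keeps cells with at least one alpha and one beta chain
#' and then removes presumed contaminating MAIT cells: cells with any alpha
#' chain using TRAV1-2 with TRAJ33, TRAJ12 or TRAJ20 and a CDR3 alpha region
#' of exactly 12 amino acids.
#'
#' @param cells A `cell_set` from [assemble_cells()].
#' @param population `"MAIT"` or `"Tmem"`.
#' @return The gated `cell_set`, with the `population` column set.
#' @export
gate_cells <- function(cells, population = c("MAIT", "Tmem")) {
  if (length(population) != 1L || !population %in% c("MAIT", "Tmem")) {
    stop("unknown population label; must be 'MAIT' or 'Tmem'")
  }
  ch <- cells$chains
  is_alpha <- ch$locus == "TRA"
  is_beta <- ch$locus == "TRB"
  v_bare <- strip_allele(ch$v_gene)
  j_bare <- strip_allele(ch$j_gene)

  has_alpha <- unique(ch$barcode[is_alpha])
  has_beta <- unique(ch$barcode[is_beta])
  if (population == "MAIT") {
    has_trav12 <- unique(ch$barcode[is_alpha & v_bare %in% "TRAV1-2"])
    keep <- intersect(has_trav12, has_beta)
  } else {
    keep <- intersect(has_alpha, has_beta)
    mait_like <- unique(ch$barcode[is_alpha & v_bare %in% "TRAV1-2" &
                                     j_bare %in% MAIT_TRAJ &
                                     nchar(ch$cdr3_aa) == 12L])
    keep <- setdiff(keep, mait_like)
  }
  out <- subset_cell_set(cells, keep)
  out$cells$population <- ifelse(out$cells$population %in% "unassigned",
                                 "unassigned", population)
  out
}
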