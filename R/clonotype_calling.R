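# Clonotype definitions.
#
# Six definition levels are supported: nucleotide and functional
# (amino-acid), each over paired alpha-beta chain sets, alpha chains only, or
# beta chains only. Chain identity is V gene + J gene + CDR3 sequence; D gene
# calls are excluded. Nucleotide clonotypes require exact chain-set equality.
# Functional clonotypes tolerate chain dropout: a cell belongs to a clonotype
# provided all of its detected chains match the clonotype's chain set.

CLONOTYPE_LEVELS <- c("nt-ab", "nt-a", "nt-b", "fn-ab", "fn-a", "fn-b")

normalise_level <- function(level) {
  level <- gsub("α", "a", level)
  level <- gsub("β", "b", level)
  level
}

new_clonotype_table <- function(level, assignment, clonotypes) {
  structure(list(level = level, assignment = assignment,
                 clonotypes = clonotypes), class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> level %s: %d cells in %d clonotypes\n",
              x$level, nrow(x$assignment), nrow(x$clonotypes)))
  invisible(x)
}

# Per-cell chain keys for one definition level. Returns a list keyed by
# barcode of character vectors of chain keys.
cell_chain_keys <- function(cells, loci, seq_level) {
  ch <- cells$chains
  keep <- ch$locus %in% loci
  ch <- ch[keep, , drop = FALSE]
  cdr3 <- if (seq_level == "nt") ch$cdr3_nt else ch$cdr3_aa
  keys <- chain_key(ch$locus, ch$v_gene, ch$j_gene, cdr3)
  split(keys, factor(ch$barcode, levels = unique(cells$cells$barcode)))
}

level_loci <- function(level_suffix) {
  switch(level_suffix, ab = c("TRA", "TRB"), a = "TRA", b = "TRB",
         stop("level must be one of 'ab', 'a', 'b'"))
}

check_gating <- function(key_list, level_suffix, cells) {
  n_keys <- lengths(key_list)
  if (any(n_keys == 0L)) {
    stop(sprintf("%d cell(s) lack a chain required for level '%s' (gating violated)",
                 sum(n_keys == 0L), level_suffix))
  }
  if (level_suffix == "ab") {
    ch <- cells$chains
    has_a <- unique(ch$barcode[ch$locus == "TRA"])
    has_b <- unique(ch$barcode[ch$locus == "TRB"])
    bad <- setdiff(cells$cells$barcode, intersect(has_a, has_b))
    if (length(bad) > 0L) {
      stop(sprintf("%d cell(s) lack an alpha or beta chain at level 'ab' (gating violated)",
                   length(bad)))
    }
  }
  invisible(TRUE)
}

#' Call nucleotide clonotypes
#'
#' Cells share a nucleotide clonotype when their full chain sets at the
#' requested level (all alpha and beta chains for `"ab"`, alpha chains only
#' for `"a"`, beta chains only for `"b"`) are identical: same V and J gene
#' segments and same CDR3 nucleotide sequences.
#'
#' @param cells A gated `cell_set`.
#' @param level `"ab"`, `"a"` or `"b"`.
#' @return A `clonotype_table` (sizes set; numbers and ranks are assigned by
#'   [number_and_rank()]).
#' @export
call_nucleotide_clonotypes <- function(cells, level = c("ab", "a", "b")) {
  level <- normalise_level(match.arg(normalise_level(level[1L]),
                                     c("ab", "a", "b")))
  key_list <- cell_chain_keys(cells, level_loci(level), "nt")
  check_gating(key_list, level, cells)
  sigs <- vapply(key_list, signature_string, character(1L))
  ids_by_sig <- stats::setNames(
    paste0("nt", level, "_", seq_along(unique(sigs))), unique(sigs))
  assignment <- tibble::tibble(
    barcode = names(sigs),
    clonotype_id = unname(ids_by_sig[sigs]),
    ambiguous = FALSE
  )
  sizes <- table(assignment$clonotype_id)
  clonotypes <- tibble::tibble(
    clonotype_id = unname(ids_by_sig),
    signature = names(ids_by_sig),
    size = as.integer(sizes[unname(ids_by_sig)]),
    number = NA_integer_,
    rank = NA_integer_
  )
  new_clonotype_table(paste0("nt-", level), assignment, clonotypes)
}

#' Call functional (amino-acid) clonotypes with dropout tolerance
#'
#' Cells are first grouped by their exact amino-acid chain-set signature
#' ("seed groups"). Signatures that are not a strict subset of any other
#' observed signature at the same level anchor the clonotypes ("maximal"
#' signatures). Each non-maximal seed group is then merged into a compatible
#' maximal clonotype: every detected chain of the group must be contained in
#' the maximal signature (for the paired level this implies at least one
#' shared alpha and one shared beta chain, since gated cells carry both
#' loci). A group contained in two or more maximal signatures is assigned to
#' the one whose seed group holds the most cells (ties broken by
#' lexicographically smallest signature) and its cells are flagged ambiguous.
#'
#' @inheritParams call_nucleotide_clonotypes
#' @return A `clonotype_table`; clonotype signatures are the anchoring
#'   maximal signatures.
#' @export
call_functional_clonotypes <- function(cells, level = c("ab", "a", "b")) {
  level <- normalise_level(match.arg(normalise_level(level[1L]),
                                     c("ab", "a", "b")))
  key_list <- cell_chain_keys(cells, level_loci(level), "fn")
  check_gating(key_list, level, cells)
  key_list <- lapply(key_list, function(k) sort(unique(k)))
  sigs <- vapply(key_list, paste, character(1L), collapse = "+")

  uniq_sigs <- unique(sigs)
  sig_keys <- lapply(uniq_sigs, function(s) strsplit(s, "+", fixed = TRUE)[[1L]])
  sig_sizes <- as.integer(table(factor(sigs, levels = uniq_sigs)))
  n_sig <- length(uniq_sigs)

  # inverted index: chain key -> indices of signatures containing it
  all_keys <- unlist(sig_keys, use.names = FALSE)
  owner <- rep.int(seq_len(n_sig), lengths(sig_keys))
  index <- split(owner, all_keys)

  # supersets of signature i: signatures containing every chain of i
  supersets <- lapply(seq_len(n_sig), function(i) {
    cand <- Reduce(intersect, index[sig_keys[[i]]])
    cand[cand != i]
  })
  n_chains <- lengths(sig_keys)
  is_maximal <- vapply(seq_len(n_sig), function(i) {
    sup <- supersets[[i]]
    length(sup) == 0L || all(n_chains[sup] <= n_chains[i])
  }, logical(1L))

  maximal_idx <- which(is_maximal)
  target <- integer(n_sig)
  ambiguous <- logical(n_sig)
  for (i in seq_len(n_sig)) {
    if (is_maximal[i]) {
      target[i] <- i
      next
    }
    compat <- intersect(supersets[[i]], maximal_idx)
    if (length(compat) == 0L) {
      # cannot happen for a finite poset, but keep the group standalone
      target[i] <- i
      next
    }
    if (length(compat) == 1L) {
      target[i] <- compat
    } else {
      ord <- order(-sig_sizes[compat], uniq_sigs[compat], method = "radix")
      target[i] <- compat[ord[1L]]
      ambiguous[i] <- TRUE
    }
  }

  cluster_of_sig <- match(target, sort(unique(target)))
  ids <- paste0("fn", level, "_", cluster_of_sig)
  sig_idx <- match(sigs, uniq_sigs)
  assignment <- tibble::tibble(
    barcode = names(sigs),
    clonotype_id = ids[sig_idx],
    ambiguous = ambiguous[sig_idx]
  )
  cluster_ids <- unique(ids)
  anchor_sig <- uniq_sigs[target[match(cluster_ids, ids)]]
  sizes <- table(assignment$clonotype_id)
  clonotypes <- tibble::tibble(
    clonotype_id = cluster_ids,
    signature = anchor_sig,
    size = as.integer(sizes[cluster_ids]),
    number = NA_integer_,
    rank = NA_integer_
  )
  new_clonotype_table(paste0("fn-", level), assignment, clonotypes)
}

#' Number and rank clonotypes by size
#'
#' Clonotype numbers are assigned in descending size order, with number 1
#' the largest; clonotypes of identical size are randomly ordered using the
#' seeded RNG so numbering is reproducible. Ranks use competition ("min")
#' ranking: clonotypes of identical size share a rank, and sizes 5, 3, 3, 1
#' receive ranks 1, 2, 2, 4.
#'
#' @param table A `clonotype_table`.
#' @param seed Seed for the tie-breaking permutation (`NULL` to use the
#'   current RNG stream).
#' @return The table with `number` and `rank` filled in.
#' @export
number_and_rank <- function(table, seed = NULL) {
  stopifnot(inherits(table, "clonotype_table"))
  cl <- table$clonotypes
  k <- nrow(cl)
  tie_break <- with_seed(seed, sample.int(k))
  ord <- order(-cl$size, tie_break)
  number <- integer(k)
  number[ord] <- seq_len(k)
  # competition rank: 1 + number of strictly larger clonotypes
  sorted_sizes <- sort(cl$size, decreasing = TRUE)
  rank <- vapply(cl$size, function(s) sum(sorted_sizes > s) + 1L, integer(1L))
  cl$number <- number
  cl$rank <- rank
  table$clonotypes <- cl
  table
}

#' Per-sample clone size vector
#'
#' @param table A `clonotype_table`.
#' @return Named integer vector of cells per clonotype.
#' @export
clone_sizes <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  stats::setNames(table$clonotypes$size, table$clonotypes$clonotype_id)
}
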