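# Linking clonal identity to function: coreceptor assignment, pseudotime
# association tests, cross-trajectory correlations and the differential
# gene-importance rank statistic.

#' Assign CD4/CD8 coreceptor phenotype
#'
#' Gene mode uses normalized expression of CD8A, CD8B and CD4: cells are
#' CD8+ if CD8A > 0 and/or CD8B > 0; otherwise CD4+ if CD4 > 0; DN
#' (double-negative) if all three are undetected. Cells satisfying both the
#' CD8 and CD4 rules are labelled CD8+ with `ambiguous = TRUE` (the CD8 rule
#' is evaluated first). Protein mode uses normalized antibody counts: CD8+
#' if CD8 > 0.3; otherwise CD4+ if CD4 > 2.5 and CD8 < 0.2; else DN.
#'
#' @param expr A data frame or matrix of normalized expression with columns
#'   `CD8A`, `CD8B`, `CD4` (gene mode) or `CD8`, `CD4` (protein mode); row
#'   names or a `barcode` column identify cells.
#' @param mode `"gene"` or `"protein"`.
#' @return A tibble with `barcode`, `label` (CD8+/CD4+/DN) and `ambiguous`.
#' @export
assign_coreceptor <- function(expr, mode = c("gene", "protein")) {
  mode <- match.arg(mode)
  expr <- as.data.frame(expr)
  barcode <- if ("barcode" %in% names(expr)) as.character(expr$barcode)
             else rownames(expr) %||% as.character(seq_len(nrow(expr)))
  needed <- if (mode == "gene") c("CD8A", "CD8B", "CD4") else c("CD8", "CD4")
  missing <- setdiff(needed, names(expr))
  if (length(missing) > 0L) {
    stop(sprintf("missing %s channel(s): %s", mode,
                 paste(missing, collapse = ", ")))
  }
  if (mode == "gene") {
    cd8 <- expr$CD8A > 0 | expr$CD8B > 0
    cd4 <- expr$CD4 > 0
    label <- ifelse(cd8, "CD8+", ifelse(cd4, "CD4+", "DN"))
    ambiguous <- cd8 & cd4
  } else {
    cd8 <- expr$CD8 > 0.3
    cd4 <- !cd8 & expr$CD4 > 2.5 & expr$CD8 < 0.2
    label <- ifelse(cd8, "CD8+", ifelse(cd4, "CD4+", "DN"))
    ambiguous <- rep(FALSE, nrow(expr))
  }
  tibble::tibble(barcode = barcode, label = label, ambiguous = ambiguous)
}

#' Pseudotime-group association (omnibus Kruskal-Wallis)
#'
#' Kruskal-Wallis test of pseudotime across groups (TRBV genes or
#' clonotypes), after removing groups below `min_size` cells. Being
#' rank-based, the result is invariant to affine rescaling of pseudotime.
#'
#' @param pt Numeric pseudotime per cell.
#' @param groups Group label per cell.
#' @param min_size Minimum cells per retained group.
#' @return A list with `H`, `df`, `p`, `n_groups` and `undefined` (fewer
#'   than two retained groups).
#' @export
pseudotime_group_association <- function(pt, groups, min_size = 20) {
  stopifnot(length(pt) == length(groups))
  keep_levels <- names(which(table(groups) >= min_size))
  keep <- groups %in% keep_levels
  if (length(keep_levels) < 2L) {
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_,
                n_groups = length(keep_levels), undefined = TRUE))
  }
  kt <- stats::kruskal.test(pt[keep], factor(groups[keep]))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       n_groups = length(keep_levels), undefined = FALSE)
}

#' Per-clonotype pseudotime shift scan
#'
#' For every group with at least `min_size` cells, a two-group rank test
#' (Kruskal-Wallis with two levels, equivalent to a Wilcoxon rank-sum test)
#' of that group's pseudotimes against all remaining cells.
#'
#' @inheritParams pseudotime_group_association
#' @return A tibble with `group`, `n`, `median_shift` (group median minus
#'   rest median) and `p`.
#' @export
clonotype_pseudotime_scan <- function(pt, groups, min_size = 20) {
  stopifnot(length(pt) == length(groups))
  sizes <- table(groups)
  tested <- names(sizes)[sizes >= min_size]
  rows <- lapply(tested, function(g) {
    in_g <- groups == g
    if (all(in_g)) return(NULL)
    kt <- stats::kruskal.test(pt, factor(ifelse(in_g, "g", "rest")))
    tibble::tibble(group = g, n = sum(in_g),
                   median_shift = stats::median(pt[in_g]) - stats::median(pt[!in_g]),
                   p = kt$p.value)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(tibble::tibble(group = character(), n = integer(),
                          median_shift = numeric(), p = numeric()))
  }
  do.call(rbind, rows)
}

#' Cross-trajectory correlation of group mean pseudotimes
#'
#' Per-group mean pseudotime is computed on each trajectory; Spearman
#' correlation is reported over groups present on both.
#'
#' @param pt_a,pt_b Pseudotime per cell on the two trajectories (`NA` for
#'   cells absent from a trajectory).
#' @param groups Group label per cell.
#' @return A list with `rho`, `p`, `n_groups`, `group_means` tibble and
#'   `undefined` (fewer than three shared groups).
#' @export
cross_trajectory_group_correlation <- function(pt_a, pt_b, groups) {
  stopifnot(length(pt_a) == length(groups), length(pt_b) == length(groups))
  mean_by <- function(pt) tapply(pt, groups, mean, na.rm = TRUE)
  ma <- mean_by(pt_a); mb <- mean_by(pt_b)
  ok <- is.finite(ma) & is.finite(mb)
  gm <- tibble::tibble(group = names(ma)[ok], mean_a = as.numeric(ma[ok]),
                       mean_b = as.numeric(mb[ok]))
  if (nrow(gm) < 3L) {
    return(list(rho = NA_real_, p = NA_real_, n_groups = nrow(gm),
                group_means = gm, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(gm$mean_a, gm$mean_b,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_groups = nrow(gm),
       group_means = gm, undefined = FALSE)
}

#' Clone size versus pseudotime correlation
#'
#' Pearson correlation between log10 clonotype frequency and pseudotime.
#' Only clonotypes with at least `min_cells` cells enter; by default each
#' cell contributes one point (its clonotype's log frequency, its
#' pseudotime); `unit = "clonotype"` uses per-clonotype mean pseudotimes.
#'
#' @param pt Pseudotime per cell.
#' @param clonotype_ids Clonotype id per cell.
#' @param min_cells Minimum clonotype size.
#' @param unit `"cell"` or `"clonotype"`.
#' @return A list with `r`, `p`, `n` and `undefined` (a single clonotype or
#'   zero frequency variance).
#' @export
clone_size_pseudotime_correlation <- function(pt, clonotype_ids,
                                              min_cells = 20,
                                              unit = c("cell", "clonotype")) {
  stopifnot(length(pt) == length(clonotype_ids))
  unit <- match.arg(unit)
  sizes <- table(clonotype_ids)
  freq <- as.numeric(sizes) / length(clonotype_ids)
  names(freq) <- names(sizes)
  keep_ids <- names(sizes)[sizes >= min_cells]
  keep <- clonotype_ids %in% keep_ids
  if (length(keep_ids) < 2L) {
    return(list(r = NA_real_, p = NA_real_, n = length(keep_ids),
                undefined = TRUE))
  }
  if (unit == "cell") {
    x <- log10(freq[clonotype_ids[keep]])
    y <- pt[keep]
  } else {
    x <- log10(freq[keep_ids])
    y <- as.numeric(tapply(pt[keep], clonotype_ids[keep], mean)[keep_ids])
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(keep_ids),
                undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(keep_ids),
       undefined = FALSE)
}

#' Differential gene importance between two trajectories
#'
#' Genes are ranked by importance on each trajectory (rank 1 = most
#' important; ties broken by table order). The differential-importance ratio
#' is the larger rank divided by the smaller (>= 1, symmetric in the two
#' trajectories). A gene is selected as differentially important when its
#' importance FDR is below `fdr_thresh` on at least one trajectory and its
#' rank is within the top `top_n` on at least one trajectory. The display
#' transform log2(1/rank) is also emitted per trajectory.
#'
#' @param importance_a,importance_b Tibbles with columns `gene`,
#'   `importance` and `fdr`, over the same gene universe.
#' @param fdr_thresh FDR threshold.
#' @param top_n Rank cutoff.
#' @return A tibble with `gene`, `rank_a`, `rank_b`, `ratio`, `fdr_a`,
#'   `fdr_b`, `selected`, `log2_inv_rank_a`, `log2_inv_rank_b`.
#' @export
differential_gene_importance <- function(importance_a, importance_b,
                                         fdr_thresh = 0.05, top_n = 150) {
  assert_cols(importance_a, c("gene", "importance", "fdr"), "importance table A")
  assert_cols(importance_b, c("gene", "importance", "fdr"), "importance table B")
  if (!setequal(importance_a$gene, importance_b$gene) ||
      nrow(importance_a) != nrow(importance_b)) {
    stop("the two importance tables cover different gene universes")
  }
  rank_a <- rank(-importance_a$importance, ties.method = "first")
  b_idx <- match(importance_a$gene, importance_b$gene)
  rank_b_full <- rank(-importance_b$importance, ties.method = "first")
  rank_b <- rank_b_full[b_idx]
  fdr_a <- importance_a$fdr
  fdr_b <- importance_b$fdr[b_idx]
  ratio <- pmax(rank_a, rank_b) / pmin(rank_a, rank_b)
  selected <- (fdr_a < fdr_thresh | fdr_b < fdr_thresh) &
    (rank_a <= top_n | rank_b <= top_n)
  tibble::tibble(
    gene = importance_a$gene, rank_a = rank_a, rank_b = rank_b,
    ratio = ratio, fdr_a = fdr_a, fdr_b = fdr_b, selected = selected,
    log2_inv_rank_a = log2(1 / rank_a), log2_inv_rank_b = log2(1 / rank_b))
}
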