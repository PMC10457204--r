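# Consensus over repeated stochastic regulon-inference runs and
# recovery-curve (AUCell-style) activity scoring.
#
# Gene-regulatory-network inference is stochastic, so the same data yield a
# different regulon set on every run. Stability across many runs is used to
# separate reproducible regulons from noise: a regulon is high-confidence
# when its transcription factor appears in more than 80% of runs and at
# least five of its target genes each appear in more than 80% of the runs
# that contain the regulon.

#' Aggregate repeated regulon-inference runs into consensus regulons
#'
#' @param runs A list of runs; each run is a named list mapping transcription
#'   factor to a character vector of target genes.
#' @param regulon_thresh Minimum run-occurrence fraction for a regulon
#'   (strict inequality).
#' @param target_thresh Minimum target-occurrence fraction (strict),
#'   denominated by the runs in which the factor's regulon appeared.
#' @param min_targets Minimum number of high-confidence targets.
#' @return A tibble with one row per high-confidence regulon: `tf`,
#'   `run_occurrence`, `targets` (named numeric list column of per-target
#'   occurrence fractions) and `hc_targets` (character list column).
#' @export
aggregate_regulon_runs <- function(runs, regulon_thresh = 0.8,
                                   target_thresh = 0.8, min_targets = 5) {
  if (length(runs) == 0L) stop("empty run set")
  if (any(c(regulon_thresh, target_thresh) <= 0) ||
      any(c(regulon_thresh, target_thresh) >= 1)) {
    stop("thresholds must lie in (0, 1)")
  }
  n_runs <- length(runs)
  tfs <- sort(unique(unlist(lapply(runs, names), use.names = FALSE)))
  rows <- list()
  for (tf in tfs) {
    present <- vapply(runs, function(r) tf %in% names(r), logical(1L))
    occ <- sum(present) / n_runs
    if (!(occ > regulon_thresh)) next
    target_lists <- lapply(runs[present], function(r) unique(r[[tf]]))
    tcount <- table(unlist(target_lists, use.names = FALSE))
    tfrac <- as.numeric(tcount) / sum(present)
    names(tfrac) <- names(tcount)
    hc <- sort(names(tfrac)[tfrac > target_thresh])
    if (length(hc) < min_targets) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tf = tf, run_occurrence = occ, n_hc_targets = length(hc),
      targets = list(tfrac[order(-tfrac, names(tfrac))]),
      hc_targets = list(hc))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(tf = character(), run_occurrence = numeric(),
                          n_hc_targets = integer(), targets = list(),
                          hc_targets = list()))
  }
  do.call(rbind, rows)
}

#' Gene-by-regulon occurrence matrix
#'
#' Entry (gene, tf) is the percentage of all runs in which the gene appeared
#' in the factor's regulon. Only high-confidence regulons whose maximum
#' occurrence over the supplied genes exceeds `min_fraction` are retained.
#'
#' @inheritParams aggregate_regulon_runs
#' @param genes Genes of interest (rows).
#' @param min_fraction Minimum occurrence fraction over the supplied genes
#'   for a factor to be kept.
#' @param consensus Optional precomputed result of
#'   [aggregate_regulon_runs()]; computed with default thresholds otherwise.
#' @return A numeric matrix (genes x factors) of occurrence percentages.
#' @export
gene_occurrence_matrix <- function(runs, genes, min_fraction = 0.5,
                                   consensus = NULL) {
  if (length(runs) == 0L) stop("empty run set")
  if (is.null(consensus)) consensus <- aggregate_regulon_runs(runs)
  tfs <- consensus$tf
  n_runs <- length(runs)
  mat <- matrix(0, nrow = length(genes), ncol = length(tfs),
                dimnames = list(genes, tfs))
  for (j in seq_along(tfs)) {
    counts <- table(unlist(lapply(runs, function(r) {
      tg <- r[[tfs[j]]]
      if (is.null(tg)) character() else unique(intersect(tg, genes))
    }), use.names = FALSE))
    if (length(counts) > 0L) {
      mat[names(counts), j] <- 100 * as.numeric(counts) / n_runs
    }
  }
  keep <- apply(mat, 2L, max) > 100 * min_fraction
  mat[, keep, drop = FALSE]
}

#' Recovery-curve (AUCell-style) gene set activity score
#'
#' For each cell, genes are ranked by decreasing expression (ties broken at
#' random under the seeded RNG, or deterministically by column order). The
#' recovery curve counts gene-set hits among the top `ceil(top_fraction * G)`
#' ranks; the score is the area under this step curve divided by the maximal
#' achievable area (all reachable hits packed at the top ranks), so scores
#' lie in [0, 1]. Being rank-based, the score is invariant under any
#' monotone transformation of a cell's expression values.
#'
#' @param expression Numeric matrix, cells x genes, with gene column names.
#' @param gene_set Character vector of gene names; must all be present in
#'   the expression matrix.
#' @param top_fraction Fraction of top-ranked genes integrated (0 < f < 1).
#' @param seed RNG seed for random tie-breaking.
#' @param ties `"random"` or `"deterministic"` (ties broken by column
#'   order, for exact reproducibility without a seed).
#' @return Named numeric vector of per-cell scores.
#' @export
aucell_score <- function(expression, gene_set, top_fraction = 0.05,
                         seed = NULL, ties = c("random", "deterministic")) {
  ties <- match.arg(ties)
  if (length(gene_set) == 0L) stop("empty gene set")
  genes <- colnames(expression)
  if (is.null(genes)) stop("expression matrix must have gene column names")
  missing <- setdiff(gene_set, genes)
  if (length(missing) == length(gene_set)) {
    stop("gene set is disjoint from the expression gene universe")
  }
  if (length(missing) > 0L) {
    stop(sprintf("gene set members absent from the expression matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must lie in (0, 1)")
  }
  G <- ncol(expression)
  max_rank <- ceiling(top_fraction * G)
  in_set <- genes %in% gene_set
  m <- min(sum(in_set), max_rank)
  max_auc <- m * max_rank - m * (m - 1) / 2
  score_one <- function(x) {
    r <- if (ties == "random") rank(-x, ties.method = "random")
         else rank(-x, ties.method = "first")
    hit_ranks <- r[in_set]
    hit_ranks <- hit_ranks[hit_ranks <= max_rank]
    if (length(hit_ranks) == 0L) return(0)
    sum(max_rank - hit_ranks + 1) / max_auc
  }
  with_seed(seed, {
    scores <- apply(expression, 1L, score_one)
  })
  names(scores) <- rownames(expression)
  scores
}

#' Differential regulon activity between two cell groups
#'
#' Two-sided rank-sum test per regulon with Bonferroni correction across
#' regulons; regulons are also ordered by the absolute difference in mean
#' activity for display of the strongest shifts.
#'
#' @param activity_a,activity_b Numeric matrices, cells x regulons, with
#'   identical regulon column names.
#' @param alpha Adjusted significance threshold defining `significant`.
#' @return A tibble sorted by decreasing `|mean_diff|` with columns
#'   `regulon`, `statistic`, `p_raw`, `p_bonferroni`, `mean_a`, `mean_b`,
#'   `mean_diff`, `significant`.
#' @export
differential_regulon_activity <- function(activity_a, activity_b, alpha = 0.01) {
  if (is.null(colnames(activity_a)) || is.null(colnames(activity_b)) ||
      !identical(colnames(activity_a), colnames(activity_b))) {
    stop("activity matrices must have identical regulon column names")
  }
  if (nrow(activity_a) < 2L || nrow(activity_b) < 2L) {
    stop("each group needs at least 2 cells")
  }
  regs <- colnames(activity_a)
  stat <- p <- ma <- mb <- numeric(length(regs))
  for (j in seq_along(regs)) {
    a <- activity_a[, j]; b <- activity_b[, j]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    stat[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
    ma[j] <- mean(a); mb[j] <- mean(b)
  }
  p[is.na(p)] <- 1  # zero-variance ties across both groups
  out <- tibble::tibble(
    regulon = regs, statistic = stat, p_raw = p,
    p_bonferroni = stats::p.adjust(p, method = "bonferroni"),
    mean_a = ma, mean_b = mb, mean_diff = ma - mb)
  out$significant <- out$p_bonferroni < alpha
  out[order(-abs(out$mean_diff), out$regulon), , drop = FALSE]
}

#' Read regulon runs from a directory of JSON files
#'
#' Each file holds one run as an object mapping transcription factor to an
#' array of target genes.
#'
#' @param dir Directory containing `*.json` run files.
#' @return A list of runs.
#' @export
read_regulon_runs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no .json run files in %s", dir))
  lapply(files, function(f) {
    run <- jsonlite::read_json(f, simplifyVector = TRUE)
    lapply(run, as.character)
  })
}

#' Write regulon runs as JSON files
#'
#' @param runs List of runs (named lists tf -> targets).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_regulon_runs <- function(runs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("run%03d.json", seq_along(runs)))
  for (i in seq_along(runs)) {
    jsonlite::write_json(runs[[i]], paths[i], auto_unbox = FALSE)
  }
  invisible(paths)
}
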