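# Exact multinomial test of clonotype-cluster association.
#
# For a clonotype of n cells over k transcriptional clusters, the null is
# that its cells fall into clusters with the whole-sample cluster
# proportions. The p-value is the total null probability of outcomes at most
# as likely as the observed one. The exact path enumerates all
# choose(n+k-1, k-1) compositions when that count ("events") is below 1e6;
# otherwise a Monte Carlo estimate with ntrial = min(10 * events, 1e8)
# samples is used.

MAX_EXACT_EVENTS <- 1e6
MC_NTRIAL_CAP <- 1e8
# enumeration remains cheaper than literal sampling up to this many outcomes
MC_ENUM_CAP <- 2e9
PMF_TIE_TOL <- 1e-12

#' Number of distinct multinomial outcomes
#'
#' The number of compositions of n cells into k clusters,
#' choose(n + k - 1, k - 1), computed by an exact integer recurrence (each
#' step of the prefix product is an integer, so the result is exact up to
#' 2^53).
#'
#' @param n Number of cells (>= 1).
#' @param k Number of clusters (>= 1).
#' @return The outcome count as a double holding an exact integer.
#' @export
composition_count <- function(n, k) {
  if (length(n) != 1L || length(k) != 1L || n < 1 || k < 1 ||
      n != floor(n) || k != floor(k)) {
    stop("n and k must be single integers >= 1")
  }
  res <- 1
  for (i in seq_len(k - 1)) {
    res <- res * (n + i) / i
  }
  round(res)
}

check_null_probs <- function(observed, null_probs) {
  if (length(observed) != length(null_probs)) {
    stop("observed and null_probs must have equal length")
  }
  if (any(observed < 0) || any(observed != floor(observed))) {
    stop("observed counts must be non-negative integers")
  }
  if (abs(sum(null_probs) - 1) > 1e-9) {
    stop("null probabilities must sum to 1 (within 1e-9)")
  }
  if (any(null_probs < 0)) stop("null probabilities must be non-negative")
  zero <- null_probs == 0
  if (any(zero & observed > 0)) {
    stop("observed count in a zero-probability cluster")
  }
  list(observed = observed[!zero], probs = null_probs[!zero] / sum(null_probs[!zero]))
}

log_pmf <- function(observed, probs) {
  lgamma(sum(observed) + 1) - sum(lgamma(observed + 1)) +
    sum(ifelse(observed == 0, 0, observed * log(probs)))
}

#' Exact multinomial goodness-of-fit test
#'
#' Enumerates every composition of n into k parts and sums the null
#' probability of outcomes whose probability is at most that of the observed
#' outcome (with a 1 + 1e-12 relative tolerance to absorb floating-point ties
#' in the pmf).
#'
#' @param observed Integer vector of counts per cluster.
#' @param null_probs Null probabilities (must sum to 1 within 1e-9).
#' @return The exact p-value in (0, 1].
#' @export
exact_multinomial_test <- function(observed, null_probs) {
  chk <- check_null_probs(observed, null_probs)
  observed <- chk$observed; probs <- chk$probs
  n <- sum(observed)
  if (n < 1) stop("at least one observed cell is required")
  k <- length(observed)
  if (k == 1L) return(1)
  events <- composition_count(n, k)
  if (events >= MAX_EXACT_EVENTS) {
    stop(sprintf(
      "number of distinct outcomes (%s) >= 1e6; use monte_carlo_multinomial_test()",
      format(events, big.mark = ",")))
  }
  thresh <- log_pmf(observed, probs) + log1p(PMF_TIE_TOL)
  res <- cpp_multinom_tail(as.integer(n), as.numeric(probs), thresh, FALSE)
  min(1, res$tail)
}

# full outcome distribution diagnostics (enumeration invariants)
multinomial_outcome_total <- function(n, probs) {
  res <- cpp_multinom_tail(as.integer(n), as.numeric(probs), Inf, TRUE)
  list(total = res$total, events = res$events)
}

#' Monte Carlo multinomial goodness-of-fit test
#'
#' Estimates the probability that a null multinomial draw is at most as
#' likely as the observed outcome, from `ntrial` null samples, using the
#' add-one estimator p = (1 + hits) / (ntrial + 1) (which cannot return an
#' exact zero). By default `ntrial = min(10 * events, 1e8)`. When the outcome
#' space is small enough to enumerate, the per-trial hit probability is
#' computed exactly and the hit count is drawn as a single binomial variate,
#' which has exactly the same distribution as the literal trial loop; larger
#' outcome spaces fall back to literal sampling.
#'
#' @inheritParams exact_multinomial_test
#' @param seed RNG seed (`NULL` to use the current stream).
#' @param ntrial Number of Monte Carlo trials; default follows the
#'   10-times-events rule capped at 1e8.
#' @return A list with `p`, `ntrial` and `events`.
#' @export
monte_carlo_multinomial_test <- function(observed, null_probs, seed = NULL,
                                         ntrial = NULL) {
  chk <- check_null_probs(observed, null_probs)
  observed <- chk$observed; probs <- chk$probs
  n <- sum(observed)
  if (n < 1) stop("at least one observed cell is required")
  k <- length(observed)
  events <- composition_count(n, k)
  if (is.null(ntrial)) ntrial <- min(10 * events, MC_NTRIAL_CAP)
  if (k == 1L) return(list(p = 1, ntrial = ntrial, events = events))
  thresh <- log_pmf(observed, probs) + log1p(PMF_TIE_TOL)
  hits <- with_seed(seed, {
    if (events <= MC_ENUM_CAP) {
      pstar <- min(1, cpp_multinom_tail(as.integer(n), as.numeric(probs),
                                        thresh, FALSE)$tail)
      stats::rbinom(1L, size = ntrial, prob = pstar)
    } else {
      cpp_multinom_mc_hits(as.integer(n), as.numeric(probs), thresh, ntrial)
    }
  })
  list(p = (1 + hits) / (ntrial + 1), ntrial = ntrial, events = events)
}

#' Scan clonotypes for nonrandom distribution across clusters
#'
#' Tests every clonotype with at least `min_cells` cells in one sample.
#' The null probabilities are the whole-sample cluster proportions (all
#' cells in `clusters`, including the tested clonotype's own cells, unless
#' `loo_null = TRUE`); clusters with zero cells overall are dropped from the
#' support. The exact test is used when the outcome count is below 1e6, and
#' the Monte Carlo path otherwise. P values are Bonferroni-adjusted for the
#' number of clonotypes tested in the sample.
#'
#' @param assignment Tibble with columns `barcode` and `clonotype_id` (cells
#'   of one donor-sample), or a `clonotype_table`.
#' @param clusters Tibble with columns `barcode` and `cluster` covering all
#'   cells of the sample.
#' @param min_cells Minimum clonotype size to test.
#' @param seed RNG seed for Monte Carlo paths.
#' @param loo_null Estimate the null proportions from all other cells
#'   (leave-clonotype-out sensitivity analysis).
#' @return A tibble with one row per tested clonotype: observed counts
#'   (list column), `events`, `method`, `ntrial`, `p_raw`, `p_bonferroni`.
#' @export
clonotype_cluster_scan <- function(assignment, clusters, min_cells = 20,
                                   seed = NULL, loo_null = FALSE) {
  if (inherits(assignment, "clonotype_table")) assignment <- assignment$assignment
  assert_cols(assignment, c("barcode", "clonotype_id"), "clonotype assignment")
  assert_cols(clusters, c("barcode", "cluster"), "cluster labels")
  cluster_levels <- sort(unique(as.character(clusters$cluster)))
  all_counts <- table(factor(as.character(clusters$cluster),
                             levels = cluster_levels))
  cluster_levels <- cluster_levels[all_counts > 0]
  all_counts <- all_counts[cluster_levels]
  n_total <- sum(all_counts)

  cl_of_cell <- stats::setNames(as.character(clusters$cluster), clusters$barcode)
  sizes <- table(assignment$clonotype_id)
  tested_ids <- names(sizes)[sizes >= min_cells]
  m <- length(tested_ids)
  rows <- vector("list", m)
  with_seed(seed, {
    for (i in seq_along(tested_ids)) {
      id <- tested_ids[i]
      bcs <- assignment$barcode[assignment$clonotype_id == id]
      obs <- table(factor(cl_of_cell[bcs], levels = cluster_levels))
      obs <- as.integer(obs)
      n <- sum(obs)
      probs <- if (loo_null) {
        rest <- as.numeric(all_counts) - obs
        rest / sum(rest)
      } else {
        as.numeric(all_counts) / n_total
      }
      events <- composition_count(n, length(obs))
      if (events < MAX_EXACT_EVENTS) {
        p <- exact_multinomial_test(obs, probs)
        method <- "exact"; ntrial <- NA_real_
      } else {
        mc <- monte_carlo_multinomial_test(obs, probs, seed = NULL)
        p <- mc$p; method <- "monte_carlo"; ntrial <- mc$ntrial
      }
      rows[[i]] <- tibble::tibble(
        clonotype_id = id, n_cells = n, observed = list(obs),
        events = events, method = method, ntrial = ntrial, p_raw = p)
    }
  })
  out <- if (m > 0L) do.call(rbind, rows) else
    tibble::tibble(clonotype_id = character(), n_cells = integer(),
                   observed = list(), events = numeric(), method = character(),
                   ntrial = numeric(), p_raw = numeric())
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  attr(out, "null_probs") <- as.numeric(all_counts) / n_total
  attr(out, "cluster_levels") <- cluster_levels
  attr(out, "family_size") <- m
  out
}

#' Correlation between clonotype size and association significance
#'
#' Spearman correlation between the clonotype size rank and the Bonferroni
#' adjusted p-value. Sizes are ranked ascending (the largest clonotype has
#' the largest rank value), so size-dependent cluster bias, where larger
#' clonotypes reach smaller p-values, yields a negative rho.
#'
#' @param results Output of [clonotype_cluster_scan()].
#' @return A list with `rho`, `p`, `n` and `undefined` (all p identical).
#' @export
size_significance_correlation <- function(results) {
  if (nrow(results) < 3L) stop("at least 3 results are required")
  if (length(unique(results$p_bonferroni)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n = nrow(results),
                undefined = TRUE))
  }
  size_rank <- rank(results$n_cells)
  ct <- suppressWarnings(stats::cor.test(size_rank, results$p_bonferroni,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(results),
       undefined = FALSE)
}
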