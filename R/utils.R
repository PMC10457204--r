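# Internal helpers shared across modules.

#' @useDynLib clonolink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Canonical key for a single chain. Equality is exact tuple equality on
# locus, V gene, J gene and CDR3; D genes are excluded throughout.
chain_key <- function(locus, v_gene, j_gene, cdr3) {
  paste(locus, v_gene, j_gene, cdr3, sep = "|")
}

# Canonical signature for a chain set: sorted unique keys joined by "+".
signature_string <- function(keys) {
  paste(sort(unique(keys)), collapse = "+")
}

signature_keys <- function(signature) {
  strsplit(signature, "+", fixed = TRUE)
}

# Gene-name match ignoring allele suffixes ("TRAV1-2*01" matches "TRAV1-2").
strip_allele <- function(gene) {
  sub("\\*.*$", "", gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
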