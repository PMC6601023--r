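#' Hypergeometric upper-tail probability of a gene-set overlap
#'
#' Exact `P(X >= k)` for the overlap of a size-`K` set and a size-`n`
#' set drawn without replacement from a universe of `N` genes:
#' `sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`, evaluated through
#' [stats::phyper()], which works in log space and is stable for
#' genome-scale parameters.
#'
#' @param N universe size.
#' @param K size of set A.
#' @param n size of set B.
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @return The upper-tail probability; 1 when `k = 0`.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  N <- check_count(N, "N", lower = 1L)
  K <- check_count(K, "K")
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (K > N || n > N) stopf("set sizes K, n must not exceed the universe N")
  if (k > min(K, n)) stopf("overlap k exceeds min(K, n)")
  if (k == 0L) return(1)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional odds ratio and exact p from [stats::fisher.test()]. The
#' two-sided p sums the probabilities of all tables no more likely than
#' the observed one under the hypergeometric null; with
#' `alternative = "greater"` the one-sided p equals the hypergeometric
#' upper tail on the corresponding overlap layout. A zero margin yields
#' an odds ratio of 0 or Inf with a finite p.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `((a, b), (c, d))`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list with `odds_ratio` (conditional MLE) and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  for (nm in c("a", "b", "c", "d"))
    check_count(get(nm), nm, lower = 0L)
  ft <- fisher.test(matrix(c(a, c, b, d), 2L, 2L), alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Overlap test between two gene sets
#'
#' Computes the observed overlap of two gene sets and its hypergeometric
#' upper-tail p against a gene universe. The universe may be a size (the
#' default, 19,000, approximates the annotated human protein-coding
#' genome and is always reported because p depends on it) or an explicit
#' [gene_set], in which case members outside the universe are dropped
#' with a warning — curated lists from heterogeneous sources routinely
#' carry identifiers absent from any fixed universe.
#'
#' @param set_a,set_b [gene_set]s (non-empty).
#' @param universe integer universe size or a [gene_set].
#' @return An object of class `overlap_test`: list with `N`, `K`, `n`,
#'   `k`, `p_upper`, `expected` (`K n / N`), `fold_enrichment`
#'   (`k / expected`), `overlap_genes` (sorted), `set_a`, `set_b`.
#' @export
overlap_summary <- function(set_a, set_b, universe = 19000) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  a <- set_a$genes
  b <- set_b$genes
  if (!length(a) || !length(b)) stopf("empty gene set in overlap test")
  if (inherits(universe, "gene_set")) {
    u <- universe$genes
    drop_a <- setdiff(a, u)
    drop_b <- setdiff(b, u)
    if (length(drop_a) || length(drop_b))
      warnf("dropping %d gene(s) outside the universe: %s",
            length(drop_a) + length(drop_b),
            paste(sort(unique(c(drop_a, drop_b))), collapse = ", "))
    a <- intersect(a, u)
    b <- intersect(b, u)
    if (!length(a) || !length(b))
      stopf("no genes left inside the universe")
    N <- length(u)
  } else {
    N <- check_count(universe, "universe", lower = 1L)
  }
  if (length(a) > N || length(b) > N)
    stopf("set larger than the universe (N = %d)", N)
  genes <- sort(intersect(a, b))
  k <- length(genes)
  K <- length(a); n <- length(b)
  expected <- K * n / N
  structure(list(N = N, K = K, n = n, k = k,
                 p_upper = hypergeometric_tail(N, K, n, k),
                 expected = expected,
                 fold_enrichment = if (expected > 0) k / expected else NA_real_,
                 overlap_genes = genes,
                 set_a = set_a$name, set_b = set_b$name),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Hypergeometric gene-set overlap test\n")
  cat(sprintf("  sets: %s (K = %d) vs %s (n = %d)\n",
              x$set_a, x$K, x$set_b, x$n))
  cat(sprintf("  universe: N = %d genes\n", x$N))
  cat(sprintf("  overlap: k = %d (expected %.2f, fold enrichment %.2f)\n",
              x$k, x$expected, x$fold_enrichment))
  cat(sprintf("  P(X >= k) = %.4g\n", x$p_upper))
  if (x$k) cat("  genes:", paste(x$overlap_genes, collapse = ", "), "\n")
  invisible(x)
}
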