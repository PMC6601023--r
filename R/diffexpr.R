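# Vectorized core of the paired screen: per-feature log2 differences ->
# geometric-mean fold change, per-pair magnitude sd, paired t.
diffexpr_core <- function(x, features = NULL) {
  stopifnot(inherits(x, "paired_expression"))
  d <- paired_log2_diff(x)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(d))
    if (length(missing)) stopf("features not in matrix: %s",
                               paste(missing, collapse = ", "))
    d <- d[features, , drop = FALSE]
  }
  np <- ncol(d)
  if (np < 2L) stopf("insufficient pairs: need >= 2, have %d", np)
  mean_d <- rowMeans(d)
  sd_d <- apply(d, 1L, sd)
  # per-pair fold-change magnitudes max(r, 1/r) = 2^|log2 diff|
  mag <- 2^abs(d)
  fc_magnitude <- 2^abs(mean_d)
  fc_sd <- apply(mag, 1L, sd)
  direction <- ifelse(mean_d > 0, "up", "down")
  t_stat <- ifelse(sd_d == 0 & mean_d == 0, 0,
                   mean_d / (sd_d / sqrt(np)))
  degenerate <- sd_d == 0 & mean_d != 0
  t_stat[degenerate] <- NA_real_
  p <- 2 * pt(-abs(t_stat), df = np - 1L)
  p[sd_d == 0 & mean_d == 0] <- 1
  if (any(degenerate))
    warnf("%d feature(s) with zero variance of paired differences: p set to NA",
          sum(degenerate))
  list(feature_id = rownames(d), fc_magnitude = fc_magnitude,
       direction = direction, fc_sd = fc_sd, t = t_stat, df = np - 1L,
       p = p, n_pairs = np)
}

#' Paired fold change of one feature
#'
#' Per-pair ratios `r_i = case_i / control_i` are taken on the linear
#' scale (log2-stored values are exponentiated). The mean ratio is the
#' geometric mean; the reported magnitude is `max(rbar, 1/rbar)` with a
#' direction flag, mirroring screening reports that print down-regulated
#' features as a positive fold change plus "down". The SD is the sd of
#' the per-pair fold-change magnitudes `max(r_i, 1/r_i)`.
#'
#' @param x a [paired_expression].
#' @param feature feature id.
#' @return A list with `fc_magnitude` (>= 1), `direction` (`"up"` /
#'   `"down"`) and `fc_sd`.
#' @export
paired_fold_change <- function(x, feature) {
  res <- diffexpr_core(x, features = feature)
  list(fc_magnitude = unname(res$fc_magnitude),
       direction = unname(res$direction), fc_sd = unname(res$fc_sd))
}

#' Paired t-test of one feature
#'
#' Student's paired t on the per-pair log2 differences (the standard
#' scale for intensity data), `df = n_pairs - 1`, two-sided p. If all
#' differences are 0 the statistic is 0 and p = 1; if the differences
#' are constant but nonzero the p-value is undefined and reported as
#' `NA` with a warning, never silently 0.
#'
#' @param x a [paired_expression].
#' @param feature feature id.
#' @return A list with `t`, `df`, `p_two_sided`.
#' @export
paired_t_test <- function(x, feature) {
  res <- diffexpr_core(x, features = feature)
  list(t = unname(res$t), df = res$df, p_two_sided = unname(res$p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sort ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in input order (delegated to
#' [stats::p.adjust()]). `NA` entries pass through.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Paired differential-expression screen
#'
#' Runs the fold-change / paired-t screen over all features (or a
#' subset): geometric-mean fold change with direction, per-pair
#' magnitude SD, raw paired-t p, and BH-adjusted q.
#'
#' @param x a [paired_expression].
#' @param features optional feature subset.
#' @return A data frame of class `diffexpr_result` with columns
#'   `feature_id`, `fc`, `sd`, `direction`, `p`, `q`, ordered by
#'   ascending p (ties by feature id); attribute `n_pairs`.
#' @export
differential_expression <- function(x, features = NULL) {
  res <- diffexpr_core(x, features = features)
  out <- data.frame(feature_id = res$feature_id, fc = res$fc_magnitude,
                    sd = res$fc_sd, direction = res$direction,
                    p = res$p, q = bh_adjust(res$p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pairs") <- res$n_pairs
  class(out) <- c("diffexpr_result", "data.frame")
  out
}

#' @export
print.diffexpr_result <- function(x, digits = 3, max_rows = 10L, ...) {
  cat(sprintf("Paired differential-expression screen: %d features, %d pairs\n",
              nrow(x), attr(x, "n_pairs") %||% NA))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print(head(df, max_rows), row.names = FALSE)
  if (nrow(df) > max_rows) cat(sprintf("... %d more rows\n", nrow(df) - max_rows))
  cat("Note: FC is magnitude >= 1 with direction; SD is the sd of per-pair",
      "fold-change magnitudes.\n")
  invisible(x)
}

#' Filter a screen by fold change (and optionally raw p)
#'
#' Keeps features with `fc >= cutoff` (inclusive); when `alpha` is given,
#' additionally requires raw `p < alpha`. Both the raw fold-change
#' screen and the significance-filtered report are supported.
#'
#' @param results a `diffexpr_result` (or data frame with `fc` and `p`).
#' @param cutoff fold-change threshold (> 1).
#' @param alpha optional raw-p level.
#' @return The filtered data frame; attribute `"n_kept"` holds the count.
#' @export
filter_by_fc <- function(results, cutoff, alpha = NULL) {
  check_number(cutoff, "cutoff")
  if (cutoff <= 1) stopf("'cutoff' must be > 1")
  keep <- !is.na(results$fc) & results$fc >= cutoff
  if (!is.null(alpha)) {
    check_number(alpha, "alpha", 0, 1)
    keep <- keep & !is.na(results$p) & results$p < alpha
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- nrow(out)
  attr(out, "n_pairs") <- attr(results, "n_pairs")
  out
}

#' Hierarchical clustering of features
#'
#' Agglomerative clustering of per-feature sample vectors with complete
#' linkage and Euclidean distance. Rows are pre-sorted lexicographically
#' by feature id so tie-breaking is deterministic and independent of
#' input order.
#'
#' @param x a [paired_expression].
#' @param features feature ids to cluster (>= 2).
#' @return An [stats::hclust] object (merge list, heights, leaf order).
#' @export
cluster_features <- function(x, features = rownames(x$values)) {
  stopifnot(inherits(x, "paired_expression"))
  features <- unique(as.character(features))
  if (length(features) < 2L) stopf("need >= 2 features to cluster")
  missing <- setdiff(features, rownames(x$values))
  if (length(missing)) stopf("features not in matrix: %s",
                             paste(missing, collapse = ", "))
  mat <- x$values[sort(features), , drop = FALSE]
  hclust(dist(mat, method = "euclidean"), method = "complete")
}
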