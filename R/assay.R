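#' Comparative-Ct relative quantification
#'
#' The comparative threshold-cycle method with amplification efficiency
#' assumed exactly 2 (no efficiency correction): replicates are averaged
#' per sample, `dCt = target Ct - reference Ct` per sample, group means
#' taken, `ddCt = dCt(case) - dCt(control)`, and relative expression
#' `2^-ddCt`. A positive ddCt therefore means lower expression in cases.
#'
#' @param table a [ct_table] with both groups present.
#' @return An object of class `relative_quant`: list with
#'   `delta_ct_case`, `delta_ct_control`, `delta_delta_ct`,
#'   `rel_expression`, `n_case`, `n_control`.
#' @export
delta_delta_ct <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  if (any(is.na(table$reference_ct))) stopf("missing reference Ct")
  groups <- unique(table$group)
  if (!all(c("case", "control") %in% groups))
    stopf("both groups (case, control) are required for relative quantification")
  # average replicates per sample first
  per_sample <- function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    tgt <- tapply(sub$target_ct, sub$sample_id, mean)
    ref <- tapply(sub$reference_ct, sub$sample_id, mean)
    as.numeric(tgt - ref[names(tgt)])
  }
  dct_case <- per_sample("case")
  dct_ctrl <- per_sample("control")
  ddct <- mean(dct_case) - mean(dct_ctrl)
  structure(list(delta_ct_case = mean(dct_case),
                 delta_ct_control = mean(dct_ctrl),
                 delta_delta_ct = ddct,
                 rel_expression = 2^(-ddct),
                 n_case = length(dct_case), n_control = length(dct_ctrl)),
            class = "relative_quant")
}

#' @export
print.relative_quant <- function(x, ...) {
  cat("Comparative-Ct relative quantification\n")
  cat(sprintf("  dCt case = %.3f (n = %d), dCt control = %.3f (n = %d)\n",
              x$delta_ct_case, x$n_case, x$delta_ct_control, x$n_control))
  cat(sprintf("  ddCt = %.3f  ->  relative expression 2^-ddCt = %.3f\n",
              x$delta_delta_ct, x$rel_expression))
  invisible(x)
}

#' Wound-closure percentage
#'
#' Fraction of the scratch that has closed:
#' `(initial - remaining) / initial * 100`. The result is invariant to
#' the unit of breadth (mm, pixels). A remaining breadth larger than the
#' initial breadth is rejected — the wound cannot grow under this
#' metric; report raw breadths instead in that case.
#'
#' @param initial_breadth wound breadth at time 0 (> 0).
#' @param remaining_breadth wound breadth at measurement, same units,
#'   in \[0, initial\].
#' @return Closure percentage in \[0, 100\]. Vectorized.
#' @export
wound_closure_percent <- function(initial_breadth, remaining_breadth) {
  if (any(!is.finite(initial_breadth)) || any(initial_breadth <= 0))
    stopf("initial breadth must be positive")
  if (any(!is.finite(remaining_breadth)) || any(remaining_breadth < 0))
    stopf("remaining breadth must be non-negative")
  if (any(remaining_breadth > initial_breadth))
    stopf("remaining breadth exceeds initial breadth; closure is undefined")
  (initial_breadth - remaining_breadth) / initial_breadth * 100
}

#' Collagen gel contraction ratio
#'
#' Ratio of treated to control gel diameter. Cells that contract the gel
#' less leave a larger diameter, so a ratio above 1 means less
#' contraction than control. `gel_contraction_ratio(a, b) *
#' gel_contraction_ratio(b, a) = 1`.
#'
#' @param diameter_treated,diameter_control gel diameters (> 0), any
#'   common unit.
#' @return Dimensionless ratio. Vectorized.
#' @export
gel_contraction_ratio <- function(diameter_treated, diameter_control) {
  if (any(!is.finite(c(diameter_treated, diameter_control))) ||
      any(diameter_treated <= 0) || any(diameter_control <= 0))
    stopf("gel diameters must be positive")
  diameter_treated / diameter_control
}

# two-sided p as twice the smaller tail of a (symmetric) permutation
# distribution, capped at 1
two_sided_from_tails <- function(stat_perm, stat_obs, eps = 1e-9) {
  lo <- mean(stat_perm <= stat_obs + eps)
  hi <- mean(stat_perm >= stat_obs - eps)
  min(1, 2 * min(lo, hi))
}

#' Exact Mann-Whitney U test
#'
#' Two-sample rank test with midranks under ties. For small samples
#' (total n <= `exact_limit`) the two-sided p is exact: all
#' `C(nx + ny, nx)` assignments of the pooled observations to the two
#' groups are enumerated and the smaller tail of the U distribution is
#' doubled (capped at 1). Larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric observation vectors (each >= 2 values).
#' @param exact_limit total-sample-size limit for exact enumeration
#'   (default 12).
#' @return A list with `U` (statistic of `x`), `p_two_sided` and
#'   `method` (`"exact enumeration"` / `"normal approximation"`).
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 12L) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("need >= 2 observations per group")
  if (any(!is.finite(c(x, y)))) stopf("observations must be finite")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_limit) {
    idx <- combn(nx + ny, nx)
    u_perm <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- two_sided_from_tails(u_perm, U)
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sig2 <= 0) return(list(U = U, p_two_sided = 1,
                               method = "normal approximation"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = unname(U), p_two_sided = p, method = method)
}

#' Exact Wilcoxon signed-rank test
#'
#' One-sample/paired signed-rank test. Zero differences are dropped
#' (their count is reported); absolute differences are midranked under
#' ties; `W` is the positive-rank sum. For n <= `exact_limit` nonzero
#' differences the two-sided p is exact over all `2^n` sign
#' assignments; beyond that a normal approximation with tie correction
#' is used.
#'
#' @param differences numeric vector of paired differences; >= 3 must be
#'   nonzero.
#' @param exact_limit nonzero-difference limit for exact enumeration
#'   (default 15).
#' @return A list with `W`, `p_two_sided`, `n_nonzero`, `n_zero`,
#'   `method`.
#' @export
wilcoxon_signed_exact <- function(differences, exact_limit = 15L) {
  if (any(!is.finite(differences))) stopf("differences must be finite")
  d <- differences[differences != 0]
  n_zero <- length(differences) - length(d)
  if (!length(d)) stopf("all differences are zero")
  n <- length(d)
  if (n < 3L) stopf("need >= 3 nonzero differences, have %d", n)
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_perm <- as.vector(signs %*% r)
    p <- two_sided_from_tails(w_perm, W)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(W = unname(W), p_two_sided = p, n_nonzero = n, n_zero = n_zero,
       method = method)
}

#' Two-sample t-test on raw observations
#'
#' Student (pooled) or Welch t-test via [stats::t.test()]. When both
#' groups have zero variance: equal means give `t = 0, p = 1` by
#' convention, unequal means are a degenerate-variance error.
#'
#' @param x,y numeric observation vectors (>= 2 each).
#' @param welch logical; `TRUE` for the Welch-Satterthwaite df.
#' @return A list with `t`, `df`, `p_two_sided`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("need >= 2 observations per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2L, p_two_sided = 1))
    stopf("degenerate variance: both groups constant with unequal means")
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value)
}

#' Two-sample t-test from printed summary statistics
#'
#' Reconstructs the t statistic from group means, standard errors of the
#' mean and sample sizes, so results printed as `mean +/- SEM (n)` can be
#' sanity-checked without raw measurements. Pooled (Student) or
#' Welch-Satterthwaite df.
#'
#' @param mean_x,mean_y group means.
#' @param sem_x,sem_y standard errors of the mean (>= 0).
#' @param n_x,n_y sample sizes (>= 2).
#' @param welch logical; `TRUE` (default) for Welch.
#' @return A list with `t`, `df`, `p_two_sided`.
#' @export
two_sample_t_summary <- function(mean_x, sem_x, n_x, mean_y, sem_y, n_y,
                                 welch = TRUE) {
  n_x <- check_count(n_x, "n_x", lower = 2L)
  n_y <- check_count(n_y, "n_y", lower = 2L)
  check_number(sem_x, "sem_x", lower = 0)
  check_number(sem_y, "sem_y", lower = 0)
  vx <- sem_x^2 * n_x  # group variance from SEM
  vy <- sem_y^2 * n_y
  if (sem_x == 0 && sem_y == 0) {
    if (mean_x == mean_y)
      return(list(t = 0, df = n_x + n_y - 2L, p_two_sided = 1))
    stopf("degenerate variance: both groups constant with unequal means")
  }
  if (welch) {
    se2 <- sem_x^2 + sem_y^2
    t <- (mean_x - mean_y) / sqrt(se2)
    df <- se2^2 / (sem_x^4 / (n_x - 1) + sem_y^4 / (n_y - 1))
  } else {
    sp2 <- ((n_x - 1) * vx + (n_y - 1) * vy) / (n_x + n_y - 2)
    t <- (mean_x - mean_y) / sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  }
  list(t = t, df = df, p_two_sided = 2 * pt(-abs(t), df))
}
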