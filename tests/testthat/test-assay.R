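make_ct <- function(case_dct, ctrl_dct, ref = 20) {
  n <- length(case_dct) + length(ctrl_dct)
  ct_table(data.frame(
    sample_id = paste0("s", seq_len(n)),
    group = rep(c("case", "control"), c(length(case_dct), length(ctrl_dct))),
    target_ct = ref + c(case_dct, ctrl_dct),
    reference_ct = ref))
}

test_that("comparative Ct: identity, closed forms, reciprocity", {
  same <- make_ct(c(5, 5), c(5, 5))
  expect_equal(delta_delta_ct(same)$rel_expression, 1)

  down <- make_ct(c(6.6, 6.6), c(5, 5))       # ddCt 1.6
  rq <- delta_delta_ct(down)
  expect_equal(rq$delta_delta_ct, 1.6)
  expect_equal(round(rq$rel_expression, 3), 0.330)

  up <- make_ct(rep(5 - 6.64, 3), rep(5, 3))  # ddCt -6.64: ~100-fold up
  expect_equal(delta_delta_ct(up)$rel_expression, 2^6.64)
  expect_equal(round(delta_delta_ct(up)$rel_expression), 100)

  # swapping groups inverts the relative expression exactly
  swapped <- make_ct(c(5, 5), c(6.6, 6.6))
  expect_equal(delta_delta_ct(down)$rel_expression *
                 delta_delta_ct(swapped)$rel_expression, 1)
})

test_that("comparative Ct averages replicates per sample first", {
  df <- data.frame(sample_id = c("a", "a", "b", "c"),
                   group = c("case", "case", "case", "control"),
                   target_ct = c(26, 27, 25, 25),
                   reference_ct = 20, replicate = c(1, 2, 1, 1))
  rq <- delta_delta_ct(ct_table(df))
  # sample a averages to 26.5; group mean of (6.5, 5) minus control 5
  expect_equal(rq$delta_delta_ct, mean(c(6.5, 5)) - 5)
  expect_equal(rq$n_case, 2L)
})

test_that("single-group Ct tables are rejected", {
  df <- data.frame(sample_id = c("a", "b"), group = "case",
                   target_ct = c(25, 26), reference_ct = 20)
  expect_error(delta_delta_ct(ct_table(df)), "both groups")
})

test_that("wound closure spans 0-100% and rejects wound growth", {
  expect_equal(wound_closure_percent(100, 100), 0)
  expect_equal(wound_closure_percent(100, 0), 100)
  expect_equal(wound_closure_percent(100, 68.24), 31.76)
  expect_error(wound_closure_percent(100, 120), "exceeds")
  # unit invariance: mm vs pixels
  expect_equal(wound_closure_percent(1.2, 0.9),
               wound_closure_percent(1.2 * 350, 0.9 * 350))
})

test_that("gel contraction ratio is reciprocal and unit-free", {
  expect_equal(gel_contraction_ratio(5, 5), 1)
  expect_equal(gel_contraction_ratio(1.36, 1.0), 1.36)
  expect_equal(gel_contraction_ratio(3, 7) * gel_contraction_ratio(7, 3), 1)
  expect_error(gel_contraction_ratio(-1, 2), "positive")
})

test_that("exact Mann-Whitney: separation, ties, identity", {
  sep <- mann_whitney_exact(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(sep$U, 16)
  expect_equal(sep$p_two_sided, 2 / 70, tolerance = 1e-12)
  expect_equal(sep$method, "exact enumeration")
  tied <- mann_whitney_exact(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tied$p_two_sided, 1)
  expect_error(mann_whitney_exact(1, c(2, 3)), ">= 2")
})

test_that("exact Mann-Whitney matches the reference on tie-free samples", {
  set.seed(51)
  for (i in 1:50) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    ours <- mann_whitney_exact(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon signed-rank: one-sided mass, preconditions, zeros", {
  allpos <- wilcoxon_signed_exact(c(1, 2, 3, 4, 5))
  expect_equal(allpos$W, 15)
  expect_equal(allpos$p_two_sided, 2 / 32, tolerance = 1e-12)
  expect_error(wilcoxon_signed_exact(c(-1, 1)), ">= 3")
  expect_error(wilcoxon_signed_exact(c(0, 0, 0)), "zero")
  withzero <- wilcoxon_signed_exact(c(0, 1, 2, -3, 4))
  expect_equal(withzero$n_zero, 1L)
  expect_equal(withzero$n_nonzero, 4L)
})

test_that("exact signed-rank matches the reference on tie-free samples", {
  set.seed(52)
  for (i in 1:50) {
    d <- rnorm(sample(3:8, 1), 0.4)
    ours <- wilcoxon_signed_exact(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(ours$W, unname(ref$statistic))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney is conservative under the null at n = 4 + 4", {
  set.seed(53)
  rejections <- vapply(1:2000, function(i)
    mann_whitney_exact(rnorm(4), rnorm(4))$p_two_sided < 0.05, TRUE)
  expect_lte(mean(rejections), 0.05)
})

test_that("two-sample t: identity, translation invariance, degenerate rules", {
  x <- c(3, 3, 3); y <- c(3, 3, 3)
  same <- two_sample_t(x, y)
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  expect_error(two_sample_t(c(2, 2), c(3, 3)), "degenerate variance")
  set.seed(54)
  a <- rnorm(5); b <- rnorm(5)
  shifted <- two_sample_t(a + 10, b + 10, welch = TRUE)
  expect_equal(shifted$t, two_sample_t(a, b, welch = TRUE)$t)
})

test_that("summary-statistic Welch t matches the printed-summary computation", {
  res <- two_sample_t_summary(31.76, 0.84, 4, 4.65, 2.36, 4, welch = TRUE)
  expect_equal(res$t, 10.8222, tolerance = 1e-4)
  expect_equal(res$df, 3.7481, tolerance = 1e-4)
  expect_lt(res$p_two_sided, 0.001)
  # cross-check against t.test on raw data via its own summaries
  set.seed(55)
  x <- rnorm(6, 10, 2); y <- rnorm(8, 7, 3)
  ref <- t.test(x, y)
  ours <- two_sample_t_summary(mean(x), sd(x) / sqrt(6), 6,
                               mean(y), sd(y) / sqrt(8), 8, welch = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
})
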