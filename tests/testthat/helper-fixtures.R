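# Builders for small in-memory and on-disk fixtures used across tests.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# paired_expression holding given log2 values for one feature; one column
# pair per value pair
pe_from_log2 <- function(case, control, feature = "F1") {
  np <- length(case)
  subjects <- sprintf("S%02d", seq_len(np))
  values <- matrix(c(case, control), nrow = 1,
                   dimnames = list(feature,
                                   c(paste0(subjects, "_t"), paste0(subjects, "_n"))))
  meta <- data.frame(sample_id = colnames(values),
                     subject_id = rep(subjects, 2),
                     condition = rep(c("case", "control"), each = np))
  paired_expression(values, meta, log2_scale = TRUE)
}

# multi-feature variant: case and control are features x pairs matrices
pe_from_matrices <- function(case, control) {
  np <- ncol(case)
  subjects <- sprintf("S%02d", seq_len(np))
  values <- cbind(case, control)
  colnames(values) <- c(paste0(subjects, "_t"), paste0(subjects, "_n"))
  meta <- data.frame(sample_id = colnames(values),
                     subject_id = rep(subjects, 2),
                     condition = rep(c("case", "control"), each = np))
  paired_expression(values, meta, log2_scale = TRUE)
}

# small deterministic weighted network from an edge string
# "A B 0.9; B C 0.8"
net_from_string <- function(s) {
  rows <- strsplit(trimws(strsplit(s, ";")[[1]]), "[ ]+")
  gene_network(data.frame(from = vapply(rows, `[[`, "", 1),
                          to = vapply(rows, `[[`, "", 2),
                          weight = as.numeric(vapply(rows, `[[`, "", 3))))
}

# brute-force hypergeometric upper tail by enumerating all size-n draws
hyper_tail_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)  # K-set taken as 1..K
}

# brute-force BH step-up: q_i = min over observed thresholds t >= p_i of
# m * t / #(p <= t)
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi - 1e-15]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t + 1e-15), 0)))
  }, 0)
}

# brute-force AUC: fraction of concordant positive-negative pairs,
# ties counting one half
auc_brute <- function(pos_scores, neg_scores) {
  grid <- outer(pos_scores, neg_scores, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(grid)
}
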