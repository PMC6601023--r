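test_that("symmetric normalization follows the degree formula", {
  two <- net_from_string("A B 1.0")
  Wn <- normalize_adjacency(two)
  expect_equal(Wn["A", "B"], 1)
  expect_equal(Wn["A", "A"], 0)

  star <- net_from_string("HUB L1 1; HUB L2 1; HUB L3 1; HUB L4 1")
  Ws <- normalize_adjacency(star)
  expect_equal(Ws["HUB", "L1"], 0.5)  # 1/sqrt(4 * 1)
  expect_equal(Ws["L1", "L2"], 0)

  iso <- gene_network(data.frame(from = "A", to = "B", weight = 1),
                      nodes = c("A", "B", "LONER"))
  expect_equal(attr(normalize_adjacency(iso), "isolated"), "LONER")
})

test_that("normalized adjacency has spectral radius at most 1", {
  for (s in 1:10) {
    set.seed(s)
    g <- igraph::sample_gnp(30, 0.15)
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) next
    net <- gene_network(data.frame(from = paste0("N", el[, 1]),
                                   to = paste0("N", el[, 2]),
                                   weight = runif(nrow(el), 0.2, 1)))
    ev <- eigen(as.matrix(normalize_adjacency(net)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("RWR reaches the two-node closed form", {
  net <- net_from_string("A B 1.0")
  f <- propagate_rwr(net, gene_set("A", "seed"),
                     propagation_config("rwr", alpha = 0.5))
  expect_equal(unname(f["A"]), 2 / 3, tolerance = 1e-8)
  expect_equal(unname(f["B"]), 1 / 3, tolerance = 1e-8)
  expect_true(attr(f, "converged"))
})

test_that("RWR limits: restart-dominated walks return the seed vector", {
  net <- net_from_string("A B 0.9; B C 0.8; C D 0.7")
  f0 <- c(A = 0.5, B = 0.5, C = 0, D = 0)
  f <- propagate_rwr(net, gene_set(c("A", "B"), "seed"),
                     propagation_config("rwr", alpha = 1e-4))
  expect_equal(unname(f[names(f0)]), unname(f0), tolerance = 5e-4)
})

test_that("components carrying no seed score zero", {
  net <- net_from_string("A B 0.9; C D 0.8")
  f <- propagate_rwr(net, gene_set("A", "seed"))
  expect_equal(unname(f[c("C", "D")]), c(0, 0))
  expect_gt(f["B"], 0)
})

test_that("RWR fixed point solves the linear system (direct-solve oracle)", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(50:200, 1)
    g <- igraph::sample_pa(n, m = 2, directed = FALSE)
    el <- igraph::as_edgelist(g)
    net <- gene_network(data.frame(from = paste0("N", el[, 1]),
                                   to = paste0("N", el[, 2]),
                                   weight = runif(nrow(el), 0.5, 1)))
    seeds <- gene_set(sample(net$nodes, 5), "seed")
    cfg <- propagation_config("rwr", alpha = 0.6, tol = 1e-10)
    f <- propagate_rwr(net, seeds, cfg)
    Wn <- as.matrix(normalize_adjacency(net))
    f0 <- setNames(numeric(length(net$nodes)), net$nodes)
    f0[intersect(seeds$genes, net$nodes)] <- 1 / 5
    direct <- solve(diag(length(f0)) - cfg$alpha * Wn, (1 - cfg$alpha) * f0)
    expect_lt(max(abs(f - direct)), 1e-8)
    resid <- (diag(length(f0)) - cfg$alpha * Wn) %*% f - (1 - cfg$alpha) * f0
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("naive Bayes scores sum log-evidence over seed neighbours", {
  net <- net_from_string("G S1 1.0; G S2 1.0; H S1 0.5; LONE H 0.9")
  s <- naive_bayes_score(net, gene_set(c("S1", "S2"), "seed"))
  expect_equal(unname(s["G"]), 2 * log(2), tolerance = 1e-12)
  expect_equal(unname(s["H"]), log(1.5), tolerance = 1e-12)
  expect_equal(unname(s["LONE"]), 0)
  # adding a seed neighbour strictly increases the score
  net2 <- net_from_string("G S1 1.0; G S2 1.0; G S3 0.4; H S1 0.5; LONE H 0.9")
  s2 <- naive_bayes_score(net2, gene_set(c("S1", "S2", "S3"), "seed"))
  expect_gt(s2["G"], s["G"])
})

test_that("seeds absent from the network are dropped; empty seed set errors", {
  net <- net_from_string("A B 0.9")
  expect_warning(f <- propagate_rwr(net, gene_set(c("A", "ZZ"), "seed")),
                 "absent")
  expect_equal(attr(f, "effective_seeds"), "A")
  expect_error(suppressWarnings(
    propagate_rwr(net, gene_set("ZZ", "seed"))), "empty effective seed set")
})

test_that("ranking sorts by score with midrank ties and exclusion", {
  r <- rank_genes(c(A = 3, B = 1, C = 2))
  expect_equal(r$gene, c("A", "C", "B"))
  expect_equal(r$rank, c(1, 2, 3))
  rt <- rank_genes(c(A = 1, B = 1))
  expect_equal(rt$rank, c(1.5, 1.5))
  rx <- rank_genes(c(A = 3, B = 1, C = 2), exclude = gene_set("A", "ex"))
  expect_equal(rx$gene, c("C", "B"))
  expect_equal(rx$rank, c(1, 2))
})

test_that("AUC follows the rank-sum formula with midranks", {
  rk <- rank_genes(c(P1 = 0.9, N1 = 0.5, P2 = 0.4, N2 = 0.1))
  v <- evaluate_auc(rk, gene_set(c("P1", "P2"), "val"))
  expect_equal(v$auc, 0.75)  # 3 of 4 concordant pairs
  expect_equal(v$n_positives, 2L)
  # perfect separation
  rk2 <- rank_genes(c(P1 = 5, P2 = 4, N1 = 3, N2 = 2, N3 = 1))
  expect_equal(evaluate_auc(rk2, gene_set(c("P1", "P2"), "val"))$auc, 1)
})

test_that("ROC curves run monotonically from (0,0) to (1,1)", {
  set.seed(17)
  sc <- setNames(round(runif(40), 1), paste0("G", 1:40))  # ties via rounding
  rk <- rank_genes(sc)
  v <- evaluate_auc(rk, gene_set(sample(names(sc), 10), "val"))
  roc <- v$roc
  expect_equal(roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("rank-sum AUC equals brute-force concordant-pair counting", {
  set.seed(18)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- setNames(sample(seq(0, 1, 0.05), n, TRUE), paste0("G", 1:n))
    pos <- sample(names(sc), sample(2:(n - 2), 1))
    v <- evaluate_auc(rank_genes(sc), gene_set(pos, "val"))
    expect_equal(v$auc, auc_brute(sc[pos], sc[setdiff(names(sc), pos)]),
                 tolerance = 1e-12)
  }
})

test_that("label-permutation null AUC is centred at one half", {
  sim <- simulate_network(network_sim_spec(n_genes = 300, module_size = 20),
                          seed = 2)
  sets <- simulate_gene_sets(sim$module, sim$network, seed_sim_spec(30, 12),
                             seed = 3)
  rk <- rank_genes(naive_bayes_score(sim$network, sets$seed),
                   exclude = sets$seed)
  null <- auc_permutation_null(rk, n_positives = 11, n_perm = 200, seed = 4)
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - 0.5), 3 * se + 0.02)
})

test_that("consistent gene relabeling leaves scores and AUC unchanged", {
  net <- net_from_string("A B 0.9; B C 0.8; C D 0.7; A D 0.95; B D 0.85")
  seeds <- gene_set(c("A", "C"), "seed")
  val <- gene_set("B", "val")
  relabel <- c(A = "W", B = "X", C = "Y", D = "Z")
  net2 <- gene_network(data.frame(from = relabel[net$edges$from],
                                  to = relabel[net$edges$to],
                                  weight = net$edges$weight))
  for (m in c("naive_bayes", "rwr")) {
    p1 <- prioritize(net, seeds, val, propagation_config(m))
    p2 <- prioritize(net2, gene_set(relabel[seeds$genes], "seed"),
                     gene_set(relabel[val$genes], "val"),
                     propagation_config(m))
    expect_equal(p1$summary$auc, p2$summary$auc)
    expect_equal(p1$ranking$score[order(p1$ranking$gene)],
                 p2$ranking$score[order(relabel[p2$ranking$gene])])
  }
})

test_that("prioritize reports shared genes, errors when seeds swallow validation", {
  sim <- simulate_network(network_sim_spec(n_genes = 200, module_size = 15),
                          seed = 5)
  sets <- simulate_gene_sets(sim$module, sim$network,
                             seed_sim_spec(20, 10, seed_validation_overlap = 2),
                             seed = 6)
  pr <- prioritize(sim$network, sets$seed, sets$validation)
  expect_length(pr$summary$seed_validation_shared, 2L)
  expect_equal(pr$summary$n_positives, 8L)  # shared genes never count
  expect_error(prioritize(sim$network, sets$seed, sets$seed),
               "no positives")
  # determinism: identical inputs give identical output
  pr2 <- prioritize(sim$network, sets$seed, sets$validation)
  expect_identical(pr$ranking, pr2$ranking)
  expect_identical(pr$summary, pr2$summary)
})
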