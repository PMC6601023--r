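test_that("network simulation is a pure function of (spec, seed)", {
  spec <- network_sim_spec(n_genes = 200, attachment = 2, module_size = 20,
                           module_extra_density = 0.3)
  set.seed(123)
  before <- .Random.seed
  a <- simulate_network(spec, seed = 1)
  expect_identical(.Random.seed, before)  # global RNG state untouched
  b <- simulate_network(spec, seed = 1)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$module, b$module)
  expect_false(identical(a$network$edges,
                         simulate_network(spec, seed = 2)$network$edges))
})

test_that("module density 1 plants a clique", {
  sim <- simulate_network(network_sim_spec(n_genes = 60, module_size = 8,
                                           module_extra_density = 1), seed = 3)
  e <- sim$network$edges
  in_mod <- e$from %in% sim$module & e$to %in% sim$module
  expect_equal(sum(in_mod), choose(8, 2))
})

test_that("planted modules are denser than the network background", {
  spec <- network_sim_spec(n_genes = 200, attachment = 2, module_size = 20,
                           module_extra_density = 0.3)
  deg_ratio <- vapply(1:20, function(s) {
    sim <- simulate_network(spec, seed = s)
    e <- sim$network$edges
    deg <- table(factor(c(e$from, e$to), levels = sim$network$nodes))
    mean(deg[sim$module]) / mean(deg)
  }, 0)
  expect_gt(mean(deg_ratio), 1)
  expect_gt(min(deg_ratio), 1)
})

test_that("gene-set simulation achieves sizes and overlaps exactly", {
  sim <- simulate_network(network_sim_spec(n_genes = 200, module_size = 20),
                          seed = 1)
  spec <- seed_sim_spec(n_seed = 30, n_validation = 15,
                        overlap_with_module = 0.5, seed_validation_overlap = 3)
  sets <- simulate_gene_sets(sim$module, sim$network, spec, seed = 2)
  expect_length(sets$seed, 30L)
  expect_length(sets$validation, 15L)
  expect_length(intersect(sets$seed$genes, sets$validation$genes), 3L)
  mc <- attr(sets, "module_counts")
  expect_equal(mc$seed, 15L)        # round(0.5 * 30)
  expect_equal(mc$validation, 8L)   # round(0.5 * 15)
})

test_that("zero module overlap keeps the seed set outside the module", {
  sim <- simulate_network(network_sim_spec(n_genes = 200, module_size = 20),
                          seed = 1)
  sets <- simulate_gene_sets(sim$module, sim$network,
                             seed_sim_spec(20, 10, overlap_with_module = 0,
                                           seed_validation_overlap = 2),
                             seed = 4)
  expect_length(intersect(sets$seed$genes, sim$module), 0L)
  expect_length(intersect(sets$seed$genes, sets$validation$genes), 2L)
})

test_that("gene-set simulation rejects infeasible specs", {
  sim <- simulate_network(network_sim_spec(n_genes = 100, module_size = 5),
                          seed = 1)
  expect_error(simulate_gene_sets(sim$module, sim$network,
                                  seed_sim_spec(n_seed = 20, n_validation = 5,
                                                overlap_with_module = 0.9),
                                  seed = 1),
               "exceeds module size")
  expect_error(seed_sim_spec(n_seed = 5, n_validation = 3,
                             seed_validation_overlap = 4), "overlap")
})

test_that("a study-shaped scaled-down fixture is valid", {
  sim <- simulate_network(network_sim_spec(n_genes = 500, module_size = 25),
                          seed = 9)
  sets <- simulate_gene_sets(sim$module, sim$network,
                             seed_sim_spec(n_seed = 38, n_validation = 11,
                                           overlap_with_module = 0.5,
                                           seed_validation_overlap = 1),
                             seed = 10)
  expect_length(sets$seed, 38L)
  expect_length(sets$validation, 11L)
  expect_length(intersect(sets$seed$genes, sets$validation$genes), 1L)
})

test_that("expression simulation is deterministic and plants recoverable FCs", {
  spec <- expression_sim_spec(n_features = 50, n_pairs = 13, n_de = 6,
                              planted_fc = 4, sigma_noise = 0.3)
  a <- simulate_paired_expression(spec, seed = 7)
  b <- simulate_paired_expression(spec, seed = 7)
  expect_identical(a$expression$values, b$expression$values)
  expect_equal(nrow(a$truth), 6L)
  expect_setequal(unique(a$truth$direction), c("up", "down"))
  de <- differential_expression(a$expression)
  planted <- de[de$feature_id %in% a$truth$feature_id, ]
  expect_true(all(planted$fc > 1.5))
  # planted directions recovered
  expect_identical(planted$direction[match(a$truth$feature_id,
                                           planted$feature_id)],
                   a$truth$direction)
})

test_that("under the global null, paired-t p-values are uniform", {
  sim <- simulate_paired_expression(
    expression_sim_spec(n_features = 1000, n_pairs = 13, n_de = 0),
    seed = 11)
  expect_equal(nrow(sim$truth), 0L)
  de <- differential_expression(sim$expression)
  ks <- stats::ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free Ct simulation hits the comparative-Ct closed forms", {
  rq0 <- delta_delta_ct(simulate_ct_table(5, 0, sd = 0, seed = 1))
  expect_equal(rq0$rel_expression, 1)
  rq <- delta_delta_ct(simulate_ct_table(5, 1.6, sd = 0, seed = 1))
  expect_equal(rq$rel_expression, 2^-1.6)
  expect_equal(round(rq$rel_expression, 3), 0.330)
  rq2 <- delta_delta_ct(simulate_ct_table(5, 2.12, sd = 0, seed = 1))
  expect_equal(round(rq2$rel_expression, 3), 0.230)
})
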