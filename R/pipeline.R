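# Deterministic helpers for pipeline outputs: fixed-format TSV/JSON so a
# rerun with the same seed reproduces identical bytes.
write_tsv_fixed <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.*g", digits, x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_fixed <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Generate the full set of synthetic pipeline inputs
#'
#' Writes all fixture files in the pipeline's file formats: a weighted
#' edge list, seed/validation/module gene lists, a paired expression
#' matrix with sample metadata and a planted-feature truth table, and a
#' qPCR Ct table. Sub-seeds for the individual simulators are derived
#' from `config$rng_seed` by fixed offsets, so one seed reproduces every
#' file byte-for-byte.
#'
#' @param out_dir output directory (created if absent).
#' @param config an [analysis_config]; `rng_seed` governs all draws.
#' @param network_spec a [network_sim_spec].
#' @param sets_spec a [seed_sim_spec].
#' @param expr_spec an [expression_sim_spec].
#' @param ct_delta_delta_ct,ct_sd,ct_n_per_group parameters of
#'   [simulate_ct_table()].
#' @return Invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(out_dir, config = analysis_config(),
                         network_spec = network_sim_spec(),
                         sets_spec = seed_sim_spec(),
                         expr_spec = expression_sim_spec(),
                         ct_delta_delta_ct = 1.6, ct_sd = 0.25,
                         ct_n_per_group = 13L) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- config$rng_seed
  net <- simulate_network(network_spec, seed = s)
  sets <- simulate_gene_sets(net$module, net$network, sets_spec, seed = s + 1L)
  expr <- simulate_paired_expression(expr_spec, seed = s + 2L)
  ct <- simulate_ct_table(n_per_group = ct_n_per_group,
                          delta_delta_ct = ct_delta_delta_ct,
                          sd = ct_sd, seed = s + 3L)
  paths <- list(
    network = file.path(out_dir, "network.tsv"),
    seeds = file.path(out_dir, "seeds.txt"),
    validation = file.path(out_dir, "validation.txt"),
    module = file.path(out_dir, "module.txt"),
    values = file.path(out_dir, "expression.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    ct = file.path(out_dir, "ct.tsv"))
  write_edge_list(net$network, paths$network)
  write_gene_set(sets$seed, paths$seeds)
  write_gene_set(sets$validation, paths$validation)
  writeLines(net$module, paths$module)
  ex <- expr$expression
  df <- data.frame(feature_id = rownames(ex$values),
                   ex$values, check.names = FALSE)
  write_tsv_fixed(df, paths$values)
  write.table(ex$metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(expr$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tsv_fixed(as.data.frame(ct), paths$ct)
  invisible(paths)
}

#' Run the differential-expression screen on files
#'
#' Reads an expression matrix and its metadata, runs
#' [differential_expression()], writes a screening report TSV (columns
#' miRNA, FC, SD, direction, p, q) and a JSON summary with the feature
#' counts passing each fold-change cutoff, raw and significance-filtered.
#'
#' @param path_values,path_metadata input TSV paths.
#' @param out_prefix path prefix; writes `<prefix>_report.tsv` and
#'   `<prefix>_summary.json`.
#' @param config an [analysis_config] (uses `fc_cutoffs`, `fdr_alpha`).
#' @param log2_scale scale of the stored values.
#' @return Invisibly, the `diffexpr_result`.
#' @export
run_diffexpr <- function(path_values, path_metadata, out_prefix,
                         config = analysis_config(), log2_scale = TRUE) {
  x <- read_expression(path_values, path_metadata, log2_scale = log2_scale)
  res <- differential_expression(x)
  report <- data.frame(miRNA = res$feature_id, FC = res$fc, SD = res$sd,
                       direction = res$direction, p = res$p, q = res$q)
  write_tsv_fixed(report, paste0(out_prefix, "_report.tsv"))
  counts <- lapply(config$fc_cutoffs, function(cut) list(
    fc_cutoff = cut,
    n_fc = attr(filter_by_fc(res, cut), "n_kept"),
    n_fc_and_p = attr(filter_by_fc(res, cut, alpha = config$fdr_alpha),
                      "n_kept")))
  write_json_fixed(list(n_features = nrow(res),
                        n_pairs = attr(res, "n_pairs"),
                        fdr_alpha = config$fdr_alpha,
                        cutoffs = counts),
                   paste0(out_prefix, "_summary.json"))
  invisible(res)
}

#' Run the gene-set overlap test on files
#'
#' @param path_set_a,path_set_b gene-set files ([read_gene_set()]
#'   formats).
#' @param out_json output JSON path.
#' @param universe universe size (always echoed in the output).
#' @return Invisibly, the [overlap_summary()] result.
#' @export
run_overlap <- function(path_set_a, path_set_b, out_json, universe = 19000) {
  a <- read_gene_set(path_set_a)
  b <- read_gene_set(path_set_b)
  res <- overlap_summary(a, b, universe = universe)
  write_json_fixed(unclass(res), out_json)
  invisible(res)
}

#' Run network-propagation prioritization on files
#'
#' Reads the weighted network and the seed and validation gene sets,
#' runs [prioritize()], and writes the ranking TSV (gene, score, rank),
#' the ROC TSV (fpr, tpr) and a JSON run summary.
#'
#' @param path_network STRING-style edge list.
#' @param path_seeds,path_validation gene-set files.
#' @param out_prefix path prefix; writes `<prefix>_ranking.tsv`,
#'   `<prefix>_roc.tsv`, `<prefix>_summary.json`.
#' @param config an [analysis_config] (uses `string_confidence_min` and
#'   `propagation`).
#' @return Invisibly, the `prioritization` object.
#' @export
run_prioritize <- function(path_network, path_seeds, path_validation,
                           out_prefix, config = analysis_config()) {
  net <- read_edge_list(path_network, min_score = config$string_confidence_min)
  seeds <- read_gene_set(path_seeds)
  validation <- read_gene_set(path_validation)
  res <- prioritize(net, seeds, validation, config = config$propagation)
  write_tsv_fixed(as.data.frame(res$ranking), paste0(out_prefix, "_ranking.tsv"))
  write_tsv_fixed(res$validation$roc, paste0(out_prefix, "_roc.tsv"))
  write_json_fixed(res$summary, paste0(out_prefix, "_summary.json"))
  invisible(res)
}

#' Run comparative-Ct quantification on a Ct table file
#'
#' @param path_ct Ct table TSV.
#' @param out_json output JSON path.
#' @return Invisibly, the `relative_quant` result.
#' @export
run_assay <- function(path_ct, out_json) {
  res <- delta_delta_ct(read_ct_table(path_ct))
  write_json_fixed(unclass(res), out_json)
  invisible(res)
}

#' Run the full in-silico pipeline on synthetic data
#'
#' End-to-end composition used for smoke testing and demonstration:
#' simulate all inputs, then run the differential-expression screen, the
#' seed-vs-validation overlap test (universe = network size), the
#' network-propagation prioritization, and the comparative-Ct
#' quantification, all from the files written by the simulation step.
#' Every stage is deterministic given `config$rng_seed`: rerunning into
#' a fresh directory reproduces identical output bytes.
#'
#' @param out_dir output directory.
#' @param config an [analysis_config].
#' @param network_spec,sets_spec,expr_spec simulation specifications.
#' @return Invisibly, a list with the stage results and `files` (all
#'   written paths).
#' @export
run_pipeline <- function(out_dir, config = analysis_config(),
                         network_spec = network_sim_spec(),
                         sets_spec = seed_sim_spec(),
                         expr_spec = expression_sim_spec()) {
  paths <- run_simulate(out_dir, config, network_spec, sets_spec, expr_spec)
  de <- run_diffexpr(paths$values, paths$metadata,
                     file.path(out_dir, "diffexpr"), config)
  ov <- run_overlap(paths$seeds, paths$validation,
                    file.path(out_dir, "overlap.json"),
                    universe = network_spec$n_genes)
  pr <- run_prioritize(paths$network, paths$seeds, paths$validation,
                       file.path(out_dir, "prioritize"), config)
  as_ <- run_assay(paths$ct, file.path(out_dir, "assay.json"))
  files <- c(unlist(paths),
             diffexpr_report = file.path(out_dir, "diffexpr_report.tsv"),
             diffexpr_summary = file.path(out_dir, "diffexpr_summary.json"),
             overlap = file.path(out_dir, "overlap.json"),
             prioritize_ranking = file.path(out_dir, "prioritize_ranking.tsv"),
             prioritize_roc = file.path(out_dir, "prioritize_roc.tsv"),
             prioritize_summary = file.path(out_dir, "prioritize_summary.json"),
             assay = file.path(out_dir, "assay.json"))
  write_json_fixed(list(rng_seed = config$rng_seed,
                        n_genes = network_spec$n_genes,
                        de_features = nrow(de),
                        overlap_k = ov$k, overlap_p = ov$p_upper,
                        auc = pr$summary$auc,
                        rel_expression = as_$rel_expression),
                   file.path(out_dir, "run_summary.json"))
  invisible(list(diffexpr = de, overlap = ov, prioritization = pr,
                 assay = as_, files = c(files,
                   run_summary = file.path(out_dir, "run_summary.json"))))
}
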