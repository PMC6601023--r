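# Every simulator is a pure function of (spec, seed): the global RNG
# state is saved and restored around the draw.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Network simulation specification
#'
#' Describes a synthetic confidence-weighted gene network: a scale-free
#' (preferential-attachment) backbone — interaction databases such as
#' STRING are hub-dominated — with a planted disease module whose members
#' receive extra internal edges, emulating a disease-gene neighbourhood.
#' An Erdos-Renyi backbone is available for null checks.
#'
#' @param n_genes node count.
#' @param attachment edges added per node during preferential attachment
#'   (ignored for `model = "erdos_renyi"`, where it sets the expected
#'   degree instead).
#' @param module_size planted-module size (<= `n_genes`).
#' @param module_extra_density probability in \[0, 1\] that each absent
#'   within-module pair gains an edge.
#' @param weight_range edge-weight interval, a sub-interval of (0, 1].
#'   Default (0.7, 1], the weight image of STRING's "high confidence"
#'   scores.
#' @param model `"preferential_attachment"` (default) or `"erdos_renyi"`.
#' @return A list of class `network_sim_spec`.
#' @export
network_sim_spec <- function(n_genes = 500L, attachment = 2L,
                             module_size = 25L, module_extra_density = 0.4,
                             weight_range = c(0.7, 1.0),
                             model = c("preferential_attachment", "erdos_renyi")) {
  n_genes <- check_count(n_genes, "n_genes", lower = 2L)
  attachment <- check_count(attachment, "attachment", lower = 1L)
  module_size <- check_count(module_size, "module_size", lower = 0L)
  if (module_size > n_genes) stopf("module_size (%d) exceeds n_genes (%d)",
                                   module_size, n_genes)
  check_number(module_extra_density, "module_extra_density", 0, 1)
  stopifnot(length(weight_range) == 2L)
  if (weight_range[1] <= 0 || weight_range[2] > 1 ||
      weight_range[1] > weight_range[2])
    stopf("weight_range must be an interval within (0, 1]")
  structure(list(n_genes = n_genes, attachment = attachment,
                 module_size = module_size,
                 module_extra_density = module_extra_density,
                 weight_range = as.numeric(weight_range),
                 model = match.arg(model)),
            class = "network_sim_spec")
}

#' Simulate a weighted gene network with a planted disease module
#'
#' Draws a scale-free backbone by preferential attachment (or an
#' Erdos-Renyi graph), selects a random module of `module_size` genes,
#' adds each absent within-module edge with probability
#' `module_extra_density`, and assigns edge weights uniformly in
#' `weight_range`. Deterministic for a fixed seed.
#'
#' @param spec a [network_sim_spec].
#' @param seed integer RNG seed.
#' @return A list with `network` (a [gene_network]) and `module`
#'   (character vector of module gene ids).
#' @export
simulate_network <- function(spec = network_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_sim_spec"))
  with_seed(seed, {
    g <- if (spec$model == "preferential_attachment")
      igraph::sample_pa(spec$n_genes, m = spec$attachment, directed = FALSE)
    else
      igraph::sample_gnp(spec$n_genes,
                         p = min(1, spec$attachment / (spec$n_genes - 1)))
    nodes <- sprintf("G%04d", seq_len(spec$n_genes))
    el <- igraph::as_edgelist(g, names = FALSE)
    from <- nodes[pmin(el[, 1], el[, 2])]
    to   <- nodes[pmax(el[, 1], el[, 2])]
    module <- sort(sample(nodes, spec$module_size))
    if (spec$module_size >= 2L && spec$module_extra_density > 0) {
      pairs <- combn(module, 2L)
      key <- paste(from, to)
      absent <- !(paste(pairs[1, ], pairs[2, ]) %in% key)
      add <- absent & (runif(ncol(pairs)) < spec$module_extra_density)
      from <- c(from, pairs[1, add])
      to   <- c(to, pairs[2, add])
    }
    keep <- !duplicated(paste(from, to)) & from != to
    from <- from[keep]; to <- to[keep]
    w <- runif(length(from), spec$weight_range[1], spec$weight_range[2])
    net <- gene_network(data.frame(from = from, to = to, weight = w,
                                   stringsAsFactors = FALSE),
                        nodes = nodes)
    list(network = net, module = module)
  })
}

#' Seed/validation gene-set simulation specification
#'
#' Describes two gene sets drawn against a network with a planted
#' module: a seed set (emulating predicted miRNA target genes) and a
#' validation set (emulating curated disease genes), each with a target
#' fraction of members drawn from the module and an exact number of
#' genes placed in both sets.
#'
#' @param n_seed,n_validation set sizes.
#' @param overlap_with_module fraction in \[0, 1\] of each set targeted to
#'   come from the planted module.
#' @param seed_validation_overlap exact count of genes placed in both
#'   sets (<= both set sizes).
#' @return A list of class `seed_sim_spec`.
#' @export
seed_sim_spec <- function(n_seed = 40L, n_validation = 12L,
                          overlap_with_module = 0.6,
                          seed_validation_overlap = 1L) {
  n_seed <- check_count(n_seed, "n_seed", lower = 1L)
  n_validation <- check_count(n_validation, "n_validation", lower = 1L)
  check_number(overlap_with_module, "overlap_with_module", 0, 1)
  seed_validation_overlap <- check_count(seed_validation_overlap,
                                         "seed_validation_overlap")
  if (seed_validation_overlap > min(n_seed, n_validation))
    stopf("seed_validation_overlap exceeds a set size")
  structure(list(n_seed = n_seed, n_validation = n_validation,
                 overlap_with_module = overlap_with_module,
                 seed_validation_overlap = seed_validation_overlap),
            class = "seed_sim_spec")
}

#' Simulate seed and validation gene sets with controlled overlap
#'
#' Set sizes and the seed-validation overlap are achieved exactly.
#' Module membership is a target: shared genes are drawn from the module
#' first (when both sets request module members), then the validation
#' set's module quota, then the seed set's, each from the remaining
#' module pool; when the joint demand exceeds the module size the later
#' draws are capped and topped up from non-module nodes. Achieved module
#' counts are recorded in the `"module_counts"` attribute.
#'
#' @param module character vector of planted-module gene ids (must be
#'   network nodes).
#' @param network a [gene_network].
#' @param spec a [seed_sim_spec].
#' @param seed integer RNG seed.
#' @return A list with `seed` and `validation`, both [gene_set]s, plus
#'   attribute `"module_counts"`.
#' @export
simulate_gene_sets <- function(module, network, spec = seed_sim_spec(),
                               seed = 1L) {
  stopifnot(inherits(network, "gene_network"), inherits(spec, "seed_sim_spec"))
  module <- normalize_gene_ids(module)
  if (!all(module %in% network$nodes))
    stopf("module genes missing from network: %s",
          paste(setdiff(module, network$nodes), collapse = ", "))
  f <- spec$overlap_with_module
  m_seed <- round(f * spec$n_seed)
  m_val  <- round(f * spec$n_validation)
  if (max(m_seed, m_val) > length(module))
    stopf("requested module overlap (%d) exceeds module size (%d)",
          max(m_seed, m_val), length(module))
  nonmod <- setdiff(network$nodes, module)
  with_seed(seed, {
    s <- spec$seed_validation_overlap
    s_mod <- min(s, m_seed, m_val)
    pool_mod <- module
    shared_mod <- sample(pool_mod, s_mod)
    pool_mod <- setdiff(pool_mod, shared_mod)
    pool_non <- nonmod
    shared_non <- sample(pool_non, s - s_mod)
    pool_non <- setdiff(pool_non, shared_non)
    shared <- c(shared_mod, shared_non)

    val_mod <- sample(pool_mod, min(m_val - s_mod, length(pool_mod)))
    pool_mod <- setdiff(pool_mod, val_mod)
    seed_mod <- sample(pool_mod, min(m_seed - s_mod, length(pool_mod)))

    n_val_non <- spec$n_validation - s - length(val_mod)
    n_seed_non <- spec$n_seed - s - length(seed_mod)
    if (n_val_non + n_seed_non > length(pool_non))
      stopf("network too small for the requested gene sets")
    val_non <- sample(pool_non, n_val_non)
    pool_non <- setdiff(pool_non, val_non)
    seed_non <- sample(pool_non, n_seed_non)

    out <- list(
      seed = gene_set(c(shared, seed_mod, seed_non), name = "seed",
                      source = "simulate_gene_sets"),
      validation = gene_set(c(shared, val_mod, val_non), name = "validation",
                            source = "simulate_gene_sets"))
    attr(out, "module_counts") <- list(
      seed = s_mod + length(seed_mod),
      validation = s_mod + length(val_mod),
      shared_in_module = s_mod)
    out
  })
}

#' Paired expression simulation specification
#'
#' Describes a synthetic paired case/control expression experiment on
#' the log2 scale: per-feature baselines, a shared subject effect within
#' each tissue pair, a planted condition effect of `planted_fc` for
#' `n_de` features (half up-, half down-regulated in cases), and
#' Gaussian residual noise. Defaults mirror the leiomyoma/myometrium
#' screen at reduced feature count: 13 subject pairs and 6 planted
#' differential features.
#'
#' @param n_features feature count.
#' @param n_pairs subject-pair count (>= 2).
#' @param n_de planted differential features (<= `n_features`).
#' @param planted_fc true fold change of planted features (> 1).
#' @param sigma_subject between-subject sd, log2 units (> 0).
#' @param sigma_noise residual sd, log2 units (> 0).
#' @return A list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_features = 500L, n_pairs = 13L,
                                n_de = 6L, planted_fc = 4,
                                sigma_subject = 0.5, sigma_noise = 0.3) {
  n_features <- check_count(n_features, "n_features", lower = 1L)
  n_pairs <- check_count(n_pairs, "n_pairs", lower = 2L)
  n_de <- check_count(n_de, "n_de")
  if (n_de > n_features) stopf("n_de exceeds n_features")
  check_number(planted_fc, "planted_fc")
  if (planted_fc <= 1) stopf("planted_fc must be > 1")
  check_number(sigma_subject, "sigma_subject")
  check_number(sigma_noise, "sigma_noise")
  if (sigma_subject <= 0 || sigma_noise <= 0) stopf("sds must be > 0")
  structure(list(n_features = n_features, n_pairs = n_pairs, n_de = n_de,
                 planted_fc = planted_fc, sigma_subject = sigma_subject,
                 sigma_noise = sigma_noise),
            class = "expression_sim_spec")
}

#' Simulate a paired expression matrix with planted fold changes
#'
#' Log2 value = feature baseline (uniform on 6-12) + subject effect
#' `N(0, sigma_subject^2)` shared by the two samples of a pair +
#' condition effect (`+/- log2(planted_fc)` in case samples of planted
#' features; the first half of planted features are up-regulated, the
#' rest down) + residual noise `N(0, sigma_noise^2)`.
#'
#' @param spec an [expression_sim_spec].
#' @param seed integer RNG seed.
#' @return A list with `expression` (a [paired_expression], log2 scale)
#'   and `truth` (data frame `feature_id`, `direction`, `fc` for planted
#'   features).
#' @export
simulate_paired_expression <- function(spec = expression_sim_spec(),
                                       seed = 1L) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  with_seed(seed, {
    nf <- spec$n_features; np <- spec$n_pairs
    features <- sprintf("miR-%04d", seq_len(nf))
    subjects <- sprintf("S%02d", seq_len(np))
    baseline <- runif(nf, 6, 12)
    subj_eff <- matrix(rnorm(nf * np, 0, spec$sigma_subject), nf, np)
    case <- baseline + subj_eff +
      matrix(rnorm(nf * np, 0, spec$sigma_noise), nf, np)
    ctrl <- baseline + subj_eff +
      matrix(rnorm(nf * np, 0, spec$sigma_noise), nf, np)
    direction <- character(0)
    if (spec$n_de > 0L) {
      n_up <- ceiling(spec$n_de / 2)
      direction <- rep(c("up", "down"), c(n_up, spec$n_de - n_up))
      eff <- ifelse(direction == "up", 1, -1) * log2(spec$planted_fc)
      case[seq_len(spec$n_de), ] <- case[seq_len(spec$n_de), ] + eff
    }
    case_ids <- paste0(subjects, "_case")
    ctrl_ids <- paste0(subjects, "_control")
    values <- cbind(case, ctrl)
    dimnames(values) <- list(features, c(case_ids, ctrl_ids))
    meta <- data.frame(sample_id = c(case_ids, ctrl_ids),
                       subject_id = rep(subjects, 2L),
                       condition = rep(c("case", "control"), each = np),
                       stringsAsFactors = FALSE)
    truth <- data.frame(feature_id = features[seq_len(spec$n_de)],
                        direction = direction,
                        fc = rep(spec$planted_fc, spec$n_de),
                        stringsAsFactors = FALSE)
    list(expression = paired_expression(values, meta, log2_scale = TRUE),
         truth = truth)
  })
}

#' Simulate a qPCR Ct table with a planted group effect
#'
#' Reference-assay Ct values have a constant mean (20 cycles); target
#' Ct values have mean 25 in controls and `25 + delta_delta_ct` in cases
#' (higher Ct = lower expression, so a positive shift plants reduced
#' expression in cases). Gaussian replicate noise of sd `sd` cycles is
#' added to every measurement; with `sd = 0` the comparative-Ct result
#' is exact.
#'
#' @param n_per_group samples per group.
#' @param delta_delta_ct planted case-minus-control shift of the
#'   target's normalized Ct, in cycles.
#' @param sd replicate noise sd in cycles (>= 0).
#' @param seed integer RNG seed.
#' @param n_replicates technical replicates per sample (default 3, the
#'   usual qPCR triplicate).
#' @return A [ct_table].
#' @export
simulate_ct_table <- function(n_per_group = 13L, delta_delta_ct = 1.6,
                              sd = 0.25, seed = 1L, n_replicates = 3L) {
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 1L)
  check_number(delta_delta_ct, "delta_delta_ct")
  check_number(sd, "sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", lower = 1L)
  with_seed(seed, {
    grp <- rep(c("case", "control"), each = n_per_group * n_replicates)
    sample_id <- c(rep(sprintf("case_%02d", seq_len(n_per_group)),
                       each = n_replicates),
                   rep(sprintf("control_%02d", seq_len(n_per_group)),
                       each = n_replicates))
    n <- length(grp)
    target <- ifelse(grp == "case", 25 + delta_delta_ct, 25) + rnorm(n, 0, sd)
    reference <- 20 + rnorm(n, 0, sd)
    ct_table(data.frame(sample_id = sample_id, group = grp,
                        target_ct = target, reference_ct = reference,
                        replicate = rep(seq_len(n_replicates),
                                        times = n / n_replicates),
                        stringsAsFactors = FALSE))
  })
}
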