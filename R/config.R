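#' Propagation configuration
#'
#' Parameters of the network-propagation step. The restart/mixing weight
#' `alpha` is the fraction of score mass that diffuses along edges each
#' iteration of random walk with restart (the walker restarts at the seed
#' distribution with probability `1 - alpha`); it is unused by the
#' one-step naive Bayes scorer.
#'
#' @param method `"naive_bayes"` (default) or `"rwr"`.
#' @param alpha diffusion weight in (0, 1).
#' @param tol L-infinity convergence tolerance (> 0).
#' @param max_iter iteration cap (>= 1).
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(method = c("naive_bayes", "rwr"),
                               alpha = 0.5, tol = 1e-8, max_iter = 1000L) {
  method <- match.arg(method)
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  check_number(tol, "tol")
  if (tol <= 0) stopf("'tol' must be > 0")
  max_iter <- check_count(max_iter, "max_iter", lower = 1L)
  structure(list(method = method, alpha = alpha, tol = tol,
                 max_iter = max_iter),
            class = "propagation_config")
}

#' Analysis configuration
#'
#' Flat configuration for the full pipeline: fold-change thresholds of
#' the differential-expression screen, the BH level, the STRING
#' confidence cutoff applied at network load, the hypergeometric
#' universe, propagation settings, and the RNG seed governing every
#' randomized operation.
#'
#' @param fc_cutoffs fold-change thresholds, each > 1. Default `c(1.5, 2)`,
#'   the two screening cutoffs of the leiomyoma miRNA screen.
#' @param fdr_alpha BH level in (0, 1).
#' @param string_confidence_min minimum raw combined score, 0-1000.
#'   Default 700 ("high confidence" in the STRING documentation).
#' @param universe hypergeometric universe size for overlap testing.
#'   Default 19000, an accepted count of annotated human protein-coding
#'   genes; always printed in overlap reports because the tail p depends
#'   on it.
#' @param propagation a [propagation_config].
#' @param rng_seed integer seed, default 1.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fc_cutoffs = c(1.5, 2.0), fdr_alpha = 0.05,
                            string_confidence_min = 700, universe = 19000,
                            propagation = propagation_config(),
                            rng_seed = 1L) {
  if (!length(fc_cutoffs) || any(!is.finite(fc_cutoffs)) || any(fc_cutoffs <= 1))
    stopf("'fc_cutoffs' must all be > 1")
  check_number(fdr_alpha, "fdr_alpha")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stopf("'fdr_alpha' must be in (0, 1)")
  check_number(string_confidence_min, "string_confidence_min", 0, 1000)
  check_count(universe, "universe", lower = 1L)
  stopifnot(inherits(propagation, "propagation_config"))
  rng_seed <- check_count(rng_seed, "rng_seed")
  structure(list(fc_cutoffs = as.numeric(sort(fc_cutoffs)),
                 fdr_alpha = fdr_alpha,
                 string_confidence_min = string_confidence_min,
                 universe = as.integer(universe),
                 propagation = propagation, rng_seed = rng_seed),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' The file is a flat document whose keys match the arguments of
#' [analysis_config()]; propagation settings nest under `propagation`.
#' Keys absent from the file keep their defaults; `overrides` (e.g. from
#' command-line flags) take precedence over file values.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param overrides named list overriding file values.
#' @return An [analysis_config].
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- utils::modifyList(raw %||% list(), overrides)
  prop <- do.call(propagation_config, raw$propagation %||% list())
  raw$propagation <- NULL
  known <- intersect(names(raw), names(formals(analysis_config)))
  unknown <- setdiff(names(raw), names(formals(analysis_config)))
  if (length(unknown)) warnf("ignoring unknown config keys: %s",
                             paste(unknown, collapse = ", "))
  do.call(analysis_config, c(raw[known], list(propagation = prop)))
}
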