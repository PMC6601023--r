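#' Construct a confidence-weighted gene network
#'
#' Undirected network over gene identifiers with per-edge confidence
#' weights in (0, 1]. Self-loops are dropped; duplicate edges (either
#' orientation) collapse to the maximum weight. STRING-style integer
#' combined scores (0-1000) map to weights as score/1000.
#'
#' @param edges data frame with columns `from`, `to`, `weight`
#'   (numeric in (0, 1]).
#' @param nodes optional character vector of node identifiers; defaults to
#'   the nodes appearing in `edges`. Extra entries become isolated nodes.
#' @param confidence_threshold the minimum raw combined score applied when
#'   the network was loaded (recorded for reporting; `NA` if none).
#' @return An object of class `gene_network`: list with `nodes` (character),
#'   `edges` (data frame `from`, `to`, `weight`, canonical orientation
#'   `from < to`) and `confidence_threshold`.
#' @export
gene_network <- function(edges, nodes = NULL, confidence_threshold = NA_real_) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    from <- toupper(trimws(as.character(edges$from)))
    to   <- toupper(trimws(as.character(edges$to)))
    w    <- as.numeric(edges$weight)
    if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
      stopf("edge weights must lie in (0, 1]")
    keep <- from != to                      # no self-loops
    from <- from[keep]; to <- to[keep]; w <- w[keep]
    a <- pmin(from, to); b <- pmax(from, to)
    key <- paste(a, b, sep = "\r")
    w <- tapply(w, key, max)                # duplicates collapse by max
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                        to = vapply(parts, `[[`, "", 2L),
                        weight = as.numeric(w),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(normalize_gene_ids(nodes %||% character()),
                         edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges,
                 confidence_threshold = confidence_threshold),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.na(x$confidence_threshold))
    cat(sprintf(" (combined score >= %s at load)", x$confidence_threshold))
  cat("\n")
  invisible(x)
}

#' Number of edges in a gene network
#' @param net a [gene_network].
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Read a STRING-style weighted edge list
#'
#' Expects whitespace/tab-separated rows of `node node combined_score`
#' with integer scores in 0-1000 (a header row naming the columns is
#' tolerated). Edges below `min_score` are dropped (inclusive threshold:
#' a score equal to `min_score` is kept), weights are stored as
#' score/1000, self-loops are removed, and symmetric duplicates merge by
#' maximum weight. Dropped-row counts are recorded in the
#' `"load_summary"` attribute so no row is silently discarded.
#'
#' @param path file path.
#' @param min_score minimum raw combined score, 0-1000. Default 700, the
#'   STRING convention for "high confidence".
#' @return A [gene_network] with attribute `"load_summary"`.
#' @export
read_edge_list <- function(path, min_score = 700) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  check_number(min_score, "min_score", 0, 1000)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # tolerate a single header line of column names
  if (length(lines) && grepl("combined_score|^\\s*node", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) {
    warnf("empty edge list: %s", path)
    net <- gene_network(NULL, confidence_threshold = min_score)
    attr(net, "load_summary") <- list(rows = 0L, kept = 0L, below_threshold = 0L,
                                      self_loops = 0L)
    return(net)
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(parts) < 3L))
    stopf("malformed edge row (need: node node score) at line %d of %s",
          which(lengths(parts) < 3L)[1], path)
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  score_chr <- vapply(parts, `[[`, "", 3L)
  if (any(!grepl("^[0-9]+$", score_chr)))
    stopf("non-integer combined score '%s' at line %d of %s",
          score_chr[!grepl("^[0-9]+$", score_chr)][1],
          which(!grepl("^[0-9]+$", score_chr))[1], path)
  score <- as.numeric(score_chr)
  if (any(score > 1000))
    stopf("combined score outside [0, 1000] in %s", path)
  self <- toupper(trimws(from)) == toupper(trimws(to))
  low <- !self & (score < min_score | score == 0)  # 0-confidence edge is no edge
  keep <- !self & !low
  net <- gene_network(data.frame(from = from[keep], to = to[keep],
                                 weight = score[keep] / 1000,
                                 stringsAsFactors = FALSE),
                      confidence_threshold = min_score)
  attr(net, "load_summary") <- list(rows = length(lines), kept = n_edges(net),
                                    below_threshold = sum(low),
                                    self_loops = sum(self))
  if (n_edges(net) == 0L) warnf("no edges at combined score >= %s in %s",
                                min_score, path)
  net
}

#' Write a network as a STRING-style edge list
#' @param net a [gene_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  df <- data.frame(node1 = net$edges$from, node2 = net$edges$to,
                   combined_score = as.integer(round(net$edges$weight * 1000)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a network at a higher confidence threshold
#'
#' Keeps edges whose raw combined score (weight x 1000) is at least
#' `min_score`. Loading at threshold a and filtering at b >= a equals
#' loading at b directly.
#'
#' @param net a [gene_network].
#' @param min_score raw combined-score threshold, 0-1000 (inclusive).
#' @return A [gene_network].
#' @export
filter_network <- function(net, min_score) {
  stopifnot(inherits(net, "gene_network"))
  check_number(min_score, "min_score", 0, 1000)
  keep <- round(net$edges$weight * 1000) >= min_score
  gene_network(net$edges[keep, , drop = FALSE], nodes = net$nodes,
               confidence_threshold = max(min_score, net$confidence_threshold,
                                          na.rm = TRUE))
}

# Sparse symmetric weighted adjacency matrix over net$nodes.
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(net$edges$weight, 2L),
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}
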