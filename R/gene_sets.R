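#' Construct a gene set
#'
#' A `gene_set` is a named collection of case-normalized gene identifiers
#' with a free-text provenance label. Identifiers are upper-cased and
#' whitespace-trimmed; duplicates after normalization collapse; empty
#' identifiers are dropped. No ortholog or alias mapping is attempted —
#' the pipeline works with human gene symbols as given.
#'
#' @param genes character vector of gene identifiers.
#' @param name short label for the set.
#' @param source free-text provenance (e.g. file path, database name).
#' @return An object of class `gene_set`: a list with elements `name`,
#'   `genes` (normalized, unique) and `source`.
#' @examples
#' gene_set(c("TP53", "ctnnb1", "tp53"), name = "example")
#' @export
gene_set <- function(genes, name = "gene_set", source = "") {
  genes <- normalize_gene_ids(genes)
  structure(list(name = as.character(name)[1],
                 genes = genes,
                 source = as.character(source)[1]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes", x$name, length(x$genes)))
  if (nzchar(x$source)) cat(sprintf(" [%s]", x$source))
  cat("\n")
  shown <- head(sort(x$genes), 8L)
  if (length(shown))
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene set from a plain list or GMT file
#'
#' Plain format: one identifier per line, blank lines skipped. GMT format:
#' tab-separated rows of name, description, members; one row is selected
#' (by `set` or the first row).
#'
#' @param path file path.
#' @param format `"auto"` (GMT iff the extension is `.gmt`), `"plain"` or
#'   `"gmt"`.
#' @param set for GMT files, the name of the row to read; default first row.
#' @param name,source overrides for the set label and provenance; defaults
#'   derive from the file.
#' @return A [gene_set].
#' @export
read_gene_set <- function(path, format = c("auto", "plain", "gmt"),
                          set = NULL, name = NULL, source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "plain"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty gene set: %s", path)

  if (format == "plain") {
    gs <- gene_set(lines,
                   name = name %||% sub("\\.[^.]*$", "", basename(path)),
                   source = source %||% path)
    if (!length(gs$genes)) stopf("empty gene set: %s", path)
    return(gs)
  }

  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 3L)
  if (length(bad))
    stopf("malformed GMT row at line %d of %s: fewer than 3 tab-separated fields",
          bad[1], path)
  set_names <- vapply(rows, `[[`, "", 1L)
  i <- if (is.null(set)) 1L else match(set, set_names)
  if (is.na(i)) stopf("GMT set '%s' not found in %s", set, path)
  gs <- gene_set(rows[[i]][-(1:2)],
                 name = name %||% set_names[i],
                 source = source %||% sprintf("%s (gmt: %s)", path, rows[[i]][2]))
  if (!length(gs$genes)) stopf("empty gene set: %s", path)
  gs
}

#' Write a gene set as a plain list file
#'
#' One identifier per line. `read_gene_set(write_gene_set(x, f))` is the
#' identity on normalized sets (up to name/source metadata).
#'
#' @param x a [gene_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(x, path) {
  stopifnot(inherits(x, "gene_set"))
  writeLines(x$genes, path)
  invisible(path)
}
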