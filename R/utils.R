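#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist hclust p.adjust phyper pt rnorm runif sd setNames
#'   t.test fisher.test rank quantile dhyper pnorm wilcox.test
#' @importFrom utils read.delim write.table combn head
NULL

# Case-normalize gene identifiers: trim whitespace, upper-case, drop empties.
# Order of first appearance is preserved; duplicates collapse.
normalize_gene_ids <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[nzchar(x)]
  unique(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar numeric check used by argument validators
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("'%s' must be an integer, got %s", name, x)
  as.integer(x)
}
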