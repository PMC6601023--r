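#' Construct a qPCR Ct table
#'
#' Threshold-cycle measurements for comparative-Ct relative
#' quantification: per row one replicate measurement of a sample, with
#' the target assay Ct and the reference (normalizer, e.g. U6 snRNA or
#' GAPDH) Ct. Ct values must be finite and in (0, 45] — the usual cycle
#' range of a 40-45 cycle run.
#'
#' @param df data frame with columns `sample_id`, `group` (`"case"` /
#'   `"control"`), `target_ct`, `reference_ct` and optionally `replicate`.
#' @return A data frame of class `ct_table`.
#' @export
ct_table <- function(df) {
  need <- c("sample_id", "group", "target_ct", "reference_ct")
  stopifnot(all(need %in% names(df)))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df <- data.frame(sample_id = as.character(df$sample_id),
                   group = as.character(df$group),
                   target_ct = as.numeric(df$target_ct),
                   reference_ct = as.numeric(df$reference_ct),
                   replicate = as.integer(df$replicate),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stopf("empty Ct table")
  if (!all(df$group %in% c("case", "control")))
    stopf("group must be 'case' or 'control'")
  ct <- c(df$target_ct, df$reference_ct)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct > 45))
    stopf("Ct values must be finite and in (0, 45]")
  structure(df, class = c("ct_table", "data.frame"))
}

#' Read a Ct table from TSV
#' @param path TSV with columns `sample_id`, `group`, `target_ct`,
#'   `reference_ct`, optionally `replicate`.
#' @return A [ct_table].
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ct_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a Ct table to TSV
#' @param x a [ct_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
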