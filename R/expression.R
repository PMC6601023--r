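#' Construct a paired expression matrix
#'
#' Expression intensities for features (e.g. miRNA probes) across samples
#' from a paired case/control design: every subject contributes exactly
#' one case sample (e.g. leiomyoma) and one control sample (e.g. matched
#' myometrium). Values may be stored on the log2 scale (the usual scale
#' for microarray intensities) or linear; downstream fold-change code
#' converts as needed.
#'
#' @param values numeric matrix, features x samples, with feature ids as
#'   row names and sample ids as column names.
#' @param metadata data frame with columns `sample_id`, `subject_id`,
#'   `condition` (values `"case"` / `"control"`).
#' @param log2_scale logical; `TRUE` if `values` are log2 intensities.
#' @return An object of class `paired_expression`: list with `values`,
#'   `metadata`, `log2_scale`, `subjects` (sorted subject ids) and index
#'   vectors `case_cols`, `control_cols` aligned to `subjects`.
#' @export
paired_expression <- function(values, metadata, log2_scale = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' needs feature row names and sample column names")
  stopifnot(all(c("sample_id", "subject_id", "condition") %in% names(metadata)))
  metadata <- data.frame(sample_id = as.character(metadata$sample_id),
                         subject_id = as.character(metadata$subject_id),
                         condition = as.character(metadata$condition),
                         stringsAsFactors = FALSE)
  if (any(!nzchar(metadata$subject_id)))
    stopf("missing subject labels in metadata")
  if (!all(metadata$condition %in% c("case", "control")))
    stopf("condition must be 'case' or 'control'; got: %s",
          paste(setdiff(unique(metadata$condition), c("case", "control")),
                collapse = ", "))
  missing_meta <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing_meta))
    stopf("samples in values but not metadata: %s",
          paste(missing_meta, collapse = ", "))
  missing_val <- setdiff(metadata$sample_id, colnames(values))
  if (length(missing_val))
    stopf("samples in metadata but not values: %s",
          paste(missing_val, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stopf("duplicated sample ids in metadata")

  # each subject: exactly one case and one control
  tab <- table(metadata$subject_id, factor(metadata$condition,
                                           levels = c("case", "control")))
  bad <- rownames(tab)[tab[, "case"] != 1L | tab[, "control"] != 1L]
  if (length(bad))
    stopf("pairing error: subjects without exactly one case and one control: %s",
          paste(sort(bad), collapse = ", "))

  subjects <- sort(unique(metadata$subject_id))
  case_ids <- metadata$sample_id[match(paste(subjects, "case"),
                                       paste(metadata$subject_id, metadata$condition))]
  ctrl_ids <- metadata$sample_id[match(paste(subjects, "control"),
                                       paste(metadata$subject_id, metadata$condition))]
  # reorder columns so pairs align: per subject, case then control
  ord <- as.vector(rbind(case_ids, ctrl_ids))
  values <- values[, ord, drop = FALSE]
  metadata <- metadata[match(ord, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata,
                 log2_scale = isTRUE(log2_scale), subjects = subjects,
                 case_cols = match(case_ids, colnames(values)),
                 control_cols = match(ctrl_ids, colnames(values))),
            class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat(sprintf("<paired_expression> %d features x %d samples (%d subject pairs, %s scale)\n",
              nrow(x$values), ncol(x$values), length(x$subjects),
              if (x$log2_scale) "log2" else "linear"))
  invisible(x)
}

#' @export
dim.paired_expression <- function(x) dim(x$values)

#' Number of subject pairs
#' @param x a [paired_expression].
#' @return integer pair count.
#' @export
n_pairs <- function(x) length(x$subjects)

#' Read a paired expression matrix from TSV files
#'
#' @param path_values TSV of intensities, features in rows (first column =
#'   feature id), samples in columns.
#' @param path_metadata TSV with columns `sample_id`, `subject_id`,
#'   `condition`.
#' @param log2_scale logical; scale of the stored values.
#' @return A [paired_expression].
#' @export
read_expression <- function(path_values, path_metadata, log2_scale = TRUE) {
  for (p in c(path_values, path_metadata))
    if (!file.exists(p)) stopf("file not found: %s", p)
  vals <- read.delim(path_values, row.names = 1L, check.names = FALSE)
  meta <- read.delim(path_metadata, stringsAsFactors = FALSE)
  paired_expression(as.matrix(vals), meta, log2_scale = log2_scale)
}

#' Write a paired expression matrix to TSV files
#' @param x a [paired_expression].
#' @param path_values,path_metadata output paths.
#' @return `c(path_values, path_metadata)`, invisibly.
#' @export
write_expression <- function(x, path_values, path_metadata) {
  stopifnot(inherits(x, "paired_expression"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path_values, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$metadata, path_metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path_values, path_metadata))
}

# log2 case-minus-control differences, features x subjects
paired_log2_diff <- function(x) {
  v <- x$values
  if (!x$log2_scale) {
    if (any(v <= 0))
      stopf("linear intensities must be positive to take log2")
    v <- log2(v)
  }
  d <- v[, x$case_cols, drop = FALSE] - v[, x$control_cols, drop = FALSE]
  colnames(d) <- x$subjects
  d
}
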