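#' Read a feature abundance table
#'
#' Tables are TSV with features as rows and injections as columns; the first
#' column holds feature identifiers. Empty cells and "NA" are missing.
#'
#' @param path TSV file path.
#' @return Numeric matrix (features x injections) with dimnames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  assert_feature_table(m)
  m
}

#' Write a feature abundance table as TSV
#'
#' @param table Feature x injection matrix.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read injection metadata
#'
#' @param path CSV with at least the columns injection_id, sample_id,
#'   subject_id, type, batch, injection_order, replicate_group,
#'   dilution_level; GA columns (ga_weeks, ga_delivery, delivery_group) are
#'   required for modelling stages.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("injection_id", "sample_id", "type", "batch",
                "injection_order")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  meta
}

# internal sanity checks for the feature-table contract
assert_feature_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("feature table must be a numeric matrix (features x injections)")
  if (is.null(rownames(table)) || anyDuplicated(rownames(table)))
    stop("feature table needs unique feature ids as rownames")
  if (is.null(colnames(table)) || anyDuplicated(colnames(table)))
    stop("feature table needs unique injection ids as colnames")
  if (any(table < 0, na.rm = TRUE))
    stop("feature table contains negative abundances")
  invisible(table)
}

# align metadata rows to table columns; errors on mismatch
align_meta <- function(table, meta) {
  idx <- match(colnames(table), meta$injection_id)
  if (anyNA(idx))
    stop("injections absent from metadata: ",
         paste(utils::head(colnames(table)[is.na(idx)], 5), collapse = ", "))
  meta[idx, , drop = FALSE]
}
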