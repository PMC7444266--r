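# Plain-text readers and writers for the pipeline's standard formats. All
# numeric output uses 15 significant digits; readers accept Windows line
# endings and require unique ids.

#' Write / read an expression matrix TSV
#'
#' Rows are genes, columns samples, first column `gene`; tab-separated,
#' header row, `.` decimal.
#'
#' @param expr numeric genes x samples matrix.
#' @param file path.
#' @return `read_expression_tsv` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_expression_tsv <- function(expr, file) {
  df <- data.frame(gene = rownames(expr),
                   apply(expr, 2, fmt_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "gene", "first column must be 'gene'")
  dup <- duplicated(df$gene)
  stop_if(any(dup), "duplicate gene id(s): ",
          paste(utils::head(df$gene[dup]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (is.numeric(vals[[j]])) next
    conv <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(conv) & !is.na(vals[[j]]))
    stop_if(length(bad) > 0, "non-numeric cell at row ", bad[1],
            ", column ", names(vals)[j])
    vals[[j]] <- conv
  }
  m <- as.matrix(vals)
  stop_if(anyNA(m), "missing value(s) in matrix")
  rownames(m) <- df$gene
  m
}

#' Write / read sample metadata TSV
#'
#' Columns `sample`, `cell_line`, `replicate`.
#'
#' @param meta data.frame.
#' @param file path.
#' @export
write_sample_metadata <- function(meta, file) {
  utils::write.table(meta, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stop_if(!all(c("sample", "cell_line") %in% names(df)),
          "metadata needs 'sample' and 'cell_line' columns")
  dup <- duplicated(df$sample)
  stop_if(any(dup), "duplicate sample id(s): ",
          paste(df$sample[dup], collapse = ", "))
  df$cell_line <- factor(df$cell_line, levels = cell_lines())
  df
}

#' Write / read a survival cohort TSV
#'
#' Patient rows with `patient`, `time`, `event`, covariates and gene columns.
#'
#' @param cohort data.frame.
#' @param file path.
#' @export
write_cohort_tsv <- function(cohort, file) {
  out <- cohort
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  check_cohort(df)
  dup <- duplicated(df$patient)
  stop_if(any(dup), "duplicate patient id(s): ",
          paste(utils::head(df$patient[dup]), collapse = ", "))
  df
}

#' Write a PTM area table CSV
#'
#' Canonical layout: `histone`, `start`, `end`, `modifications`, one area
#' column per sample. Read back with [parse_ptm_table()].
#'
#' @param ptm data.frame in canonical layout.
#' @param file path.
#' @export
write_ptm_csv <- function(ptm, file) {
  out <- ptm
  num <- vapply(out, is.double, TRUE)
  for (j in which(num)) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}
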