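# TSV dialect shared by all modules: matrices are written with the probe
# identifier as the first column ("probe_id") and one column per sample;
# tables are plain tab-separated files with a header.

#' Write a probe x sample matrix as TSV
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe x sample matrix from TSV
#' @param path file written by [write_matrix_tsv()].
#' @return numeric matrix with probe rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output file.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path file.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a QC report as TSV tables plus a JSON summary
#'
#' Writes each removal table of a `QCReport` (from [pfilter()] or
#' [pc_outlier_removal()]) as `<prefix>_<name>.tsv` and a machine-readable
#' summary of removal counts as `<prefix>_summary.json`.
#'
#' @param report a `QCReport`.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the paths written.
#' @export
write_qc_report <- function(report, prefix) {
  stopifnot(inherits(report, "QCReport"))
  paths <- character(0)
  summary <- list()
  for (nm in c("samples_removed", "probes_removed")) {
    if (!is.null(report[[nm]])) {
      p <- paste0(prefix, "_", nm, ".tsv")
      write_table_tsv(report[[nm]], p)
      paths <- c(paths, p)
      summary[[paste0("n_", nm)]] <- nrow(report[[nm]])
    }
  }
  jp <- paste0(prefix, "_summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE)
  invisible(c(paths, jp))
}
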