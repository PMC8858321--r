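#' Write a count table as TSV
#'
#' First column `sgrna_id`, then one column per sample named
#' `{arm}_{timepoint}_rep{k}`.
#'
#' @param counts a [count_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(sgrna_id = rownames(counts), unclass(counts)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#'
#' Sample metadata (arm, timepoint, replicate) is reconstructed from the
#' `{arm}_{timepoint}_rep{k}` column names.
#'
#' @param path TSV path written by [write_counts()].
#' @return a [count_table].
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sgrna_id
  parts <- regmatches(colnames(m),
                      regexec("^([a-z]+)_(day[0-9]+)_rep([0-9]+)$", colnames(m)))
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    stop("unparseable sample column name: ", colnames(m)[bad[1L]])
  }
  meta <- data.frame(sample = colnames(m),
                     arm = vapply(parts, `[`, "", 2L),
                     timepoint = vapply(parts, `[`, "", 3L),
                     replicate = as.integer(vapply(parts, `[`, "", 4L)),
                     stringsAsFactors = FALSE)
  count_table(m, meta)
}

#' Write an enrichment table as TSV
#'
#' @param enrichment a `sgrna_enrichment` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(as.data.frame(enrichment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-hit table as TSV
#'
#' @param hits a `gene_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dose panel as CSV
#'
#' Columns `cell_line,drug,dose_uM,replicate,absorbance`.
#'
#' @param path CSV path.
#' @return [read_panel_csv()]: a `dose_panel` data frame.
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "dose_uM", "replicate", "absorbance")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("panel CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  structure(df[, need], class = c("dose_panel", "data.frame"))
}

#' @rdname read_panel_csv
#' @param panel a `dose_panel` data frame.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
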