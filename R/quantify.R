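#' Count library guides in a FASTQ file
#'
#' Assigns each read to a library sgRNA by comparing the 20-mer at a fixed
#' offset against the library spacers. By default the match must be exact;
#' with `allow_mismatch = 1` an unmatched window is assigned to a spacer at
#' Hamming distance 1 only when that assignment is unique (ambiguous reads
#' stay unassigned, never double-counted). Reads shorter than `offset + 20`
#' are unassigned.
#'
#' @param fastq path to a FASTQ file (plain or gzip).
#' @param lib an [sgrna_library]; its spacers must be unique (enforced by the
#'   class).
#' @param offset 0-based position of the spacer within the read, or `"auto"`
#'   to estimate it as the offset maximising exact matches over the first
#'   1,000 reads.
#' @param allow_mismatch 0 (exact) or 1 (unique single-mismatch rescue).
#' @return a `read_counts` list: `counts` (named integer vector over the
#'   library), `n_reads_total`, `n_reads_unassigned`, `offset`.
#' @export
count_reads <- function(fastq, lib, offset = "auto", allow_mismatch = 0) {
  if (!file.exists(fastq)) stop("FASTQ file not found: ", fastq)
  check_fastq_structure(fastq)
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  n_total <- length(reads)
  if (identical(offset, "auto")) {
    offset <- detect_offset(reads, lib$spacer)
  }
  offset <- as.integer(offset)
  if (offset < 0L) stop("offset must be nonnegative")

  win <- substr(reads, offset + 1L, offset + 20L)
  idx <- match(win, lib$spacer)
  idx[nchar(win) < 20L] <- NA_integer_

  if (allow_mismatch >= 1L) {
    un <- which(is.na(idx) & nchar(win) == 20L)
    if (length(un) > 0L) idx[un] <- match_one_mismatch(win[un], lib$spacer)
  }

  counts <- tabulate(idx, nbins = nrow(lib))
  names(counts) <- lib$sgrna_id
  structure(list(counts = counts, n_reads_total = n_total,
                 n_reads_unassigned = n_total - sum(counts),
                 offset = offset),
            class = "read_counts")
}

check_fastq_structure <- function(fastq) {
  n_lines <- length(readLines(fastq, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ record ", n_lines %/% 4L + 1L, " in ", fastq)
  }
  invisible(TRUE)
}

detect_offset <- function(reads, spacers, n_probe = 1000L) {
  probe <- head(reads, n_probe)
  if (length(probe) == 0L) return(0L)
  max_off <- max(0L, min(nchar(probe)) - 20L)
  hits <- vapply(0L:max_off, function(o) {
    sum(!is.na(match(substr(probe, o + 1L, o + 20L), spacers)))
  }, integer(1))
  (0L:max_off)[which.max(hits)]
}

# Unique Hamming-distance-1 assignment; ambiguous windows -> NA.
match_one_mismatch <- function(windows, spacers) {
  bases <- c("A", "C", "G", "T")
  vapply(windows, function(w) {
    hits <- integer(0)
    for (pos in 1:20) {
      for (b in bases) {
        if (substr(w, pos, pos) == b) next
        v <- w
        substr(v, pos, pos) <- b
        m <- match(v, spacers)
        if (!is.na(m)) hits <- c(hits, m)
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) hits else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Library-representation coverage QC
#'
#' Coverage is the fraction of library guides detected at or above a read
#' floor in a sample; in a well-executed genome-wide screen the day-0 baseline
#' is expected to exceed roughly 88%.
#'
#' @param counts per-sgRNA counts: a `read_counts` object from
#'   [count_reads()], or a numeric vector aligned to the library.
#' @param min_reads minimum reads for a guide to count as detected
#'   (default 1).
#' @return a `coverage_report` list: `n_sgrna`, `n_detected`, `coverage`,
#'   `n_reads_total`, `n_reads_unassigned`, `counts`.
#' @export
coverage_qc <- function(counts, min_reads = 1) {
  if (inherits(counts, "read_counts")) {
    vec <- counts$counts
    total <- counts$n_reads_total
    unassigned <- counts$n_reads_unassigned
  } else {
    vec <- counts
    total <- sum(vec)
    unassigned <- 0L
  }
  if (length(vec) == 0L) stop("empty library: no guides to assess")
  n_det <- sum(vec >= min_reads)
  structure(list(n_sgrna = length(vec), n_detected = n_det,
                 coverage = n_det / length(vec),
                 n_reads_total = total, n_reads_unassigned = unassigned,
                 counts = vec),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage: %.1f%% (%d / %d sgRNAs detected); %d reads, %d unassigned\n",
              100 * x$coverage, x$n_detected, x$n_sgrna,
              x$n_reads_total, x$n_reads_unassigned))
  invisible(x)
}

#' Write a coverage report as JSON
#'
#' @param report a `coverage_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_json <- function(report, path) {
  jsonlite::write_json(report[c("n_sgrna", "n_detected", "coverage",
                                "n_reads_total", "n_reads_unassigned")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
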