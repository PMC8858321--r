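#' Read a GMT gene-set collection
#'
#' Standard GMT: one tab-separated line per set -- term, description, then
#' gene symbols. Genes are deduplicated within a set.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: named list of character vectors, with a
#'   `source` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated ",
           "fields, got ", length(fields))
    }
    term <- fields[1L]
    if (term %in% names(sets)) stop("duplicate term '", term, "' at line ", i)
    sets[[term]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (term -> gene symbols).
#' @param source free-text provenance label.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (length(sets) > 0L) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stop("set terms must be unique and named")
    }
    if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
  }
  structure(lapply(sets, unique), source = source,
            class = "gene_set_collection")
}

#' Hypergeometric overrepresentation of a hit list
#'
#' For each gene set, tests whether the hit list contains more of the set's
#' genes than expected from drawing `n` genes at random from the universe:
#' upper-tail `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)` with
#' `N = |universe|`, `K = |set in universe|`, `k = |hits in set|`,
#' `n = |hits|`. p-values are BH-adjusted across the tested terms. The
#' natural universe for a pooled screen is the library's targeting genes, not
#' the genome.
#'
#' @param hits character vector of hit gene symbols; must lie in `universe`.
#' @param universe character vector of all testable gene symbols.
#' @param sets a `gene_set_collection` (sets are intersected with the
#'   universe; terms with no universe gene are dropped).
#' @return an `ora_result` data frame sorted by ascending `p`, with columns
#'   `term`, `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
overrepresentation <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    stop("hit gene(s) not in universe: ", paste(outside, collapse = ", "))
  }
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(sets), function(term) {
    set_u <- intersect(sets[[term]], universe)
    K <- length(set_u)
    if (K == 0L) return(NULL)
    k <- length(intersect(hits, set_u))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  structure(out, class = c("ora_result", "data.frame"))
}

#' @export
print.ora_result <- function(x, n = 10L, ...) {
  cat("overrepresentation: ", nrow(x), " gene sets tested, ",
      sum(x$q < 0.05), " with q < 0.05\n", sep = "")
  print(head(as.data.frame(x), n))
  invisible(x)
}
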