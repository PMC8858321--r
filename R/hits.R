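#' Two-criteria gene-level hit calling
#'
#' A guide passes iff its enrichment p-value is below `alpha` and its log2
#' fold change is at least `fc_threshold` (inclusive); a gene is a hit iff at
#' least `min_sgrnas` of its guides pass. Non-targeting controls are excluded
#' from gene calling. An advisory BH-adjusted per-gene one-sample t p-value
#' over each gene's guide fold changes is reported alongside; no gene-level
#' multiple-testing correction enters the hit decision itself.
#'
#' @param enrichment a `sgrna_enrichment` table from [enrich_screen()], or any
#'   data frame with columns `sgrna_id`, `gene`, `log2fc`, `p_value`.
#' @param fc_threshold minimum log2 fold change (inclusive).
#' @param alpha per-guide significance level (strict).
#' @param min_sgrnas minimum number of passing guides per hit gene.
#' @return a `gene_hits` data frame (one row per targeting gene, sorted by
#'   `n_sgrna_passing` then `median_fc`, descending) with columns `gene`,
#'   `n_sgrna_total`, `n_sgrna_passing`, `median_fc`, `max_fc`, `gene_p_bh`,
#'   `is_hit`.
#' @examples
#' enr <- data.frame(sgrna_id = paste0("sg", 1:4), gene = "G1",
#'                   log2fc = c(2.5, 2.2, 3.0, 0.1),
#'                   p_value = c(.01, .02, .001, .8))
#' call_hits(enr)
#' @export
call_hits <- function(enrichment, fc_threshold = 2, alpha = 0.05,
                      min_sgrnas = 3) {
  if (fc_threshold <= 0 || alpha <= 0 || min_sgrnas <= 0) {
    stop("thresholds must be positive")
  }
  e <- enrichment[enrichment$gene != CONTROL_LABEL, , drop = FALSE]
  if (nrow(e) == 0L) stop("no targeting guides in enrichment table")
  pass <- e$p_value < alpha & e$log2fc >= fc_threshold
  genes <- unique(e$gene)
  gidx <- match(e$gene, genes)
  gfac <- factor(gidx, levels = seq_along(genes))
  n_total <- tabulate(gidx, length(genes))
  n_pass <- as.integer(rowsum(as.numeric(pass), gidx)[, 1L])
  med_fc <- vapply(split(e$log2fc, gfac), median, numeric(1))
  max_fc <- vapply(split(e$log2fc, gfac), max, numeric(1))
  gene_p <- gene_t_pvalues(e$log2fc, gidx, length(genes))
  out <- data.frame(gene = genes, n_sgrna_total = n_total,
                    n_sgrna_passing = n_pass, median_fc = med_fc,
                    max_fc = max_fc,
                    gene_p_bh = p.adjust(gene_p, method = "BH"),
                    is_hit = n_pass >= min_sgrnas,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sgrna_passing, -out$median_fc), ]
  rownames(out) <- NULL
  structure(out, fc_threshold = fc_threshold, alpha = alpha,
            min_sgrnas = min_sgrnas,
            class = c("gene_hits", "data.frame"))
}

# Vectorised two-sided one-sample t over gene groups; agrees with
# gene_group_test()'s t.test (pinned in the suite). Degenerate groups follow
# the same rules: all-zero -> 1, zero variance nonzero -> 0, n < 2 -> NA.
gene_t_pvalues <- function(fc, gidx, n_groups) {
  n <- tabulate(gidx, n_groups)
  s1 <- rowsum(fc, gidx)[, 1L]
  s2 <- rowsum(fc^2, gidx)[, 1L]
  mean_g <- s1 / n
  var_g <- pmax(0, (s2 - n * mean_g^2) / pmax(1, n - 1))
  p <- rep(NA_real_, n_groups)
  ok <- n >= 2L & var_g > 0
  tt <- mean_g[ok] / sqrt(var_g[ok] / n[ok])
  p[ok] <- 2 * pt(-abs(tt), n[ok] - 1L)
  degen <- n >= 2L & var_g == 0
  p[degen] <- ifelse(abs(mean_g[degen]) < .Machine$double.eps^0.5, 1, 0)
  p
}

#' @export
print.gene_hits <- function(x, n = 10L, ...) {
  cat("gene-level hit calls: ", sum(x$is_hit), " hits / ", nrow(x),
      " genes (log2FC >= ", attr(x, "fc_threshold"), ", p < ",
      attr(x, "alpha"), ", >= ", attr(x, "min_sgrnas"),
      " sgRNAs/gene)\n", sep = "")
  print(head(as.data.frame(x), n))
  invisible(x)
}

#' Hit genes of a `gene_hits` table
#'
#' @param hits a `gene_hits` data frame.
#' @return character vector of hit gene symbols.
#' @export
hit_genes <- function(hits) hits$gene[hits$is_hit]

#' Number of a gene's guides above a fold-change threshold
#'
#' The per-gene guide-enrichment count reported for candidate genes (e.g. how
#' many of a coagulation-factor gene's six library guides exceed 2 log2
#' fold change).
#'
#' @param gene gene symbol present in the enrichment table.
#' @param enrichment a `sgrna_enrichment` table.
#' @param fc_threshold log2 fold-change threshold (inclusive).
#' @return integer count.
#' @export
enriched_sgrna_count <- function(gene, enrichment, fc_threshold = 2) {
  rows <- enrichment$gene == gene
  if (!any(rows)) stop("unknown gene: ", gene)
  sum(enrichment$log2fc[rows] >= fc_threshold)
}
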