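#' Reads-per-million normalisation
#'
#' Scales each sample (column) to one million total reads. For fixed-length
#' guide cassettes the conventional RPKM differs from RPM only by a constant
#' that cancels in fold changes, so RPM is the working unit throughout; the
#' log-scale report `log2(RPM + pseudocount)` is exposed as "transformed
#' RPKM" in the enrichment table.
#'
#' @param counts numeric matrix (guides x samples) or a single sample vector.
#' @return object of the same shape with each sample summing to 1e6.
#' @export
normalize_rpm <- function(counts) {
  if (is.null(dim(counts))) {
    tot <- sum(counts)
    if (tot <= 0) stop("all-zero sample: cannot normalise")
    return(counts / tot * 1e6)
  }
  m <- as.matrix(counts)
  tots <- colSums(m)
  bad <- which(tots <= 0)
  if (length(bad) > 0L) {
    nm <- colnames(m)[bad[1L]]
    stop("all-zero sample '", if (is.null(nm)) bad[1L] else nm,
         "': cannot normalise")
  }
  sweep(m, 2L, tots, "/") * 1e6
}

#' Pseudocounted log2 fold change
#'
#' @param rpm_t14,rpm_t0 nonnegative normalised abundances.
#' @param pseudocount additive guard against zeros (default 1 RPM).
#' @return `log2((rpm_t14 + pseudocount) / (rpm_t0 + pseudocount))`.
#' @export
log2fc <- function(rpm_t14, rpm_t0, pseudocount = 1) {
  if (any(rpm_t14 < 0) || any(rpm_t0 < 0)) stop("abundances must be >= 0")
  log2((rpm_t14 + pseudocount) / (rpm_t0 + pseudocount))
}

#' One-sided per-sgRNA enrichment p-values
#'
#' Three nulls for the same question -- is this guide's log2 fold change
#' larger than chance?
#'
#' * `robust_z`: z-score of the fold change against the bulk of the library
#'   (median / 1.4826 x MAD), upper normal tail. Robust because true hits are
#'   a small minority.
#' * `control_null`: empirical upper-tail probability against the
#'   non-targeting-control fold-change distribution, with add-one smoothing:
#'   `p = (#{controls >= fc} + 1) / (n_controls + 1)`.
#' * `permutation`: timepoint labels of the replicate samples are permuted in
#'   every balanced way, fold changes recomputed, and the permuted values of
#'   all guides pooled into one empirical null (pooling across guides gives
#'   the resolution that a handful of per-guide permutations cannot).
#'
#' @param fc numeric vector of per-guide log2 fold changes.
#' @param method `"robust_z"`, `"control_null"` or `"permutation"`.
#' @param control_fc fold changes of non-targeting controls
#'   (`control_null` only).
#' @param counts count matrix restricted to the replicate samples
#'   (`permutation` only).
#' @param t0_cols,t14_cols column names of the day-0 / day-14 samples in
#'   `counts` (`permutation` only).
#' @param pseudocount passed to [log2fc()] for permuted fold changes.
#' @return numeric vector of one-sided (enrichment) p-values.
#' @export
sgrna_pvalues <- function(fc, method = c("robust_z", "control_null",
                                         "permutation"),
                          control_fc = NULL, counts = NULL,
                          t0_cols = NULL, t14_cols = NULL, pseudocount = 1) {
  method <- match.arg(method)
  switch(method,
    robust_z = {
      if (length(fc) < 50L) stop("robust_z needs at least 50 sgRNAs")
      s <- mad(fc)
      if (s == 0) stop("degenerate fold-change distribution: MAD is zero")
      pnorm((fc - median(fc)) / s, lower.tail = FALSE)
    },
    control_null = {
      if (is.null(control_fc) || length(control_fc) == 0L) {
        stop("control_null requires non-targeting control fold changes")
      }
      empirical_upper_p(fc, control_fc)
    },
    permutation = {
      if (is.null(counts) || is.null(t0_cols) || is.null(t14_cols)) {
        stop("permutation requires counts, t0_cols and t14_cols")
      }
      pool <- permutation_fc_pool(counts, t0_cols, t14_cols, pseudocount)
      empirical_upper_p(fc, pool)
    })
}

# (#{null >= x} + 1) / (n + 1), vectorised over x via the sorted null.
empirical_upper_p <- function(x, null) {
  s <- sort(null)
  n_ge <- length(s) - findInterval(x, s, left.open = TRUE)
  (n_ge + 1) / (length(s) + 1)
}

permutation_fc_pool <- function(counts, t0_cols, t14_cols, pseudocount,
                                max_perm = 100L) {
  cols <- c(t0_cols, t14_cols)
  rpm <- normalize_rpm(counts[, cols, drop = FALSE])
  k <- length(t0_cols)
  combos <- utils::combn(length(cols), k, simplify = FALSE)
  if (length(combos) > max_perm) combos <- combos[seq_len(max_perm)]
  unlist(lapply(combos, function(i0) {
    log2fc(rowMeans(rpm[, -i0, drop = FALSE]),
           rowMeans(rpm[, i0, drop = FALSE]), pseudocount)
  }), use.names = FALSE)
}

#' Per-gene one-sample summary tests of guide enrichment
#'
#' Tests a gene's guide log2 fold changes against zero with a one-sample
#' t-test and a Wilcoxon signed-rank test (both two-sided), the conventional
#' violin-plot companion statistics for a candidate gene's guides.
#'
#' Degenerate inputs are resolved deterministically: all values exactly zero
#' gives p = 1 for both tests (no evidence either way); nonzero values with
#' zero variance give t p = 0 (the t statistic diverges).
#'
#' @param fc numeric vector of one gene's guide log2 fold changes.
#' @return named vector `c(t_p = , wilcoxon_p = )`.
#' @export
gene_group_test <- function(fc) {
  if (length(fc) < 1L) stop("need at least one value")
  if (all(fc == 0)) return(c(t_p = 1, wilcoxon_p = 1))
  t_p <- if (length(fc) < 2L) {
    NA_real_
  } else if (stats::sd(fc) == 0) {
    0
  } else {
    t.test(fc, mu = 0)$p.value
  }
  w_p <- suppressWarnings(wilcox.test(fc, mu = 0)$p.value)
  c(t_p = t_p, wilcoxon_p = w_p)
}

#' Per-sgRNA enrichment between day 0 and day 14
#'
#' Normalises the selected samples to RPM, averages replicates within
#' timepoint, computes pseudocounted log2 fold changes and one-sided
#' enrichment p-values, and flags each guide against the fold-change and
#' significance thresholds. Per-replicate fold changes are kept alongside
#' when the timepoints pair by replicate index.
#'
#' @param counts a [count_table] (or plain matrix with named columns).
#' @param lib the [sgrna_library] the rows are aligned to.
#' @param t0_cols,t14_cols sample (column) names for baseline and endpoint;
#'   default: the drug arm's `day0` / `day14` samples from the metadata.
#' @param method p-value method, see [sgrna_pvalues()].
#' @param pseudocount fold-change pseudocount, in RPM.
#' @param fc_threshold log2 fold-change threshold for `passes_fc`
#'   (inclusive).
#' @param alpha significance level for `passes_p` (strict).
#' @return a `sgrna_enrichment` data frame sorted by descending `log2fc`,
#'   with columns `sgrna_id`, `gene`, `rpm_t0`, `rpm_t14`, `log2fc`,
#'   `transformed_rpkm_t0`, `transformed_rpkm_t14`, per-replicate
#'   `log2fc_rep*`, `p_value`, `passes_fc`, `passes_p`, and the thresholds as
#'   attributes.
#' @export
enrich_screen <- function(counts, lib, t0_cols = NULL, t14_cols = NULL,
                          method = "robust_z", pseudocount = 1,
                          fc_threshold = 2, alpha = 0.05) {
  meta <- sample_meta(counts)
  if (is.null(t0_cols) || is.null(t14_cols)) {
    if (is.null(meta)) stop("no sample metadata; supply t0_cols and t14_cols")
    arm <- if ("drug" %in% meta$arm) "drug" else meta$arm[1L]
    t0_cols <- meta$sample[meta$arm == arm & meta$timepoint == "day0"]
    t14_cols <- meta$sample[meta$arm == arm & meta$timepoint == "day14"]
  }
  if (length(t0_cols) == 0L || length(t14_cols) == 0L) {
    stop("could not locate day-0 / day-14 samples")
  }
  m <- unclass(counts)
  attr(m, "samples") <- NULL
  rpm <- normalize_rpm(m[, c(t0_cols, t14_cols), drop = FALSE])
  rpm_t0 <- rowMeans(rpm[, t0_cols, drop = FALSE])
  rpm_t14 <- rowMeans(rpm[, t14_cols, drop = FALSE])
  fc <- log2fc(rpm_t14, rpm_t0, pseudocount)

  p <- switch(method,
    robust_z = sgrna_pvalues(fc, "robust_z"),
    control_null = sgrna_pvalues(
      fc, "control_null",
      control_fc = fc[lib$klass == "control"]),
    permutation = sgrna_pvalues(
      fc, "permutation", counts = m, t0_cols = t0_cols, t14_cols = t14_cols,
      pseudocount = pseudocount),
    stop("unknown p-value method: ", method))

  out <- data.frame(sgrna_id = lib$sgrna_id, gene = lib$gene,
                    rpm_t0 = rpm_t0, rpm_t14 = rpm_t14, log2fc = fc,
                    transformed_rpkm_t0 = log2(rpm_t0 + pseudocount),
                    transformed_rpkm_t14 = log2(rpm_t14 + pseudocount),
                    stringsAsFactors = FALSE)
  if (length(t0_cols) == length(t14_cols) && length(t0_cols) > 1L) {
    for (k in seq_along(t0_cols)) {
      out[[paste0("log2fc_rep", k)]] <-
        log2fc(rpm[, t14_cols[k]], rpm[, t0_cols[k]], pseudocount)
    }
  }
  out$p_value <- p
  out$passes_fc <- fc >= fc_threshold
  out$passes_p <- p < alpha
  out <- out[order(-out$log2fc), ]
  rownames(out) <- NULL
  structure(out, fc_threshold = fc_threshold, alpha = alpha,
            pseudocount = pseudocount, method = method,
            class = c("sgrna_enrichment", "data.frame"))
}

#' @export
print.sgrna_enrichment <- function(x, n = 6L, ...) {
  cat("per-sgRNA enrichment (", nrow(x), " guides, method ",
      attr(x, "method"), ")\n", sep = "")
  cat(sum(x$passes_fc & x$passes_p), "guides pass log2FC >=",
      attr(x, "fc_threshold"), "and p <", attr(x, "alpha"), "\n")
  print(head(as.data.frame(x), n))
  invisible(x)
}
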