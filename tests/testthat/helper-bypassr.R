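# Small-library builders and independent oracles shared across the suite.

tiny_lib <- function(n_genes = 5, per_gene_range = c(4, 4), n_controls = 2,
                     seed = 7) {
  generate_library(n_genes = n_genes, per_gene_range = per_gene_range,
                   n_controls = n_controls, seed = seed)
}

# A simulated null screen (no bypass genes, matched rates) and its enrichment.
null_screen <- function(n_genes = 200, n_controls = 50, seed = 1,
                        method = "robust_z", ...) {
  lib <- generate_library(n_genes = n_genes, n_controls = n_controls,
                          seed = seed)
  sim <- simulate_screen(lib, screen_truth(r_untreated = 0.05),
                         sim_config(seed = seed, include_vehicle = FALSE, ...))
  list(lib = lib, sim = sim,
       enr = enrich_screen(sim$counts, lib, method = method))
}

# Brute-force re-implementation of the two-criteria hit rule: loop over genes
# and count passing guides. Deliberately naive and independent of call_hits.
brute_force_hits <- function(enr, fc_threshold, alpha, min_sgrnas) {
  genes <- unique(enr$gene[enr$gene != "NonTargeting"])
  hits <- character(0)
  for (g in genes) {
    rows <- enr[enr$gene == g, ]
    n_pass <- 0
    for (i in seq_len(nrow(rows))) {
      if (rows$p_value[i] < alpha && rows$log2fc[i] >= fc_threshold) {
        n_pass <- n_pass + 1
      }
    }
    if (n_pass >= min_sgrnas) hits <- c(hits, g)
  }
  sort(hits)
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of size N and count draws overlapping the set by >= k.
exhaustive_hyper_p <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(universe, n, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, inset)) >= k, logical(1)))
}
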