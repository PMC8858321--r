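#' Default pipeline configuration
#'
#' All tunables of the screen pipeline in one list; [run_pipeline()] merges
#' user overrides onto these defaults and echoes the merged configuration
#' into every stage log.
#'
#' @param ... named overrides of the defaults.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_genes = 19050L, per_gene_range = c(5L, 6L), n_controls = 1000L,
    bypass_genes = bypass_gene_set(), efficacy = 0.95,
    r_bypass = 0.8, r_arrest = 0.05, r_untreated = 1.0, duration_days = 14,
    plasmid_skew_sigma = 1, depth_per_sgrna = 200, n_replicates = 2L,
    n_cells = NULL, include_vehicle = FALSE,
    method = "robust_z", pseudocount = 1,
    fc_threshold = 2, alpha = 0.05, min_sgrnas = 3L,
    min_reads = 1L, min_drugs = 2L,
    library = NULL, counts = NULL, enrichment = NULL, hits = NULL,
    gmt = NULL, panel = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  defaults
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing input for stage '", what, "': ",
         if (is.null(path)) "no path configured" else path)
  }
  path
}

write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

stage_log <- function(out_dir, stage, cfg, seed, inputs, headline) {
  log <- list(stage = stage, seed = seed,
              config = cfg[!vapply(cfg, is.null, logical(1))],
              input_md5 = as.list(tools::md5sum(inputs)),
              headline = headline,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_atomic(function(p) jsonlite::write_json(log, p, auto_unbox = TRUE,
                                                digits = NA),
               file.path(out_dir, paste0("log_", stage, ".json")))
}

# Deterministic per-stage seed substreams fanned out from the run seed, so a
# stage rerun in isolation reproduces its artifacts exactly.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, count = 202L, enrich = 303L, hits = 404L,
               ora = 505L, panel = 606L)
  as.integer(seed) + offsets[[stage]]
}

#' Run pipeline stages over a shared output directory
#'
#' Orchestrates the screen pipeline: `simulate` writes a generated library
#' and simulated screen counts; `count` computes day-0 coverage QC;
#' `enrich` computes the per-sgRNA enrichment table; `hits` calls gene-level
#' hits; `ora` tests the hit list against a GMT collection (for simulated
#' runs without a GMT, against the planted bypass genes as a single set);
#' `panel` classifies responders from a dose-panel CSV. `"all"` chains
#' simulate, count, enrich, hits and ora end-to-end on synthetic data.
#' Artifacts are written atomically and every stage drops a JSON log with
#' its configuration, seed, input checksums and headline numbers.
#'
#' @param stage one of `"simulate"`, `"count"`, `"enrich"`, `"hits"`,
#'   `"ora"`, `"panel"`, `"all"`.
#' @param out_dir output directory (created if needed); stages find their
#'   inputs here unless the config points elsewhere.
#' @param config list from [pipeline_config()].
#' @param seed run seed, fanned out into per-stage substreams.
#' @return named list of artifact paths and headline numbers, invisibly for
#'   `"all"`.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "count", "enrich",
                                   "hits", "ora", "panel"),
                         out_dir, config = pipeline_config(), seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(config$fc_threshold > 0, config$alpha > 0, config$min_sgrnas > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    res <- list()
    for (s in c("simulate", "count", "enrich", "hits", "ora")) {
      res[[s]] <- run_pipeline(s, out_dir, config, seed)
    }
    return(invisible(res))
  }
  path_of <- function(field, default) {
    if (!is.null(config[[field]])) config[[field]]
    else file.path(out_dir, default)
  }
  sseed <- stage_seed(seed, stage)

  if (stage == "simulate") {
    lib <- if (!is.null(config$library)) {
      read_library(config$library)
    } else {
      g <- generate_library(config$n_genes, config$per_gene_range,
                            config$n_controls, seed = sseed)
      # plant configured bypass genes into the generated gene names
      if (!all(config$bypass_genes %in% library_genes(g))) {
        g <- relabel_genes(g, config$bypass_genes)
      }
      g
    }
    truth <- screen_truth(config$bypass_genes, config$efficacy,
                          config$r_bypass, config$r_arrest,
                          config$r_untreated, config$duration_days)
    sim <- simulate_screen(lib, truth, sim_config(
      n_cells = config$n_cells,
      plasmid_skew_sigma = config$plasmid_skew_sigma,
      depth_per_sgrna = config$depth_per_sgrna,
      n_replicates = config$n_replicates,
      include_vehicle = config$include_vehicle, seed = sseed))
    lib_path <- file.path(out_dir, "library.csv")
    counts_path <- file.path(out_dir, "counts.tsv")
    write_atomic(function(p) write_library(lib, p), lib_path)
    write_atomic(function(p) write_counts(sim$counts, p), counts_path)
    stage_log(out_dir, stage, config, sseed, character(0),
              list(n_sgrna = nrow(lib), n_samples = ncol(sim$counts)))
    return(list(library = lib_path, counts = counts_path))
  }

  if (stage == "count") {
    counts_path <- require_input(path_of("counts", "counts.tsv"), stage)
    counts <- read_counts_tsv(counts_path)
    meta <- sample_meta(counts)
    day0 <- meta$sample[meta$timepoint == "day0"][1L]
    rep_qc <- coverage_qc(counts[, day0], min_reads = config$min_reads)
    cov_path <- file.path(out_dir, "coverage.json")
    write_atomic(function(p) write_coverage_json(rep_qc, p), cov_path)
    stage_log(out_dir, stage, config, sseed, counts_path,
              list(sample = day0, coverage = rep_qc$coverage))
    return(list(coverage = cov_path, report = rep_qc))
  }

  if (stage == "enrich") {
    counts_path <- require_input(path_of("counts", "counts.tsv"), stage)
    lib_path <- require_input(path_of("library", "library.csv"), stage)
    counts <- read_counts_tsv(counts_path)
    lib <- read_library(lib_path)
    enr <- enrich_screen(counts, lib, method = config$method,
                         pseudocount = config$pseudocount,
                         fc_threshold = config$fc_threshold,
                         alpha = config$alpha)
    enr_path <- file.path(out_dir, "enrichment.tsv")
    write_atomic(function(p) write_enrichment(enr, p), enr_path)
    stage_log(out_dir, stage, config, sseed, c(counts_path, lib_path),
              list(n_pass_both = sum(enr$passes_fc & enr$passes_p)))
    return(list(enrichment = enr_path))
  }

  if (stage == "hits") {
    enr_path <- require_input(path_of("enrichment", "enrichment.tsv"), stage)
    enr <- utils::read.delim(enr_path, stringsAsFactors = FALSE)
    hits <- call_hits(enr, config$fc_threshold, config$alpha,
                      config$min_sgrnas)
    hits_path <- file.path(out_dir, "hits.tsv")
    write_atomic(function(p) write_hits(hits, p), hits_path)
    summary_path <- file.path(out_dir, "hits_summary.json")
    write_atomic(function(p) jsonlite::write_json(
      list(fc_threshold = config$fc_threshold, alpha = config$alpha,
           min_sgrnas = config$min_sgrnas, n_hits = sum(hits$is_hit)),
      p, auto_unbox = TRUE, digits = NA), summary_path)
    stage_log(out_dir, stage, config, sseed, enr_path,
              list(n_hits = sum(hits$is_hit)))
    return(list(hits = hits_path, summary = summary_path))
  }

  if (stage == "ora") {
    hits_path <- require_input(path_of("hits", "hits.tsv"), stage)
    hits_df <- utils::read.delim(hits_path, stringsAsFactors = FALSE)
    universe <- hits_df$gene
    hit_set <- hits_df$gene[hits_df$is_hit]
    sets <- if (!is.null(config$gmt)) {
      read_gmt(require_input(config$gmt, stage))
    } else {
      gene_set_collection(
        list(planted_bypass = intersect(config$bypass_genes, universe)),
        source = "simulation ground truth")
    }
    ora <- overrepresentation(hit_set, universe, sets)
    ora_path <- file.path(out_dir, "ora.tsv")
    write_atomic(function(p) utils::write.table(
      as.data.frame(ora), p, sep = "\t", quote = FALSE, row.names = FALSE),
      ora_path)
    stage_log(out_dir, stage, config, sseed, hits_path,
              list(n_terms = nrow(ora), top_p = if (nrow(ora)) ora$p[1L] else NA))
    return(list(ora = ora_path))
  }

  if (stage == "panel") {
    panel_path <- require_input(path_of("panel", "panel.csv"), stage)
    panel <- read_panel_csv(panel_path)
    calls <- call_responders(panel, alpha = config$alpha,
                             min_drugs = config$min_drugs)
    resp_path <- file.path(out_dir, "responders.tsv")
    write_atomic(function(p) utils::write.table(
      as.data.frame(calls), p, sep = "\t", quote = FALSE, row.names = FALSE),
      resp_path)
    summary_path <- file.path(out_dir, "responders_summary.json")
    write_atomic(function(p) jsonlite::write_json(
      list(alpha = config$alpha, min_drugs = config$min_drugs,
           n_responders = sum(calls$is_responder),
           responders = responder_lines(calls)),
      p, auto_unbox = TRUE, digits = NA), summary_path)
    stage_log(out_dir, stage, config, sseed, panel_path,
              list(n_responders = sum(calls$is_responder)))
    return(list(responders = resp_path, summary = summary_path,
                calls = calls))
  }
}
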