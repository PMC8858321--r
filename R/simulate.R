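#' Ground truth for a simulated bypass screen
#'
#' Describes what is true in a simulated screen: which genes, when knocked
#' out, let cells escape the drug-imposed arrest, how effective each guide's
#' knockout is, and the growth rates of the three cell states over the
#' selection window.
#'
#' @param bypass_genes character vector of gene symbols whose knockout
#'   bypasses the arrest.
#' @param efficacy fraction of infected cells with a functional knockout;
#'   either a single number applied to every guide or a named vector keyed by
#'   `sgrna_id`.
#' @param r_bypass divisions/day of bypass-knockout cells under drug.
#' @param r_arrest divisions/day of arrested cells (default 0.05 models
#'   incomplete arrest).
#' @param r_untreated divisions/day of all cells in the vehicle arm.
#' @param duration_days length of the selection window (default 14).
#' @return a `screen_truth` list.
#' @export
screen_truth <- function(bypass_genes = character(0), efficacy = 0.95,
                         r_bypass = 0.8, r_arrest = 0.05, r_untreated = 1.0,
                         duration_days = 14) {
  if (any(efficacy < 0 | efficacy > 1)) stop("efficacy must be in [0, 1]")
  if (r_arrest > r_bypass) stop("r_arrest must not exceed r_bypass")
  if (duration_days <= 0) stop("duration_days must be positive")
  structure(list(bypass_genes = unique(as.character(bypass_genes)),
                 efficacy = efficacy, r_bypass = r_bypass,
                 r_arrest = r_arrest, r_untreated = r_untreated,
                 duration_days = duration_days),
            class = "screen_truth")
}

#' Simulation configuration for the pooled screen
#'
#' @param moi mean lentiviral integrations per cell; the simulator operates in
#'   the low-MOI single-integration regime (each infected cell carries one
#'   guide), which the default 0.3 in the conventional 0.2-0.5 window
#'   justifies.
#' @param n_cells infected-cell pool size; `NULL` means 500 x library size.
#' @param plasmid_skew_sigma lognormal sigma of plasmid library
#'   representation skew.
#' @param depth_per_sgrna mean sequencing reads per guide per sample.
#' @param n_replicates number of independent screen replicates.
#' @param include_vehicle also sequence a vehicle (untreated) arm.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(moi = 0.3, n_cells = NULL, plasmid_skew_sigma = 1,
                       depth_per_sgrna = 200, n_replicates = 2,
                       include_vehicle = TRUE, seed = 1L) {
  stopifnot(moi > 0, plasmid_skew_sigma > 0, depth_per_sgrna > 0,
            n_replicates >= 1)
  if (!is.null(n_cells) && n_cells <= 0) stop("n_cells must be positive")
  structure(list(moi = moi, n_cells = n_cells,
                 plasmid_skew_sigma = plasmid_skew_sigma,
                 depth_per_sgrna = depth_per_sgrna,
                 n_replicates = as.integer(n_replicates),
                 include_vehicle = isTRUE(include_vehicle),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a count table
#'
#' An sgRNA x sample matrix of nonnegative integer read counts plus per-sample
#' metadata (arm, timepoint, replicate). Sample names follow
#' `{arm}_{timepoint}_rep{k}`.
#'
#' @param counts integer matrix, rows named by `sgrna_id`.
#' @param samples data frame with columns `sample`, `arm` (`drug`/`vehicle`),
#'   `timepoint` (`day0`/`day14`), `replicate`.
#' @return a `count_table` (matrix with a `samples` attribute).
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) != nrow(samples)) stop("samples must describe each column")
  colnames(counts) <- samples$sample
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  structure(counts, samples = samples,
            class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  s <- attr(x, "samples")
  cat("count table: ", nrow(x), " sgRNAs x ", ncol(x), " samples\n", sep = "")
  cat("samples:", paste(s$sample, collapse = ", "), "\n")
  cat("column sums:", paste(colSums(x), collapse = ", "), "\n")
  invisible(x)
}

sample_meta <- function(x) attr(x, "samples")

expand_efficacy <- function(truth, lib) {
  eff <- truth$efficacy
  if (length(eff) == 1L && is.null(names(eff))) {
    return(rep(as.numeric(eff), nrow(lib)))
  }
  out <- eff[lib$sgrna_id]
  if (anyNA(out)) stop("efficacy vector missing sgrna_id(s): ",
                       paste(head(lib$sgrna_id[is.na(out)], 3L), collapse = ", "))
  as.numeric(out)
}

#' Simulate a pooled CRISPR bypass screen
#'
#' Forward-simulates the screen: (1) plasmid representation per guide is
#' lognormal(0, sigma), normalised, drawn once and shared by all replicates
#' (one plasmid pool); then per replicate (2) the infected-cell pool is
#' allocated to guides by a multinomial draw, and each guide's cells split
#' into a knockout fraction (its efficacy) and a residual wild-type fraction;
#' (3) cell mass grows deterministically and exponentially over the selection
#' window -- knockouts of bypass genes at `r_bypass` divisions/day in the drug
#' arm, everything else arrested at `r_arrest`; the vehicle arm grows
#' uniformly at `r_untreated`; (4) day-0 and day-14 libraries are sequenced by
#' multinomial sampling at total depth `depth_per_sgrna` x library size.
#' Stochasticity therefore enters only at cell allocation and sequencing.
#'
#' @param lib an [sgrna_library].
#' @param truth a [screen_truth]; `bypass_genes` must be library genes.
#' @param cfg a [sim_config].
#' @return a `screen_sim` list with elements `counts` (a [count_table]) and
#'   `truth` (the ground truth used).
#' @examples
#' lib <- generate_library(n_genes = 50, n_controls = 10, seed = 1)
#' tr <- screen_truth(bypass_genes = "GENE00001")
#' sim <- simulate_screen(lib, tr, sim_config(seed = 1))
#' print(sim$counts)
#' @export
simulate_screen <- function(lib, truth, cfg = sim_config()) {
  unknown <- setdiff(truth$bypass_genes, library_genes(lib))
  if (length(unknown) > 0L) {
    stop("bypass gene(s) not in library: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(lib)
  if (n == 0L) stop("empty library")
  n_cells <- if (is.null(cfg$n_cells)) 500 * n else cfg$n_cells
  if (n_cells <= 0) stop("n_cells must be positive")
  set.seed(cfg$seed)
  depth <- round(cfg$depth_per_sgrna * n)
  eff <- expand_efficacy(truth, lib)
  is_bypass <- lib$gene %in% truth$bypass_genes
  d <- truth$duration_days
  arms <- if (cfg$include_vehicle) c("drug", "vehicle") else "drug"

  # one plasmid pool, shared by all replicates; infection allocation and
  # sequencing are per replicate
  w <- rlnorm(n, 0, cfg$plasmid_skew_sigma)
  cols <- list(); meta <- list()
  for (rep_i in seq_len(cfg$n_replicates)) {
    cells <- as.numeric(rmultinom(1L, n_cells, w / sum(w)))
    ko <- cells * eff
    wt <- cells - ko
    r_eff <- ifelse(is_bypass, truth$r_bypass, truth$r_arrest)
    mass14 <- list(
      drug = ko * 2^(r_eff * d) + wt * 2^(truth$r_arrest * d),
      vehicle = cells * 2^(truth$r_untreated * d)
    )
    for (arm in arms) {
      cols[[paste0(arm, "_day0_rep", rep_i)]] <-
        as.integer(rmultinom(1L, depth, cells / sum(cells)))
      cols[[paste0(arm, "_day14_rep", rep_i)]] <-
        as.integer(rmultinom(1L, depth, mass14[[arm]] / sum(mass14[[arm]])))
      meta[[length(meta) + 1L]] <- data.frame(
        sample = paste0(arm, c("_day0_rep", "_day14_rep"), rep_i),
        arm = arm, timepoint = c("day0", "day14"), replicate = rep_i,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- lib$sgrna_id
  structure(list(counts = count_table(counts, do.call(rbind, meta)),
                 truth = truth),
            class = "screen_sim")
}

#' Emit simulated sequencing reads as FASTQ
#'
#' Writes one FASTQ file per sample of a count table: each count c for a guide
#' yields c reads of the form `adapter + spacer + A-fill` to `read_len` bases,
#' constant quality, in shuffled order. Round-trips exactly through
#' [count_reads()].
#'
#' @param counts a [count_table].
#' @param lib the [sgrna_library] the counts are aligned to.
#' @param dir output directory (created if needed).
#' @param adapter constant 5' sequence preceding the spacer.
#' @param read_len total read length; must cover adapter + 20 nt.
#' @param seed seed for the read shuffle.
#' @return named character vector of FASTQ paths, one per sample.
#' @export
emit_fastq <- function(counts, lib, dir, adapter = "TTGTGGAAAGGACGAAACACCG",
                       read_len = 75L, seed = 1L) {
  if (read_len < nchar(adapter) + 20L) {
    stop("read_len must be at least nchar(adapter) + 20")
  }
  if (!identical(rownames(counts), lib$sgrna_id)) {
    stop("count rows must match library sgrna_ids")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  fill_len <- read_len - nchar(adapter) - 20L
  tmpl <- paste0(adapter, lib$spacer, strrep("A", fill_len))
  qual <- strrep("I", read_len)
  paths <- character(0)
  for (s in colnames(counts)) {
    cvec <- counts[, s]
    seqs <- rep(tmpl, cvec)
    if (length(seqs) > 0L) seqs <- seqs[sample.int(length(seqs))]
    path <- file.path(dir, paste0(s, ".fastq"))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- if (length(seqs) > 0L) {
      paste0("read", seq_along(seqs))
    } else character(0)
    Biostrings::writeXStringSet(
      dna, path, format = "fastq",
      qualities = Biostrings::BStringSet(rep(qual, length(seqs))))
    paths[s] <- path
  }
  paths
}

#' Ground truth for a simulated dose-response panel
#'
#' One row per (cell line, drug) pair stating whether the line responds to the
#' drug and with what maximal fractional growth inhibition.
#'
#' @param cell_lines,drugs character vectors; the truth covers their full
#'   cross product.
#' @param responsive logical vector (recycled) over the cross product, lines
#'   varying fastest.
#' @param effect maximal fractional reduction of absorbance for responsive
#'   pairs.
#' @return data frame classed `panel_truth` with columns `cell_line`, `drug`,
#'   `responsive`, `effect`.
#' @export
panel_truth <- function(cell_lines, drugs, responsive, effect = 0.6) {
  grid <- expand.grid(cell_line = cell_lines, drug = drugs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$responsive <- rep_len(as.logical(responsive), nrow(grid))
  grid$effect <- ifelse(grid$responsive, effect, 0)
  structure(grid, class = c("panel_truth", "data.frame"))
}

#' Simulate a multi-line inhibitor dose-response panel
#'
#' Generates crystal-violet-style absorbance readings for every
#' (line, drug, dose, replicate) well. For responsive pairs the mean
#' absorbance is `baseline * (1 - effect * h(dose))` with `h` a Hill-type
#' saturating function of log dose (half-maximal at the geometric mid-dose);
#' non-responsive pairs stay at baseline. Gaussian noise with standard
#' deviation `noise_sd * baseline` is added everywhere. Dose 0 encodes the
#' vehicle wells.
#'
#' @param truth a [panel_truth].
#' @param doses positive ascending dose vector, in micromolar.
#' @param n_reps replicates per well condition (at least 2).
#' @param noise_sd well noise as a fraction of baseline.
#' @param baseline mean vehicle absorbance (arbitrary OD units at 570 nm).
#' @param seed integer seed.
#' @return a `dose_panel` data frame with columns `cell_line`, `drug`,
#'   `dose_uM`, `replicate`, `absorbance`.
#' @export
simulate_panel <- function(truth, doses = c(0.25, 1, 5), n_reps = 3,
                           noise_sd = 0.05, baseline = 1.0, seed = 1L) {
  if (length(doses) == 0L) stop("dose list must not be empty")
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be positive and strictly ascending")
  }
  if (n_reps < 2L) stop("need at least 2 replicates")
  set.seed(seed)
  ec50 <- sqrt(min(doses) * max(doses))
  all_doses <- c(0, doses)
  grid <- merge(truth,
                expand.grid(dose_uM = all_doses, replicate = seq_len(n_reps),
                            KEEP.OUT.ATTRS = FALSE),
                by = NULL)
  h <- ifelse(grid$dose_uM > 0, grid$dose_uM / (grid$dose_uM + ec50), 0)
  mu <- baseline * (1 - grid$effect * h)
  grid$absorbance <- mu + rnorm(nrow(grid), 0, noise_sd * baseline)
  out <- grid[order(grid$cell_line, grid$drug, grid$dose_uM, grid$replicate),
              c("cell_line", "drug", "dose_uM", "replicate", "absorbance")]
  rownames(out) <- NULL
  structure(out, class = c("dose_panel", "data.frame"))
}
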