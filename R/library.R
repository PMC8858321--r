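#' @importFrom stats rmultinom rnorm rlnorm median mad pnorm t.test
#'   wilcox.test phyper p.adjust lm pt setNames
#' @importFrom utils read.csv write.csv head
NULL

# Reserved gene label for non-targeting control guides.
CONTROL_LABEL <- "NonTargeting"

#' Construct an sgRNA library object
#'
#' An `sgrna_library` is a data frame with one row per guide and columns
#' `sgrna_id`, `gene`, `spacer` (20-nt protospacer over A/C/G/T) and `klass`
#' (`"targeting"` or `"control"`). Non-targeting controls carry the reserved
#' gene label `"NonTargeting"`.
#'
#' @param records data frame with columns `sgrna_id`, `gene`, `spacer`,
#'   `klass`, one row per guide.
#' @return the validated library, classed `sgrna_library`.
#' @export
sgrna_library <- function(records) {
  required <- c("sgrna_id", "gene", "spacer", "klass")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records[, required], stringsAsFactors = FALSE)
  rownames(records) <- NULL
  lib <- structure(records, class = c("sgrna_library", "data.frame"))
  validate_library(lib)
  lib
}

validate_library <- function(lib) {
  if (nrow(lib) == 0L) return(invisible(lib))
  dup_id <- which(duplicated(lib$sgrna_id))
  if (length(dup_id) > 0L) {
    stop("duplicate sgrna_id '", lib$sgrna_id[dup_id[1L]],
         "' at row ", dup_id[1L])
  }
  dup_sp <- which(duplicated(lib$spacer))
  if (length(dup_sp) > 0L) {
    stop("duplicate spacer '", lib$spacer[dup_sp[1L]],
         "' at row ", dup_sp[1L])
  }
  bad <- which(nchar(lib$spacer) != 20L | grepl("[^ACGT]", lib$spacer))
  if (length(bad) > 0L) {
    stop("malformed spacer at row ", bad[1L],
         ": must be 20 characters over A/C/G/T, got '", lib$spacer[bad[1L]], "'")
  }
  if (!all(lib$klass %in% c("targeting", "control"))) {
    stop("klass must be 'targeting' or 'control'")
  }
  mismatch <- which((lib$klass == "control") != (lib$gene == CONTROL_LABEL))
  if (length(mismatch) > 0L) {
    stop("row ", mismatch[1L], ": klass 'control' must pair with gene label '",
         CONTROL_LABEL, "' and vice versa")
  }
  invisible(lib)
}

#' @export
print.sgrna_library <- function(x, ...) {
  genes <- library_genes(x)
  cat("sgRNA library: ", nrow(x), " guides, ", length(genes),
      " targeting genes, ", sum(x$klass == "control"),
      " non-targeting controls\n", sep = "")
  if (length(genes) > 0L) {
    per_gene <- table(x$gene[x$klass == "targeting"])
    cat("guides per gene: ", min(per_gene), "-", max(per_gene), "\n", sep = "")
  }
  invisible(x)
}

#' Targeting gene symbols of a library
#'
#' @param lib an `sgrna_library`.
#' @return character vector of distinct targeting gene symbols, in library order.
#' @export
library_genes <- function(lib) {
  unique(lib$gene[lib$klass == "targeting"])
}

# Uniform random 20-mers, distinct, vectorised with a retry loop for the
# (astronomically rare at library scale) collision case.
random_spacers <- function(n, max_tries = 10L) {
  if (n == 0L) return(character(0))
  spacers <- character(0)
  for (i in seq_len(max_tries)) {
    need <- n - length(spacers)
    if (need <= 0L) break
    draw <- matrix(sample(c("A", "C", "G", "T"), 20L * need, replace = TRUE),
                   nrow = need)
    spacers <- unique(c(spacers, apply(draw, 1L, paste, collapse = "")))
  }
  if (length(spacers) < n) {
    stop("could not draw ", n, " distinct 20-mers after ", max_tries, " tries")
  }
  spacers[seq_len(n)]
}

#' Generate a synthetic GeCKO-style sgRNA library
#'
#' Emulates a genome-scale knockout library: `n_genes` targeting genes, each
#' covered by a number of guides drawn uniformly from `per_gene_range`, plus
#' `n_controls` non-targeting control guides. Spacers are distinct uniform
#' random 20-mers. The default dimensions follow the GeCKOv2 design
#' (19,050 genes at 5-6 guides per gene).
#'
#' @param n_genes number of targeting genes.
#' @param per_gene_range integer pair `c(min, max)` guides per gene.
#' @param n_controls number of non-targeting control guides.
#' @param seed integer seed; the same seed reproduces the library exactly.
#' @return an [sgrna_library] object.
#' @examples
#' lib <- generate_library(n_genes = 10, per_gene_range = c(5, 6),
#'                         n_controls = 4, seed = 1)
#' print(lib)
#' @export
generate_library <- function(n_genes = 19050L, per_gene_range = c(5L, 6L),
                             n_controls = 1000L, seed = 1L) {
  if (n_genes < 0L || n_controls < 0L) stop("counts must be nonnegative")
  lo <- as.integer(per_gene_range[1L]); hi <- as.integer(per_gene_range[2L])
  if (lo < 1L || hi < lo) stop("per_gene_range must satisfy 1 <= min <= max")
  set.seed(seed)
  per_gene <- if (n_genes == 0L) integer(0)
              else if (lo == hi) rep(lo, n_genes)
              else sample(lo:hi, n_genes, replace = TRUE)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  gene_col <- c(rep(genes, per_gene), rep(CONTROL_LABEL, n_controls))
  klass <- c(rep("targeting", sum(per_gene)), rep("control", n_controls))
  n_total <- length(gene_col)
  ids <- character(n_total)
  if (n_genes > 0L) {
    within <- sequence(per_gene)
    ids[klass == "targeting"] <- paste0("sg", rep(genes, per_gene), "_", within)
  }
  if (n_controls > 0L) {
    ids[klass == "control"] <- sprintf("sgCTRL_%04d", seq_len(n_controls))
  }
  sgrna_library(data.frame(sgrna_id = ids, gene = gene_col,
                           spacer = random_spacers(n_total), klass = klass,
                           stringsAsFactors = FALSE))
}

#' Rename targeting genes of a generated library
#'
#' Utility for planting named ground-truth genes: replaces the symbols of the
#' first `length(new_names)` targeting genes with `new_names`.
#'
#' @param lib an `sgrna_library`.
#' @param new_names character vector of replacement gene symbols.
#' @return the relabelled library.
#' @export
relabel_genes <- function(lib, new_names) {
  genes <- library_genes(lib)
  if (length(new_names) > length(genes)) stop("more names than genes")
  idx <- match(lib$gene, genes[seq_along(new_names)])
  lib$gene[!is.na(idx)] <- new_names[idx[!is.na(idx)]]
  lib$sgrna_id <- ifelse(lib$klass == "targeting",
                         paste0("sg", lib$gene, "_",
                                stats::ave(seq_len(nrow(lib)), lib$gene,
                                           FUN = seq_along)),
                         lib$sgrna_id)
  sgrna_library(lib)
}

#' Read an sgRNA library from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `sgrna_id,gene,spacer,klass`. All library invariants (unique ids and
#' spacers, 20-nt A/C/G/T spacers, control labelling) are checked and
#' violations reported with the offending row.
#'
#' @param path file path.
#' @return an [sgrna_library].
#' @export
read_library <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  sgrna_library(df)
}

#' Write an sgRNA library to CSV
#'
#' @param lib an [sgrna_library].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  write.csv(as.data.frame(lib), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export library spacers as FASTA
#'
#' @param lib an [sgrna_library].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spacers_fasta <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(setNames(lib$spacer, lib$sgrna_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
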