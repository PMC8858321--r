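test_that("emit_fastq -> count_reads round-trips counts exactly", {
  lib <- tiny_lib(n_genes = 8, n_controls = 2)
  sim <- simulate_screen(lib, screen_truth(),
                         sim_config(depth_per_sgrna = 30, seed = 3,
                                    include_vehicle = FALSE))
  dir <- withr::local_tempdir()
  paths <- emit_fastq(sim$counts, lib, dir, read_len = 60, seed = 5)
  for (s in colnames(sim$counts)) {
    rc <- count_reads(paths[s], lib, offset = 22)
    expect_identical(unname(rc$counts), unname(sim$counts[, s]))
    expect_identical(rc$n_reads_unassigned, 0L)
    # auto offset detection finds the adapter length
    expect_identical(count_reads(paths[s], lib, offset = "auto")$offset, 22L)
  }
})

test_that("all-zero counts give an empty FASTQ and all-zero counts back", {
  lib <- tiny_lib(n_genes = 3, n_controls = 0)
  zero <- count_table(matrix(0L, nrow(lib), 1,
                             dimnames = list(lib$sgrna_id, "drug_day0_rep1")),
                      data.frame(sample = "drug_day0_rep1", arm = "drug",
                                 timepoint = "day0", replicate = 1))
  dir <- withr::local_tempdir()
  p <- emit_fastq(zero, lib, dir, read_len = 50, seed = 1)
  rc <- count_reads(p[1], lib, offset = 22)
  expect_identical(rc$n_reads_total, 0L)
  expect_true(all(rc$counts == 0))
})

test_that("unmatched reads are tallied unassigned, never double-counted", {
  lib <- tiny_lib(n_genes = 2, n_controls = 0)
  path <- withr::local_tempfile(fileext = ".fastq")
  alien <- strrep("N", 20)  # matches no spacer
  writeLines(c("@r1", paste0(lib$spacer[1], strrep("A", 20)), "+",
               strrep("I", 40),
               "@r2", paste0(alien, strrep("A", 20)), "+", strrep("I", 40),
               "@r3", "ACGT", "+", "IIII"),  # shorter than offset+20
             path)
  rc <- count_reads(path, lib, offset = 0)
  expect_identical(sum(rc$counts), 1L)
  expect_identical(rc$n_reads_unassigned, 2L)
  expect_identical(sum(rc$counts) + rc$n_reads_unassigned, rc$n_reads_total)
})

test_that("single-mismatch rescue assigns unique neighbours only", {
  spacers <- c(strrep("A", 20), paste0(strrep("A", 19), "C"))
  lib <- sgrna_library(data.frame(
    sgrna_id = c("sg1", "sg2"), gene = c("G1", "G2"),
    spacer = spacers, klass = "targeting"))
  path <- withr::local_tempfile(fileext = ".fastq")
  # read1: distance 1 from sg1 only (position 10); read2: distance 1 from
  # both sg1 and sg2 (differs from each at one position) -> ambiguous
  r1 <- paste0(strrep("A", 9), "G", strrep("A", 10))
  r2 <- paste0(strrep("A", 19), "G")
  writeLines(c("@a", r1, "+", strrep("I", 20),
               "@b", r2, "+", strrep("I", 20)), path)
  exact <- count_reads(path, lib, offset = 0, allow_mismatch = 0)
  expect_identical(sum(exact$counts), 0L)
  rescued <- count_reads(path, lib, offset = 0, allow_mismatch = 1)
  expect_identical(unname(rescued$counts), c(1L, 0L))
  expect_identical(rescued$n_reads_unassigned, 1L)
})

test_that("counting is order-independent for exact matching", {
  lib <- tiny_lib(n_genes = 4, n_controls = 1)
  reads <- rep(paste0(lib$spacer, strrep("T", 10)),
               times = c(3, 0, 2, 1, 4, seq_len(12)))
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  fq <- function(seqs) as.vector(rbind(paste0("@r", seq_along(seqs)), seqs,
                                       "+", strrep("I", nchar(seqs))))
  writeLines(fq(reads), p1)
  set.seed(1)
  writeLines(fq(sample(reads)), p2)
  expect_identical(count_reads(p1, lib, offset = 0)$counts,
                   count_reads(p2, lib, offset = 0)$counts)
})

test_that("truncated FASTQ records are reported with their index", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(count_reads(path, tiny_lib(), offset = 0),
               "truncated FASTQ record 2")
})

test_that("coverage_qc computes detection fractions as defined", {
  expect_equal(coverage_qc(c(0, 5, 2, 0))$coverage, 0.5)
  expect_equal(coverage_qc(c(1, 8, 3))$coverage, 1.0)
  expect_error(coverage_qc(numeric(0)), "empty library")
  # non-increasing in min_reads
  set.seed(2)
  counts <- rpois(500, 3)
  covs <- vapply(1:6, function(m) coverage_qc(counts, m)$coverage, numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("coverage report serialises to JSON faithfully", {
  rep_qc <- coverage_qc(c(0, 4, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_coverage_json(rep_qc, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$coverage, 2 / 3)
  expect_identical(back$n_sgrna, 3L)
})
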