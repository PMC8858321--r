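flat_panel <- function(lines = "L1", drugs = c("d1", "d2", "d3"),
                       value = 0.8) {
  simulate_panel(panel_truth(lines, drugs, responsive = FALSE),
                 noise_sd = 0, baseline = value, seed = 1)
}

test_that("vehicle normalisation is exact and scale-invariant", {
  p <- flat_panel(value = 0.8)
  p$absorbance[p$dose_uM == 5] <- 0.4
  norm <- normalize_panel(p)
  expect_true(all(norm$absorbance[norm$dose_uM == 0] == 1))
  expect_equal(unique(norm$absorbance[norm$dose_uM == 5]), 0.5)
  # rescaling one (line,drug)'s wells by a constant changes nothing
  p2 <- p
  sel <- p2$drug == "d1"
  p2$absorbance[sel] <- p2$absorbance[sel] * 7
  expect_equal(normalize_panel(p2)$absorbance, norm$absorbance)
  # missing or nonpositive vehicle wells are errors
  noveh <- p[p$dose_uM > 0, ]
  expect_error(normalize_panel(noveh), "no vehicle")
  zero <- p; zero$absorbance[zero$dose_uM == 0] <- 0
  expect_error(normalize_panel(zero), "vehicle mean")
})

test_that("trend test centre, divergence and symmetry", {
  doses <- rep(c(0.25, 1, 5), each = 3)
  flat <- trend_test(rep(1, 9), doses)
  expect_equal(unname(flat["slope"]), 0)
  expect_equal(unname(flat["p"]), 0.5)
  tr <- panel_truth("L", "d", TRUE, effect = 0.9)
  noiseless <- normalize_panel(simulate_panel(tr, noise_sd = 0, seed = 1))
  nz <- noiseless[noiseless$dose_uM > 0, ]
  dec <- trend_test(nz$absorbance, nz$dose_uM)
  expect_lt(unname(dec["p"]), 1e-4)
  inc <- trend_test(2 - nz$absorbance, nz$dose_uM)
  expect_equal(unname(inc["p"]), 1 - unname(dec["p"]))
  expect_error(trend_test(rep(1, 4), rep(c(1, 5), 2)), "3 distinct")
  expect_error(trend_test(1:3, c(1, 2, 5)), "replicates")
})

test_that("responder rule counts responsive drugs against min_drugs", {
  tr <- rbind(panel_truth("R2of3", c("d1", "d2"), TRUE),
              panel_truth("R2of3", "d3", FALSE),
              panel_truth("R1of3", "d1", TRUE),
              panel_truth("R1of3", c("d2", "d3"), FALSE))
  calls <- call_responders(simulate_panel(tr, noise_sd = 0.02, seed = 3))
  expect_identical(responder_lines(calls), "R2of3")
  expect_identical(calls$n_drugs_responsive[calls$cell_line == "R1of3"], 1L)
})

test_that("a noiseless non-responsive panel yields zero responders", {
  calls <- call_responders(flat_panel(lines = paste0("L", 1:4)))
  expect_identical(sum(calls$is_responder), 0L)
})

test_that("responder counts are monotone in alpha and min_drugs", {
  set.seed(2)
  panel <- simulate_panel(cdk46_panel_truth("primary"), seed = 2)
  n_resp <- function(...) sum(call_responders(panel, ...)$is_responder)
  expect_true(all(diff(vapply(c(.2, .05, .01, .001),
    function(a) n_resp(alpha = a), numeric(1))) <= 0))
  expect_true(all(diff(vapply(1:3,
    function(m) n_resp(min_drugs = m), numeric(1))) <= 0))
})

test_that("responder calling is sensitive and specific across seeds", {
  truth <- cdk46_panel_truth("primary")
  truth_lines <- tapply(truth$responsive, truth$cell_line, sum) >= 2
  tp <- fp <- tn <- fn <- 0
  for (s in 1:50) {
    calls <- call_responders(simulate_panel(truth, seed = s))
    called <- setNames(calls$is_responder, calls$cell_line)
    called <- called[names(truth_lines)]
    tp <- tp + sum(called & truth_lines)
    fn <- fn + sum(!called & truth_lines)
    fp <- fp + sum(called & !truth_lines)
    tn <- tn + sum(!called & !truth_lines)
  }
  expect_gte(tp / (tp + fn), 0.95)   # sensitivity
  expect_gte(tn / (tn + fp), 0.95)   # specificity
})

test_that("secondary confirmation keeps two-round responders only", {
  primary_truth <- cdk46_panel_truth("primary")
  primary <- call_responders(simulate_panel(primary_truth, seed = 4))
  # identical data re-tested: confirmation is idempotent
  same <- secondary_confirmation(
    primary, simulate_panel(primary_truth, seed = 4)[
      simulate_panel(primary_truth, seed = 4)$cell_line %in%
        responder_lines(primary), ])
  expect_setequal(responder_lines(same), responder_lines(primary))
  # a primary responder flat in the secondary round is dropped
  sec_truth <- cdk46_panel_truth("secondary")
  sec <- simulate_panel(sec_truth, seed = 5)
  confirmed <- secondary_confirmation(primary, sec)
  expect_setequal(responder_lines(confirmed),
                  c("MCF7", "SKMEL28", "ACHN", "HT-29", "SNU-387"))
  # lines outside the primary responder set are ignored with a warning
  stray <- simulate_panel(cdk46_panel_truth("secondary"), seed = 6)
  stray$cell_line[stray$cell_line == "SYN06"] <- "NOT_IN_PRIMARY"
  expect_warning(secondary_confirmation(primary, stray), "NOT_IN_PRIMARY")
})
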