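#' Candidate bypass-gene list for screen recovery experiments
#'
#' An 18-gene ground-truth list for planting in [simulate_screen()]: the two
#' coagulation-pathway genes recurrently nominated by CDK4/6-inhibitor bypass
#' screens (F9, PROZ) plus 16 synthetic placeholder symbols standing in for
#' the remainder of a screen's candidate list, whose identities are not
#' modelled.
#'
#' @return character vector of 18 gene symbols.
#' @export
bypass_gene_set <- function() {
  c("F9", "PROZ", sprintf("BYPASS%02d", 3:18))
}

#' Built-in ground truth for the 22-line CDK4/6-inhibitor panel
#'
#' A 22-cell-line x 3-drug (Palbociclib, Abemaciclib, Ribociclib)
#' responsiveness configuration for [simulate_panel()]:
#'
#' * `"primary"`: 8 responder lines (responsive to >= 2 drugs) -- the five
#'   confirmable lines MCF7, SKMEL28, ACHN, HT-29 and SNU-387 responsive to
#'   all three drugs, plus three synthetic responder lines (SYN06-SYN08)
#'   responsive to exactly two; the remaining 14 lines do not respond to any
#'   drug. Planted truth is kept away from the responder decision boundary
#'   (no line is responsive to exactly one drug) so that the recovery
#'   experiment measures the classifier, not type-I coin flips on boundary
#'   lines.
#' * `"secondary"`: the re-test design over the 8 primary responders, in
#'   which only the five confirmable lines retain responsiveness to >= 2
#'   drugs and SYN06-SYN08 are flat (a primary responder that does not
#'   re-test is dropped).
#'
#' Line names other than the five confirmable lines are synthetic
#' placeholders.
#'
#' @param stage `"primary"` or `"secondary"`.
#' @param effect maximal fractional inhibition for responsive pairs.
#' @return a [panel_truth] data frame.
#' @export
cdk46_panel_truth <- function(stage = c("primary", "secondary"),
                              effect = 0.6) {
  stage <- match.arg(stage)
  drugs <- c("Palbociclib", "Abemaciclib", "Ribociclib")
  confirmed <- c("MCF7", "SKMEL28", "ACHN", "HT-29", "SNU-387")
  partial <- sprintf("SYN%02d", 6:8)      # primary-only responders
  inert <- sprintf("SYN%02d", 9:22)       # no response
  resp <- function(lines, n_drugs) {
    grid <- expand.grid(cell_line = lines, drug = drugs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$responsive <- match(grid$drug, drugs) <= n_drugs
    grid
  }
  truth <- if (stage == "primary") {
    rbind(resp(confirmed, 3L), resp(partial, 2L), resp(inert, 0L))
  } else {
    rbind(resp(confirmed, 3L), resp(partial, 0L))
  }
  truth$effect <- ifelse(truth$responsive, effect, 0)
  structure(truth[order(truth$cell_line, truth$drug), ],
            class = c("panel_truth", "data.frame"))
}
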