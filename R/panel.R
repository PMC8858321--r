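#' Normalise a dose panel to its vehicle wells
#'
#' Divides every absorbance by the mean vehicle (dose 0) absorbance of its
#' (cell line, drug) pair, so the vehicle mean maps to 1 and dose wells read
#' as fractions of untreated growth. Normalisation is per condition, not
#' plate-wide, matching per-condition vehicle controls.
#'
#' @param panel a `dose_panel` data frame (`cell_line`, `drug`, `dose_uM`,
#'   `replicate`, `absorbance`).
#' @return the panel with `absorbance` rescaled; attribute
#'   `normalized = TRUE`.
#' @export
normalize_panel <- function(panel) {
  key <- paste(panel$cell_line, panel$drug, sep = "\r")
  veh <- panel$dose_uM == 0
  if (!all(unique(key) %in% key[veh])) {
    miss <- setdiff(unique(key), key[veh])[1L]
    stop("no vehicle wells for ", sub("\r", " / ", miss))
  }
  vmeans <- tapply(panel$absorbance[veh], key[veh], mean)
  denom <- as.numeric(vmeans[key])
  if (any(denom <= 0)) {
    bad <- key[denom <= 0][1L]
    stop("vehicle mean <= 0 for ", sub("\r", " / ", bad))
  }
  panel$absorbance <- panel$absorbance / denom
  structure(panel, normalized = TRUE,
            class = c("dose_panel", "data.frame"))
}

#' One-sided log-dose trend test
#'
#' Regresses normalised absorbance on log10(dose) over the nonzero doses and
#' returns the least-squares slope with a one-sided p-value for a decreasing
#' trend (slope < 0) from the regression t statistic. This encodes
#' "dose-dependent response" directly: growth falls as dose rises.
#'
#' Noiseless data are handled deterministically: a flat profile gives
#' p = 0.5 (the centre of the one-sided null), a strictly monotone noiseless
#' profile gives p = 0 or 1 as the t statistic diverges.
#'
#' @param values normalised absorbances for the nonzero-dose wells.
#' @param doses matching doses (micromolar, all > 0); at least 3 distinct
#'   doses with >= 2 replicates each.
#' @return named vector `c(slope = , p = )`.
#' @export
trend_test <- function(values, doses) {
  if (any(doses <= 0)) stop("trend test uses nonzero doses only")
  if (length(unique(doses)) < 3L) stop("need >= 3 distinct doses")
  if (min(table(doses)) < 2L) stop("need >= 2 replicates per dose")
  x <- log10(doses)
  fit <- lm(values ~ x)
  # summary() warns on noiseless profiles; that case is handled explicitly
  sms <- suppressWarnings(summary(fit))
  slope <- sms$coefficients["x", "Estimate"]
  se <- sms$coefficients["x", "Std. Error"]
  scale_y <- mean(abs(values)) + .Machine$double.eps
  tol <- 1e-10 * scale_y
  if (abs(slope) < tol) slope <- 0
  if (!is.finite(se) || sms$sigma < tol) {
    # noiseless profile: the t statistic is 0/0 (flat) or divergent (monotone)
    p <- if (slope == 0) 0.5 else if (slope < 0) 0 else 1
  } else {
    p <- pt(slope / se, df = fit$df.residual)
  }
  c(slope = unname(slope), p = unname(p))
}

#' Classify cell lines as CDK4/6-inhibitor responders
#'
#' Normalises the panel to vehicle, runs the one-sided log-dose [trend_test()]
#' per (line, drug), flags a pair responsive when p < `alpha` with a negative
#' slope, and calls a line a responder when it is responsive to at least
#' `min_drugs` drugs. A (line, drug) whose trend test cannot run (too few
#' doses or replicates) is recorded as non-responsive with the reason.
#'
#' @param panel a `dose_panel`.
#' @param alpha per-(line, drug) significance level.
#' @param min_drugs minimum number of responsive drugs for responder status.
#' @return a `responder_calls` data frame (one row per line: `cell_line`,
#'   `n_drugs_responsive`, `is_responder`) with the per-(line, drug) table in
#'   attribute `detail` (`cell_line`, `drug`, `slope`, `p`, `responsive`,
#'   `reason`).
#' @export
call_responders <- function(panel, alpha = 0.05, min_drugs = 2) {
  if (alpha <= 0 || min_drugs <= 0) stop("thresholds must be positive")
  norm <- normalize_panel(panel)
  pairs <- unique(norm[, c("cell_line", "drug")])
  detail <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sub <- norm[norm$cell_line == pairs$cell_line[i] &
                norm$drug == pairs$drug[i] & norm$dose_uM > 0, ]
    res <- tryCatch(trend_test(sub$absorbance, sub$dose_uM),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(cell_line = pairs$cell_line[i], drug = pairs$drug[i],
                 slope = NA_real_, p = NA_real_, responsive = FALSE,
                 reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(cell_line = pairs$cell_line[i], drug = pairs$drug[i],
                 slope = res[["slope"]], p = res[["p"]],
                 responsive = res[["p"]] < alpha && res[["slope"]] < 0,
                 reason = "", stringsAsFactors = FALSE)
    }
  }))
  n_resp <- tapply(detail$responsive, detail$cell_line, sum)
  lines <- unique(panel$cell_line)
  calls <- data.frame(cell_line = lines,
                      n_drugs_responsive = as.integer(n_resp[lines]),
                      is_responder = as.integer(n_resp[lines]) >= min_drugs,
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls, detail = detail, alpha = alpha, min_drugs = min_drugs,
            class = c("responder_calls", "data.frame"))
}

#' @export
print.responder_calls <- function(x, ...) {
  md <- attr(x, "min_drugs"); al <- attr(x, "alpha")
  cat("responder calls: ", sum(x$is_responder), " / ", nrow(x),
      " cell lines responsive to >= ", if (is.null(md)) "min_drugs" else md,
      " drugs (alpha ", if (is.null(al)) "?" else al, ")\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Responder cell lines of a call set
#'
#' @param calls a `responder_calls` data frame.
#' @return character vector of responder cell-line names.
#' @export
responder_lines <- function(calls) calls$cell_line[calls$is_responder]

#' Secondary-screen confirmation of primary responders
#'
#' Re-evaluates the primary responders on an independent secondary panel with
#' the same rule; a line is confirmed iff it is a responder in both rounds.
#' Secondary measurements for lines that were not primary responders trigger
#' a warning and are ignored.
#'
#' @param primary a `responder_calls` from the primary screen.
#' @param secondary_panel a `dose_panel` measured on the primary responders.
#' @param alpha,min_drugs thresholds for the secondary round (defaults taken
#'   from the primary call).
#' @return a `responder_calls` for the secondary round, restricted to primary
#'   responders; `responder_lines()` of it is the confirmed set.
#' @export
secondary_confirmation <- function(primary, secondary_panel,
                                   alpha = attr(primary, "alpha"),
                                   min_drugs = attr(primary, "min_drugs")) {
  keep <- responder_lines(primary)
  extra <- setdiff(unique(secondary_panel$cell_line), keep)
  if (length(extra) > 0L) {
    warning("ignoring secondary lines not among primary responders: ",
            paste(extra, collapse = ", "))
    secondary_panel <- secondary_panel[secondary_panel$cell_line %in% keep, ]
  }
  call_responders(secondary_panel, alpha = alpha, min_drugs = min_drugs)
}
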