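---
title: "Models and methods behind bypassr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bypassr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bypassr)
```

`bypassr` packages two linked pieces of machinery: a forward simulator of a
pooled CRISPR knockout bypass screen (and of a multi-cell-line inhibitor
dose-response panel), and the estimators that analyse such screens —
enrichment statistics, gene-level hit calling, overrepresentation, responder
classification. This vignette explains the models, the defaults, the
numerical corner cases, and what the simulator does and does not capture.

## The screen model

A positive-selection ("bypass") screen couples three stochastic layers to
one deterministic one. `simulate_screen()` implements, in order:

1. **Plasmid representation.** Guide abundance in the plasmid pool is
   lognormal(0, σ), normalised; σ (`plasmid_skew_sigma`, default 1) controls
   how unevenly the library is represented. One pool is drawn per run and
   shared by all replicates, because replicates are infections from the same
   amplified library, not independent libraries. This matters statistically:
   cross-replicate contrasts (used by the permutation null) would otherwise
   be inflated by independent abundance draws.
2. **Infection.** The infected pool of `n_cells` cells (default 500 ×
   library size) is allocated to guides by one multinomial draw per
   replicate. Low MOI (0.2–0.5, default 0.3) justifies the single-integration
   assumption: every infected cell carries exactly one guide. Each guide's
   cells then split deterministically into a knockout fraction (its
   `efficacy`) and a residual wild-type fraction.
3. **Selection.** Cell mass grows exponentially and deterministically for
   `duration_days` (default 14): knockouts of bypass genes at `r_bypass`
   divisions/day (default 0.8) in the drug arm, everything else at
   `r_arrest` (default 0.05 — arrest is rarely absolute); the vehicle arm
   grows uniformly at `r_untreated` (default 1.0). The rate defaults give a
   strong (~2^10.5-fold) but not degenerate separation over two weeks.
   Growth stochasticity is intentionally omitted: with hundreds of cells per
   guide, allocation and sequencing noise dominate, and the deterministic
   expectation is far cheaper than clonal simulation.
4. **Sequencing.** Day-0 and day-14 samples are multinomial draws of
   `depth_per_sgrna × |library|` reads (default 200× — a typical screen
   depth; the true screen's depth is not public) from the cell-mass
   proportions. Multinomial sampling means column sums are conserved
   exactly; there is no overdispersion knob in this version (a documented
   extension point).

The default library follows the GeCKOv2 design: 19,050 genes at 5–6 guides
per gene plus 1,000 non-targeting controls (the published library's exact
control and miRNA composition is not modelled; its reported guide total is
itself stated inconsistently — ~123,441 in one place, 123,411 in another —
and the generator forces neither). Spacers are distinct uniform 20-mers;
`emit_fastq()`/`count_reads()` round-trip counts through reads of the form
`adapter + spacer + fill` so the quantification path can be tested
end-to-end.

## Enrichment statistics

Counts are normalised to reads-per-million per sample. For fixed-length
guide cassettes RPKM is RPM times a constant, which cancels in fold changes,
so RPM is the working unit; `log2(RPM + c)` is reported alongside as the
log-scale abundance. Replicates are averaged within timepoint *before* the
ratio (the alternative — averaging per-replicate fold changes — differs
whenever day-0 abundances differ between replicates; the choice is pinned by
a regression test, and per-replicate fold changes are emitted for
sensitivity analyses). The pseudocount (default 1 RPM) guards zeros and is
configurable.

Three one-sided p-value methods are offered, because two replicates
under-power any parametric per-guide test:

* **robust_z** (default): `z = (fc − median) / (1.4826 · MAD)`, upper normal
  tail. Robust location/scale because true hits are a small minority.
* **control_null**: add-one empirical upper tail against the non-targeting
  control fold-change distribution — the controls experience the same
  arrest, so they form a natural null.
* **permutation**: timepoint labels of the replicate samples are permuted in
  every balanced way and the permuted fold changes of *all* guides are
  pooled into one null. With two replicates per timepoint only six balanced
  relabelings exist, so a per-guide permutation p could never fall below
  1/7; pooling across guides restores resolution and is the standard screen
  fix.

A known limitation, measured by the test suite's null-calibration check
(2,000-gene library, ~12,000 guides, 200× depth): under the default
representation skew (σ = 1) the two empirical nulls hold their nominal
type-I error at α = 0.05, but **robust_z is anti-conservative (~0.08)**,
because fold-change variance scales inversely with guide abundance and a
single pooled MAD understates the tail scale of low-abundance guides. Under
homoscedastic fold changes (weak skew) robust_z calibrates exactly. This
does not affect hit calling at the default thresholds — a log2FC ≥ 2
requirement sits far outside sampling noise at 200× depth — but robust_z
p-values near the threshold should not be taken at face value on heavily
skewed libraries; prefer `control_null` there.

Per-gene one-sample t and Wilcoxon signed-rank tests of a gene's guide fold
changes against zero are provided (`gene_group_test()`), with deterministic
degenerate-case rules: all values exactly zero → p = 1 (no evidence), zero
variance around a nonzero mean → t p = 0 (divergent statistic).

## Hit calling

A guide passes iff `p < α` (strict) and `log2FC ≥ fc_threshold` (inclusive,
matching the "≥ 2" convention); a gene is a hit iff `≥ min_sgrnas` (default
3) of its guides pass. Controls are excluded; no gene-level multiple-testing
correction enters the decision (an advisory BH-adjusted gene p is reported).
The rule is deliberately simple — multiple independent guides converging on
one gene is itself the guard against off-target noise — and is verified
against a brute-force oracle on randomised tables, plus monotonicity checks
in all three thresholds. In recovery experiments (planted bypass genes at
efficacy ≥ 0.9, growth advantage ≥ 0.5 divisions/day, 200× depth) the caller
recovers the planted set exactly across seeds at genome scale.

Overrepresentation of the hit list uses the hypergeometric upper tail with
BH adjustment across terms. The universe defaults to the library's targeting
genes, not the genome: the screen can only nominate what it targets. BH is
applied even though small candidate lists are often reported uncorrected; it
is the stricter convention.

## The dose-response panel

`simulate_panel()` models crystal-violet absorbance at 570 nm:
`A = baseline · (1 − effect · h(dose)) + ε`, with `h` a Hill-type saturating
function of dose (half-maximal at the geometric mid-dose of the design,
`h = 0` for non-responsive pairs) and `ε ~ N(0, (noise_sd · baseline)²)`.
Defaults: doses {0.25, 1, 5} µM plus vehicle, 3 replicates (the real panel's
replicate count per dose is not public), `effect = 0.6`, `noise_sd = 0.05`.

Analysis normalises each well to the mean vehicle absorbance of its
(line, drug) — per-condition, not plate-wide — then regresses normalised
absorbance on log10(dose) over the nonzero doses and takes the one-sided p
for a negative slope from the regression t statistic (df = 7 at the default
design). Degenerate noiseless profiles are resolved by a relative tolerance
on the residual standard error: flat → p = 0.5, strictly monotone → p = 0
or 1. A line is a responder iff ≥ 2 of its drugs respond at α = 0.05;
`secondary_confirmation()` re-runs the rule on an independent panel
restricted to primary responders.

The built-in 22-line ground truth (`cdk46_panel_truth()`) plants 8
responders — the five confirmable lines MCF7, SKMEL28, ACHN, HT-29 and
SNU-387 responsive to all three inhibitors, three synthetic lines responsive
to exactly two — and 14 flat non-responders; in the secondary design only
the five confirmable lines stay responsive. Two deliberate design choices:

* **Truth stays off the decision boundary.** A line truly responsive to
  exactly one drug is one per-pair type-I error away from the responder
  call; with 42 null (line, drug) pairs tested at one-sided α = 0.05, about
  two false-positive pairs are expected per panel, and boundary lines would
  flip in ~10% of panels. Recovery experiments are meant to measure the
  classifier, not coin flips on boundary lines, so planted non-responders
  are flat. One-drug configurations remain expressible via `panel_truth()`.
* **Counts are measured as a median.** Even with flat non-responders, a
  single panel flips a line in roughly one run in ten. The acceptance
  script therefore reports the responder and confirmation counts as the
  median over 11 replicate panels seeded from the run seed — a
  variance-controlled estimate of the same quantity.

## Numerical and interface conventions

* Every stochastic function takes an integer seed and is exactly
  reproducible under it; `run_pipeline()` fans one run seed into fixed
  per-stage substreams so stages rerun in isolation reproduce their
  artifacts, and logs config, seed and input checksums as JSON.
* Read assignment is exact 20-mer matching at a fixed (or auto-detected)
  offset; optional single-mismatch rescue assigns only unique neighbours and
  never double-counts — ambiguous reads stay unassigned. Reads shorter than
  `offset + 20` are unassigned, not errors.
* Coverage "detected" means ≥ `min_reads` (default 1) — the minimal reading
  of the conventional > 88% day-0 QC bound; the floor is exposed because the
  convention varies.
* Empirical p-values use add-one smoothing (never exactly zero); BH is
  `stats::p.adjust`; the hypergeometric tail is `stats::phyper`, checked in
  the suite against exhaustive enumeration for universes of ≤ 12 genes.

## What the simulator does not capture

No PCR jackpots or sequencing overdispersion beyond multinomial; no multiple
integrations, clonal drift, apoptosis, or drug-withdrawal arms; guide
efficacy is a fixed per-guide fraction rather than a distribution over
editing outcomes; panel noise is Gaussian and homoscedastic. Passing
recovery tests therefore shows that the estimators invert the modelled noise
sources correctly — not that they are robust to every artefact of real
screens. Gene symbols beyond F9/PROZ and the five confirmable panel lines
are synthetic placeholders (`BYPASS03`…, `SYN06`…), not claims about real
genes or cell lines.

## Problem sizes used in the checks

The test suite runs libraries of 60–2,000 genes (up to ~12,000 guides) for
distributional checks and the full 19,050-gene design for the
library-structure, recovery and coverage checks; panel checks use the
22-line design across 50 seeds. The acceptance script runs the genome-scale
screen twice (hit recovery, coverage), a 2,000-gene screen (per-gene guide
enrichment), and 11 replicate panels; it completes in well under a minute on
one core.
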