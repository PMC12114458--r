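---
title: "Label-free cytometric MBC determination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free cytometric MBC determination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocide)
```

## The problem

Standard disinfectant efficacy testing determines the minimum bactericidal
concentration (MBC) by quantitative suspension tests: expose a defined
inoculum to a two-fold dilution ladder of disinfectant, neutralize, plate,
incubate overnight, and count colonies. The readout takes a day or more per
round. Label-free flow cytometry replaces the plating step with a volumetric
event count: bacteria-like events are gated in scatter space and their
concentration in the treated sample, normalized between an untreated growth
control and a cell-free negative control, is compared against a cut-off.
`cytocide` implements that pipeline end to end, plus the statistics needed
to compare it against the reference method.

## Pipeline overview

1. **Ingest** (`read_events`): FCS 3.0/3.1 list-mode files or CSV with a
   JSON metadata sidecar. Acquisition metadata (flow rate, volume, duration)
   is carried with every event table because the readout is a *rate*.
2. **Threshold** (`apply_event_threshold`): drop events below the
   acquisition trigger level on FSC-H (default 1000), mirroring the
   instrument-side threshold that suppresses electronic noise.
3. **Doublet exclusion** (`exclude_doublets`): coincident particles inflate
   pulse area relative to height; events whose SSC-A/SSC-H ratio exceeds
   the median by more than `k` median absolute deviations (default k = 3)
   are removed.
4. **Bacteria gate** (`build_bacteria_gate`): SYTO9-positive events of the
   stained growth control are back-gated onto (log10 FSC-H, log10 SSC-H);
   the gate is the convex hull of the smallest set of 64 x 64 histogram
   bins covering 98% of those events. The SYTO9 positivity cut is the
   99.5th percentile of an unstained control when available, otherwise an
   absolute default.
5. **Quantify** (`count_rate`, `normalize_rate`): gated events per second;
   normalized count = (rate − rate_NC) / (rate_PC − rate_NC), clamped at 0.
6. **Call** (`classify_concentration`, `call_mbc`): a concentration is
   bactericidal-equivalent when its normalized count is strictly below 0.1;
   the MBC is the lowest concentration of the contiguous killing run from
   the top of the ladder.

`run_pipeline` orchestrates 2–6 for one assay and keeps a per-step event
count audit (raw ≥ thresholded ≥ singlet ≥ gated for every sample).

## The synthetic cytometer

No instrument data ships with the package; all tests and examples run on a
generative model (`synthetic_config`, `simulate_experiment`) whose ground
truth is known by construction:

- **Populations**: intact cells (bivariate log-normal, log10 FSC-H mean
  4.0, SSC-H 3.7, sd 0.12, correlation 0.6), membrane-damaged cells
  (FSC shifted −0.3 decades, SSC spread ×1.5), plus sub-cluster debris and
  electronic noise drawn from exponentials. The damaged-population shift is
  a placeholder magnitude: real damage signatures vary by species and
  chemistry, and nothing downstream depends on its exact value.
- **Kill curve**: survival(c) = floor + (1 − floor) / (1 + (c/c50)^hill),
  a four-parameter Hill drop. Expected intact events in a treated sample
  are n0 · growth_factor · survival(c); killed cells reappear as damaged
  events, which is exactly what makes gated counts a *proxy* for viability
  rather than viability itself.
- **Acquisition artifacts**: a configurable fraction of doublets (area
  gain 2.0 vs the singlet 1.5, height gain 1.3), Poisson event counts
  scaled by acquisition duration, and an optional 2 × 2 FL1/FL3 spillover.
- **Determinism**: every sample draws from an isolated RNG substream keyed
  by (seed, role, concentration), so single samples are reproducible
  regardless of simulation order, and nothing leaks into the caller's RNG
  state.

The generator is deliberately simple: no day effects, no carryover, no
instrument drift, single-species samples only. It exists to give the
pipeline a falsifiable ground truth, not to imitate any particular
instrument.

## Dual-stain viability arm

`quadrant_fractions` implements SYTO9/PI quadrant analysis for sub-MBC
exposures: cuts are per-channel 99.5th percentiles of the unstained control
on the log10 scale, at most 5000 events are analyzed (seeded uniform
subsample beyond that), and the FL1+/FL3+ double-positive quadrant is
reported as "membrane-compromised / VBNC-candidate" — a dye phenotype, not
a viability claim. `estimate_spillover` and `compensate` handle two-color
spillover from single-stain controls.

## Method-comparison statistics

- `categorical_agreement` / `essential_agreement`: exact concordance and
  ±k doubling-dilution agreement (|log2(MBC_FCM / MBC_std)| ≤ k, default
  k = 1), with censored calls excluded from the denominator.
- `roc_analysis`: the score is the normalized count and *lower is
  positive*; thresholds sweep the observed scores, AUC is the trapezoidal
  area (equal to the normalized Mann–Whitney U, tie credit 0.5), and the
  operating point maximizes Youden's J with ties broken toward higher
  specificity.
- `welch_t`, `kruskal_wallis`: thin wrappers over `stats::t.test` and
  `stats::kruskal.test` with defined behavior on degenerate (constant)
  input.
- `log_reduction`: censored log10 reduction against the ≥5-log
  bactericidal criterion used by quantitative suspension tests.

The package also bundles a published-style reference panel
(`suspension_mbc_panel`, `fcm_agreement_counts`: 14 ESKAPEE-group strains
× 5 disinfectants) used by the acceptance checks and the worked examples.

## Numerical and design choices

- **Cut-off 0.1 on the normalized scale.** The source protocol's "below
  10%" rule is read as *normalized* count < 0.1 (strictly below), which is
  invariant to common background and to acquisition volume. An absolute
  10%-of-control reading differs only when NC rates are large; the strict
  inequality makes the boundary case reproducible.
- **Strict contiguity for the MBC call.** An isolated passing well below a
  failing one does not move the call (policy `"strict"`); the permissive
  `"lowest_passing"` policy is available for sensitivity analysis.
- **All-kill ladders** are called at the lowest tested concentration with
  `below_range = TRUE` rather than censored, keeping log2 comparisons with
  the reference method well defined.
- **Boundary conventions**: events exactly at the FSC-H threshold are
  kept; points on a gate edge are inside; quadrant events at a cut are
  positive. Each is pinned by a unit test.
- **Grid sizes**: the 64 × 64 back-gating histogram and 98% density mass
  trade gate tightness against stability at a few thousand control events;
  both are configuration parameters, not constants.
- **Problem sizes in tests** (event counts of a few hundred to a few
  thousand, 200-experiment recovery sweeps) are chosen so the whole suite
  runs in well under a minute on one CPU while keeping Monte-Carlo margins
  comfortable.

## Limitations

- Gated scatter counts include membrane-damaged but particle-intact cells;
  log-reduction claims therefore use viable-count inputs (the
  suspension-test emulator `simulate_suspension_test`), not gated counts.
- The ±2 pp quadrant-recovery tolerance and the 95% MBC-recovery bound are
  properties of this generator at the tested sizes, not instrument
  guarantees.
- FCS support covers list-mode integer/float files with the keywords the
  pipeline needs; it is not a general-purpose FCS library.

## Reproducing the headline figures

`scripts/acceptance.R --seed <int> --out results/acceptance.json`
recomputes the pooled agreement percentages, the discordance count, a
seeded ≥5-log reduction and the reference-panel median MBC from scratch
through the installed package.
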