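# cytocide

Label-free flow-cytometric determination of disinfectant bactericidal
efficacy, with the statistics needed to compare it against standard
quantitative suspension tests.

## The problem

The reference method for the minimum bactericidal concentration (MBC) of a
disinfectant is a quantitative suspension test: expose a defined bacterial
inoculum to a two-fold dilution ladder, neutralize, plate, incubate
overnight, count colonies. The answer takes a day or more. Label-free flow
cytometry gets a same-day surrogate: gate bacteria-like events in scatter
space (no stains needed on the treated samples), count them volumetrically,
normalize each treated sample's event rate between an untreated growth
control (defined as 1) and a cell-free negative control (defined as 0), and
call a concentration bactericidal-equivalent when its normalized count
falls strictly below 0.1. The MBC is the lowest concentration of the
contiguous killing run from the top of the ladder.

## What the package provides

- **FCS I/O** — minimal FCS 3.0/3.1 list-mode reader and FCS 3.1 writer
  (plus CSV with a JSON metadata sidecar), carrying the flow rate, volume
  and duration that turn counts into rates.
- **Gating** — FSC-H event threshold, pulse area-vs-height doublet
  exclusion, and a density-based bacteria gate back-gated from
  SYTO9-positive growth-control events onto log scatter space.
- **Quantification & MBC calling** — control-anchored normalized counts,
  strict-contiguity MBC calls on two-fold ladders, censoring semantics for
  out-of-range ladders, and EN 13727-style ≥5-log10 reduction checks.
- **Method comparison** — exact categorical and ±k doubling-dilution
  essential agreement, ROC analysis with a lower-is-positive orientation
  (AUC = normalized Mann–Whitney U), Welch and Kruskal–Wallis wrappers
  with defined degenerate behavior.
- **Dual-stain viability arm** — SYTO9/PI quadrant fractions with
  control-anchored cuts, event cap, and two-color spillover estimation and
  compensation; double positives are reported as membrane-compromised /
  VBNC-candidate.
- **Synthetic cytometer** — a seeded generative model (scatter mixture
  populations, Hill kill curve, doublets, spillover, Poisson event counts)
  providing ground truth for every test; no instrument data is required.
- **Pipeline & CLI** — `run_pipeline()` per assay with a per-step event
  count audit, `run_pipeline_files()` over a validated sample plan, and a
  command-line front end (`inst/cli/cytocide.R`) with verbs `simulate`,
  `gate`, `call-mbc`, `agreement`, `vbnc`, `run`.

A bundled reference panel (14 ESKAPEE-group strains × 5 disinfectants;
`suspension_mbc_panel()`, `fcm_agreement_counts()`) supplies the
method-comparison worked examples and acceptance checks.

## Worked example

Simulate one assay (five-point two-fold ladder, 50% kill at concentration
2, Hill slope 4), run the full pipeline, and compare the call against the
generator's truth:

```r
library(cytocide)

cfg <- synthetic_config(seed = 7, n0_events = 300, growth_factor = 15,
                        kill = kill_curve(c50 = 2, hill = 4))
ex <- simulate_experiment(cfg)
ex$growth_control
#> <event_table> growth_control: 4691 events x 8 channels (FSC-H, FSC-A, SSC-H, SSC-A, FL1-H, FL1-A, FL3-H, FL3-A)
#>   acquisition: 25.0 uL at 35.0 uL/min (42.9 s)

res <- run_pipeline(ex)
res$counts[, c("sample_id", "role", "concentration", "n_gated", "rate", "normalized")]
#>          sample_id             role concentration n_gated   rate normalized
#> 1   growth_control   growth_control            NA    4360 101.73     1.0000
#> 2 negative_control negative_control            NA       0   0.00     0.0000
#> 3               10          treated        10.000     158   3.69     0.0362
#> 4                5          treated         5.000     293   6.84     0.0672
#> 5              2.5          treated         2.500    1380  32.20     0.3165
#> 6             1.25          treated         1.250    3636  84.84     0.8339
#> 7            0.625          treated         0.625    4230  98.70     0.9702

res$mbc
#> <mbc_call> status=called mbc=5 (threshold 0.1, strict policy)
true_mbc(cfg)
#> [1] 5
```

Method comparison on paired MBC calls:

```r
essential_agreement(c(2.5, 5, 1.25), c(2.5, 2.5, 5))
#> $n_within_k
#> [1] 2
#> $n_evaluable
#> [1] 3
#> $n_censored
#> [1] 0
#> $percent
#> [1] 66.7
```

## Command line

```sh
Rscript inst/cli/cytocide.R simulate --seed 7 --out assay/
Rscript inst/cli/cytocide.R run --plan assay/plan.csv --out report.json
```

## Documentation

Function documentation lives in the roxygen comments in `R/`; the methods
and design-notes vignette is `vignettes/label-free-mbc.Rmd` (model
description, numerical conventions, limitations).
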