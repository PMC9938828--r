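# ptewater

Contamination indices and probabilistic health-risk assessment for
potentially toxic elements (PTEs) in drinking water.

Water-quality monitoring campaigns measure trace metals — here lead,
mercury, manganese and iron — in tap water across sites and seasons, and
then have to answer three questions: is the water contaminated relative to
regulatory standards, what ingestion risk does it pose to children and
adults, and how robust are those answers to uncertainty in the exposure
inputs? `ptewater` implements the standard assessment chain for analysts
and environmental-health researchers working with such data:

* **Contamination indices** — per-metal contamination factor
  `Cf = M/S − 1`, degree of contamination `Cd = Σ Cf`, and the heavy-metal
  pollution index `HPI = Σ WᵢQᵢ / Σ Wᵢ` with `Wᵢ = k/Sᵢ` and
  `Qᵢ = |Mᵢ − Iᵢ|/|Sᵢ − Iᵢ| × 100`, with their classification bands
  (`Cd < 1` significantly low; `HPI < 50` excellent).
* **Deterministic ingestion risk** — chronic daily intake
  `CDI = C·IR·EF·ED / (f·BW·AT)` (mg/kg/day), hazard quotient
  `HQ = CDI/RfD` (TDI for Pb), hazard index `HI = Σ HQ`, and carcinogenic
  risk `CR = CDI·SF` for slope-factor metals, for child and adult receptor
  profiles.
* **Monte Carlo uncertainty** — 10,000-repetition propagation with
  log-normal concentrations, truncated-normal intake rate, triangular
  exposure frequency and log-normal body weight, plus signed
  rank-correlation contribution-to-variance sensitivity analysis.
* **Seasonal statistics** — Lilliefors-screened Welch-t / Mann–Whitney
  seasonal comparisons and Spearman correlation matrices with
  weak/moderate/strong bands.
* **Synthetic data** — a seeded generator emulating a 45 + 45 sample
  two-season survey from per-metal seasonal moments, so everything above is
  testable without external data.

Regulatory standards (EPA/WHO), ideal values, RfD/TDI/SF constants and the
receptor exposure profiles ship as editable YAML registries
(`inst/extdata/`), so other agencies, metals or receptors are drop-in.

## Worked example

```r
library(ptewater)

s <- generate_samples(seed = 1)        # 90 synthetic samples, 45 per season
summarize_samples(s, metal = "Fe")
#> # A tibble: 2 × 7
#>   metal season     n   min   max  mean    sd
#> 1 Fe    winter    45 0.768  26.6  7.47  5.15
#> 2 Fe    summer    45 5.39   15.5 10.1   2.52

compute_indices(summarize_samples(s))$indices
#> # A tibble: 4 × 7
#>   agency season    cd cd_class            hpi hpi_table hpi_class
#> 1 EPA    winter -3.75 significantly_low 19.8      20.1  excellent
#> 2 EPA    summer -3.83 significantly_low 14.9      15.2  excellent
#> 3 WHO    winter -3.88 significantly_low  4.72      4.74 excellent
#> 4 WHO    summer -3.89 significantly_low  3.72      3.74 excellent

compute_risk(summarize_samples(s))$hazard
#> # A tibble: 6 × 4
#>   group    season            hi hi_class
#> 1 children winter        0.127  acceptable
#> 2 children summer        0.0839 acceptable
#> 3 adults   winter        0.0342 acceptable
#> 4 adults   summer        0.0226 acceptable
#> 5 adults   winter+summer 0.0567 acceptable
#> 6 children winter+summer 0.211  acceptable

run_hi_mcs("children", mcs_config(n_iter = 10000, seed = 1))
#> <mcs_result: HI_children> 10000 repetitions (seed 1)
#>   mean 0.1003; percentiles: 5% = 0.03465, 95% = 0.2075
#>   sensitivity (%): C_Hg +64.4, IR +13.7, BW -12.8, EF +6.2, C_Pb +2.8, ...
```

Reading the output: every seasonal degree of contamination is far below 1
(significantly low) and every HPI far below 50 (excellent); hazard indices
stay below 1 for both receptors, i.e. no appreciable noncarcinogenic risk;
and the children's Monte Carlo hazard index centres near 0.10 with a 90%
interval of roughly 0.03–0.21, driven mainly by the mercury concentration
and the intake rate, with body weight acting protectively (negative
contribution).

`run_pipeline(out_dir = "results", seed = 1)` runs all stages on one sample
table and writes tidy CSV/JSON reports plus a closing manifest. A thin
shell wrapper with `synth | indices | risk | mcs | stats | run-all`
subcommands is installed at `inst/scripts/ptew.R`.

## Documentation

The methods vignette (`vignettes/pte-water-assessment.Rmd`) explains the
model equations and their assumptions, the printed-table emulation modes,
the Monte Carlo design (including the assumed 20% coefficients of
variation for intake rate and body weight and what that implies for
validation), the statistical stage, and what the synthetic generator does
and does not emulate.
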