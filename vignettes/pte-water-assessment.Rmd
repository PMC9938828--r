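---
title: "Assessing potentially toxic elements in drinking water: indices, ingestion risk and Monte Carlo uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing potentially toxic elements in drinking water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptewater)
```

## The problem

Tap water carries trace concentrations of potentially toxic elements (PTEs)
— here lead, mercury, manganese and iron — picked up from source water,
treatment residuals and the distribution network itself (lead solder and
brass fittings, iron pipe corrosion, manganese breakthrough). A monitoring
campaign produces per-site, per-season concentration tables; the questions
that follow are always the same. Is the water contaminated relative to
regulatory standards? What dose do people actually ingest, and is the
noncarcinogenic and carcinogenic risk acceptable? How robust are those
answers to the uncertainty in every exposure input? `ptewater` implements
that assessment chain end to end, with a seeded synthetic-sample generator
so the whole pipeline can be exercised and tested without any external
data. The packaged defaults emulate a two-season urban survey of 45 winter
and 45 summer tap-water samples per metal.

## Contamination indices

For metal $i$ with measured (seasonal mean) concentration $M_i$ and
permissible standard $S_i$ (µg/L), the contamination factor and degree of
contamination are

$$Cf_i = \frac{M_i}{S_i} - 1, \qquad C_d = \sum_i Cf_i,$$

with $C_d \le 1$ read as significantly low contamination, $1 < C_d \le 3$
moderate and $C_d > 3$ high. The heavy-metal pollution index is the
weighted arithmetic mean of sub-indices,

$$HPI = \frac{\sum_i W_i Q_i}{\sum_i W_i}, \qquad
  W_i = \frac{k}{S_i}, \qquad
  Q_i = \frac{|M_i - I_i|}{|S_i - I_i|} \times 100,$$

where $I_i$ is the ideal concentration (0 for Pb, Hg and Fe; 100 µg/L for
Mn) and $k = 1$. The absolute differences in $Q_i$ keep the sub-index
well-defined when $I_i > S_i$, as for Mn under the EPA standard. HPI
below 50 is excellent water; the index is invariant to rescaling all
weights, so the choice of $k$ cancels.

Two numerical conventions deserve explanation:

* **Band edges.** The customary band definitions use strict inequalities
  and leave $C_d = 1$, $C_d = 3$ (and $|\rho| = 0.5, 0.7$ for correlation
  strength) unassigned. `classify_cd()` assigns edges to the
  lower-severity class; `classify_correlation()` assigns them to the
  higher band, matching how the band lists are written
  (e.g. "good (50–99.99)" puts 50 in *good*). Both rules are documented on
  the classifiers.
* **Printed-table emulation.** Published index tables round and truncate
  intermediate columns: weights are displayed to four truncated decimals,
  sub-indices and their products to two rounded decimals, and the two
  column sums are truncated to two decimals before the final division.
  `hpi(..., rounding = "table")` reproduces that arithmetic; the default
  `rounding = "full"` keeps full precision and is what new analyses should
  use. On the packaged reference means the two modes give 20.82 vs 20.47
  (EPA, winter) — the gap is entirely display arithmetic, and both sit far
  inside the *excellent* band. The same truncating display convention
  (`trunc_decimals()`) is used wherever computed values are compared
  against published table displays.

```{r}
idx <- compute_indices(reference_summary())
idx$indices
```

## Deterministic ingestion risk

The chronic daily intake for a receptor drinking the water is

$$CDI = \frac{C \times IR \times EF \times ED}{f \times BW \times AT}
  \quad \text{(mg/kg/day)},$$

with $C$ the concentration (µg/L), $IR$ the intake rate (children
1.25, adults 1.95 L/day), $EF$ the exposure frequency (days/year,
triangular 180/345/365), $ED$ the exposure duration (6 / 50 years), $f =
1000$ the µg→mg conversion and $BW$ the body weight (10.64 / 61.68 kg).
The averaging time is $AT = ED \times 365$ days for the noncarcinogenic
endpoint — so $ED$ cancels — and $70 \times 365$ days for the carcinogenic
endpoint. Point estimates evaluate $EF$ at its mode (345 days/year): that
is the value under which the computed child intakes agree with the
reference survey's reported means (e.g. Mn winter 0.00025 mg/kg/day),
whereas 365 days/year does not reproduce them. `cdi()` keeps `ef` an
explicit argument.

Noncarcinogenic risk divides by the safe dose, $HQ = CDI/\mathrm{RfD}$
(RfD 0.0003 for Hg, 0.14 for Mn, 0.7 for Fe mg/kg/day; Pb uses its
tolerable daily intake, 0.0035 mg/kg/day), and sums to the hazard index
$HI = \sum_m HQ_m$; both are acceptable below 1. Carcinogenic risk is the
linear dose–response $CR = CDI \times SF$ with Pb's slope factor 0.0085
kg·day/mg, read against the USEPA bands ($<10^{-6}$ negligible,
$10^{-6}$–$10^{-4}$ threshold, $>10^{-4}$ potent). Only metals carrying a
slope factor enter the CR block — Pb alone in the default registry, but
the registry is extensible.

```{r}
risk <- compute_risk(reference_summary())
risk$hazard
```

## Monte Carlo uncertainty and sensitivity

Single-number risk estimates hide the variability of every input.
`run_mcs()` propagates distributions through the same equations:
concentrations are log-normal (moment-matched to each season's mean and
sd; by default the two seasons are pooled as an equal-weight mixture),
intake rate is normal truncated at zero, exposure frequency triangular,
body weight log-normal, and ED, AT, RfD and SF are fixed. 10,000
repetitions are the default.

The survey reports no dispersion for IR or BW, only their families. Both
coefficients of variation therefore default to 20% — an explicit,
overridable assumption, flagged in the pipeline manifest, and the reason
the Monte Carlo means are validated as brackets and orderings rather than
exact values.

Sampling is seeded hierarchically: every input derives a child RNG stream
from the root seed and its own name, so results are bit-reproducible and
adding an input leaves the other draws untouched. Moment matching for the
log-normal uses $\sigma^2_{\log} = \log(1 + (sd/mean)^2)$,
$\mu_{\log} = \log(mean) - \sigma^2_{\log}/2$; the triangular is sampled
by inverse CDF; the truncated normal by rejection (the truncation point
is 5 sd below the mean, so the acceptance rate is essentially 1). With
every spec fixed, the engine reproduces the deterministic estimate
bit-exactly — the model functions use the same operation order as the
deterministic chain on purpose.

Sensitivity uses rank-correlation contribution-to-variance, the
convention of the spreadsheet risk tools this field commonly uses: for
input $j$, $\rho_j$ is the Spearman correlation between its draws and the
output, and the signed contribution is
$\mathrm{sign}(\rho_j)\,\rho_j^2 / \sum_k \rho_k^2 \times 100$. Fixed
inputs contribute 0; absolute contributions sum to 100%. Body weight
always contributes negatively (it sits in the denominator), and the
pooled Pb concentration — whose summer sd (0.62 µg/L on a mean of 0.50)
makes it by far the widest input — dominates the carcinogenic-risk
variance. Variance-based Sobol indices are out of scope.

```{r}
run_hi_mcs("children", mcs_config(n_iter = 5000, seed = 1))
run_cr_mcs("children", mcs_config(n_iter = 5000, seed = 1))
```

## Seasonal statistics

`compare_seasons()` reproduces the survey's statistical stage: each
season is screened for normality and the seasonal difference is tested
with a two-sided Welch t-test when both seasons pass, a Mann–Whitney
rank-sum test otherwise, at $\alpha = 0.05$. The normality screen
defaults to the Lilliefors-corrected Kolmogorov–Smirnov test
(`nortest::lillie.test`), which stays calibrated when mean and sd are
estimated from the data — the behaviour of the SPSS procedure this kind
of survey typically uses; the uncorrected KS variant is available as
`method = "ks"` for comparison. Whether the original analysis assumed
equal variances is not stated; Welch's form is the safer default. The
equal-variance t-test is not exposed. No multiple-testing correction is
applied across metals, matching the conventional reporting of such
surveys.

`spearman_matrix()` computes pairwise Spearman correlations with
asymptotic two-sided p-values and classifies strengths as weak
($|\rho| < 0.5$), moderate ($0.5 \le |\rho| < 0.7$) or strong
($|\rho| \ge 0.7$). Constant columns make the coefficient undefined and
are reported as `NA` with a warning rather than silently dropped.

## The synthetic generator

`generate_samples()` draws each metal × season cell from the
moment-matched log-normal of the reference statistics — log-normal
because that is the family the field's own uncertainty analyses assign
to concentrations, and because concentrations are positive and
right-skewed. Truncation to the reference min–max range is available but
off by default, since truncation biases the moments the generator is
supposed to reproduce. Site coordinates are cosmetic jitter inside a
bounding box; there is no spatial model, no measurement-error model and
no between-site correlation structure. Metals are independent by
default; `inject_correlation()` rearranges one metal's values through a
Gaussian-copula rank coupling (copula correlation
$2\sin(\pi\rho_s/6)$) to hit a target Spearman correlation without
touching the marginal values, which is exactly what testing the
correlation stage needs.

What passing tests on synthetic data do show: the index and risk
equations, classifications, calibration of the test procedure (type-I
error ≈ 5% on null data), the power to detect the reference seasonal
iron shift, and recovery of the generator's own moments. What they do
not show: anything about spatial structure, detection limits, censoring,
or analytical measurement error in real surveys — none of which the
generator emulates.

A note on moment recovery: at $n = 45$ the sample *sd* of a heavy-tailed
log-normal (Mn in winter has cv ≈ 1.7) is noticeably biased low, so the
generator's spread is validated on the variance scale, where the sample
variance is unbiased at any $n$.

## Problem sizes and determinism

The shipped tests run the Monte Carlo stages at 10,000 repetitions,
distributional checks at up to $10^6$ draws, and the calibration
simulations at 200 seeds of the full 90-sample survey — sizes chosen so
the whole suite completes in a few minutes on a single core while
keeping Monte Carlo standard errors far below the tolerances being
asserted. Every stochastic stage takes an explicit seed; identical seeds
give byte-identical outputs, including the pipeline's JSON reports.

## Known limitations

* Ingestion is the only exposure route; dermal and inhalation pathways
  are out of scope.
* The printed-table emulation reproduces published displays up to their
  own internal rounding inconsistencies, which are documented rather than
  imitated cell by cell; full-precision results are always reported
  alongside.
* Monte Carlo input distributions are sampled independently; real
  exposure inputs may be correlated, but no correlation structure is
  asserted by the underlying survey.
* The IR and BW coefficients of variation are assumptions (20%), so
  Monte Carlo sensitivity percentages are qualitative (signs and
  rankings), not exact targets.
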