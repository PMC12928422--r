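---
title: "Methods: TEQ scoring, cancer-risk estimation and Monte Carlo uncertainty for PAHs in bread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TEQ scoring, cancer-risk estimation and Monte Carlo uncertainty for PAHs in bread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem

Polycyclic aromatic hydrocarbons (PAHs) form during high-temperature baking,
especially in direct-fired traditional ovens, and several congeners are
carcinogenic. Where bread is a dietary staple, chronic low-level PAH intake
is a population-scale exposure worth quantifying. `pahrisk` implements the
full chain from a per-sample congener concentration table to a probabilistic
cancer-risk statement: toxic-equivalency scoring, a dietary dose equation,
risk-band classification, Monte Carlo uncertainty propagation and a
contribution-to-variance sensitivity analysis, together with a synthetic
study generator that makes every stage testable without measured data.

## The model

### Toxic equivalents

Congener potencies differ by orders of magnitude, so a mixture is collapsed
to the equivalent concentration of the reference carcinogen
benzo[a]pyrene (BaP):

$$\mathrm{TEQ} = \sum_{i=1}^{16} C_i \cdot \mathrm{TEF}_i
\quad [\mu g\ \mathrm{BaPeq}/kg],$$

with toxic equivalency factors TEF in {0.001, 0.01, 0.1, 1}; BaP and
dibenz[a,h]anthracene carry TEF = 1. The registry
(`pah_registry()`) fixes the 16 congeners, their ring counts (2–3 rings =
light, 4–6 = heavy), TEFs, and detection/quantification limits with
LOQ = 3 × LOD. TEQ is linear, so the TEQ of a group-mean concentration
vector equals the mean of per-sample TEQs; `group_summary()` exploits this
and reports the sample SD of per-sample TEQs as the TEQ spread.

### Dose and lifetime risk

Daily dietary exposure is $ED = \mathrm{TEQ} \times IR$ (µg BaPeq/day), and
the incremental lifetime cancer risk is

$$\mathrm{ILCR} = \frac{\mathrm{TEQ}\cdot IR\cdot EF\cdot ED_y\cdot
\mathrm{CSF}\cdot CF}{BW\cdot AT},$$

with intake rate $IR$ (kg/day), exposure frequency $EF$ (days/year),
exposure duration $ED_y$ (years), body weight $BW$ (kg), averaging time
$AT$ (days), oral cancer slope factor CSF and unit conversion CF. The adult
defaults (IR 0.23, EF 365, ED 70, BW 70, AT 25550) make the time ratio
$EF\cdot ED_y/AT$ exactly 1. Risks are banded at the conventional
thresholds: below 10⁻⁶ negligible, 10⁻⁶–10⁻⁴ (closed interval) acceptable,
above 10⁻⁴ high.

Two constant sets are shipped. `paper_compat` (CSF = 1, CF = 0.1) is the
set under which the source survey's printed TEQ-to-risk pairs are
reproduced to their printed precision; the survey never states CF, and 0.1
is the unique decade factor consistent with its tables. `usepa_standard`
(CSF = 7.3 per the USEPA oral slope factor for BaP, CF = 10⁻³ for µg→mg)
is the dimensionally conventional set. The mode is explicit in every
output; the two differ by a constant factor ~73.

### Left-censored values

Non-detects (value below the congener's LOD) are carried as censored
entries and substituted only at analysis time via `apply_censoring()`:
`zero`, `half_lod`, or `lod`. Substitution is entry-wise, idempotent and
monotone (`zero ≤ half_lod ≤ lod`), so a TEQ under the three policies
brackets the censoring uncertainty. The default is `zero`: it is the
convention under which the survey's summary TEQ of 0.18 µg BaPeq/kg is
reproduced from its printed zone means. `half_lod` is the textbook choice
for dietary exposure work and is a one-argument switch. Censoring is
strict (`value < LOD`); a value exactly at the LOD is a detection, since
the LOD is itself defined as the 3:1 signal-to-noise detection boundary.

When a file carries an explicit `censored` column, that flag is
authoritative; the `< LOD` auto-rule applies only to unflagged rows. This
matters for tables of *summary* rows: a mean of several samples can
legitimately fall below the LOD (the shipped zone table's BaP means do)
without being a non-detect.

## Monte Carlo layer

Input uncertainty is declared per variable with `dist_spec()`:
concentrations lognormal (right-skewed environmental data), body weight
normal, exposure frequency/duration uniform, constants point masses.
Lognormal specs are parameterised by arithmetic mean and SD and
moment-matched ($\sigma^2 = \ln(1+sd^2/m^2)$, $\mu = \ln m - \sigma^2/2$),
which preserves the arithmetic mean — so by linearity of the TEQ the Monte
Carlo mean TEQ equals the deterministic TEQ of the means up to sampling
error, a property the tests assert.

Numerical choices:

* **Seeding.** One master seed; each variable's stream is derived from a
  hash of its name, so adding or removing a variable never perturbs the
  draws of the others, and a run is bit-reproducible end to end.
* **Truncation.** Physical quantities are floored at 0 by *resampling*
  offending draws, not clipping, which would distort moments.
* **Iterations.** Default 100,000 — the scale at which the summaries
  reported here stabilise well below the percent level. Tests and examples
  use smaller runs sized to the quantity they check.
* **Intervals.** The 95% interval is the empirical 2.5th/97.5th sample
  percentile; no distribution is fitted to the output.
* **Degeneracy.** With all-point specs the sampled outputs equal the
  deterministic pipeline values exactly (the TEQ is accumulated in a fixed
  summation order rather than through BLAS matrix–vector kernels, whose
  row-dependent rounding would otherwise leave ulp-level noise).

`concentration_specs()` fits per-congener lognormal specs from a table's
sample moments. It uses the values *as stored*, before ND substitution:
fitting a lognormal to zero-substituted data biases congeners that sit
near their detection limit (BaP's mean in these data is at its LOD), and
in small studies that bias is large enough to scramble the sensitivity
ranking. Always-censored congeners become point masses at zero.

### Sensitivity

`contribution_to_variance()` implements the signed
contribution-to-variance convention used by risk-assessment spreadsheets:
per input the Spearman rank correlation $r_i$ with the output, and share
$\mathrm{sign}(r_i)\,100\,r_i^2/\sum_j r_j^2$, so absolute shares sum to
100% and the sign records the direction of influence (body weight comes
out negative: heavier individuals receive a smaller dose per kg). Shares
are rank-based and therefore invariant under any strictly increasing
transform of an input. Inputs sampled jointly, as the engine does, are
independent by construction, which is the regime in which this estimator
is interpretable; it does not decompose interactions (no Sobol indices,
no correlated-input copulas).

## Synthetic study generator

`generate_synthetic_study()` emulates the survey's factorial design:
8 zones × 2 baking methods × 3 bread types × 2 replicates = 96 samples.
Each detected congener is drawn from a moment-matched lognormal whose cell
mean is `baseline × method multiplier × type multiplier`, with a constant
per-congener CV across cells. `default_paper_model()` sets the baselines
to the survey's grand means, per-congener SDs to its mean printed
within-zone SDs (the printed dispersions, not a flat CV — this is what
makes BaP the dominant and benzo[a]anthracene the second sensitivity
driver structurally rather than by luck), a traditional/industrial ratio
of 68.63/39.87 on the Σ16 scale and bread-type multipliers proportional to
66.58/40.95/51.62 (Lavash/Sangak/Barbari), both normalised to average 1 so
the overall expectation stays at the baselines; its TEQ is ≈ 0.18. Zone
effects default to none (the survey found no significant zone
differences); a per-zone multiplier exists for stress tests.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: between-congener correlation beyond the shared
method/type factors (no covariance information is available), measurement
noise of the GC-MS method, recovery losses, and any bakery-level
clustering. Draws below a congener's LOD are flagged censored exactly as a
real measurement would be reported, but the raw draw is retained so
parameter-recovery tests can compare against the configured truth; the
three always-ND congeners (IP, DhA, BghiP) are emitted censored
everywhere. The generator constructor's fallback CV where no SD is given
is 0.5, bracketing the survey's printed SD/mean ratios.

Problem sizes used in the shipped tests: the full n = 96 design for
design-structure, ranking and 15%-level recovery checks; 500 replicates
per cell (48,000 samples) for 2%-level per-congener mean recovery;
10⁵ iterations for Monte Carlo mean-preservation (assertion at 2%, the
sampling error there being ~0.1%); 2 × 10⁴ iterations where only an
ordering is asserted.

## Pipeline and reporting

`run_pipeline()` chains load → censor → group summaries → deterministic
TEQ/ILCR per group → Monte Carlo → sensitivity, writing `results.json`,
group CSVs, sensitivity CSV and a run log that records policy, mode,
iterations, seed and package version; rerunning a config is byte-identical.
Stage failures abort with a stage label and remove partial outputs.
`render_report()` applies display rounding only (concentrations and TEQ to
2 decimals, risks to one significant figure); the bundle keeps full
precision. The report also flags the EU limits for cereal products — BaP
≤ 1 µg/kg and the PAH4 sum (BaA + CHR + BbF + BaP) ≤ 1 µg/kg — without
gating execution; note the zone-mean data are BaP-compliant while their
PAH4 sum sits marginally above 1 µg/kg, driven by chrysene.

## Known limitations

* The survey's probabilistic 95% interval cannot be regenerated exactly:
  that would require the per-sample raw data, which are not published. The
  engine's corresponding guarantees are the structural ones tested:
  mean preservation under moment-matched lognormals, exact quantile
  equivariance between TEQ and ILCR under point exposure constants, and
  exact collapse to the deterministic value under point specs.
* Dispersion parameters for IR, EF, ED, BW are this package's defaults
  (IR lognormal CV 25%, BW normal(70, 7), EF uniform(350, 365), ED uniform
  (60, 70), AT fixed), chosen as typical adult-population spreads; they
  are not survey-reported values and are fully overridable.
* Only dietary exposure through bread is modelled: no inhalation/dermal
  pathways, no other food groups, no child-specific (lower body weight)
  risk model, and no non-cancer hazard quotient.
* Recovery correction of concentrations, calibration-curve fitting and
  instrument-level QC beyond `validate_method_table()` are out of scope.
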