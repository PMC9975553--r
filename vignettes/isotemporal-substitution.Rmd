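---
title: "Isotemporal substitution of activity intensities: models, score construction and the simulated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotemporal substitution of activity intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotempo)
```

## 1. The three model families

Let $A = (SB, LPA, MPA, VPA)$ be a participant's mean daily minutes in
the four intensity bands, entered in 10-minute units, $C$ the
covariates (gender, age, resting energy expenditure) and $y$ the change
in the composite risk score. The package fits, by ordinary least
squares with classical $t$ intervals:

* **Single model** — $y = \beta A_k + \gamma C$. One band at a time;
  $\beta$ confounds the band with everything it displaces.
* **Partition model** — $y = \sum_k \beta_k A_k + \gamma C$. Each
  $\beta_k$ is an *addition* effect: 10 more minutes of band $k$ with
  the other three held fixed, so total monitored time grows.
* **Isotemporal substitution model (ISM)** — drop one band $j$ and add
  total time: $y = \sum_{k \neq j} \beta_k A_k + \beta_T\,TPA + \gamma C$
  with $TPA = SB+LPA+MPA+VPA$. Holding $TPA$ and the other retained
  bands fixed, a unit increase in $A_k$ can only come out of $A_j$, so
  $\beta_k$ estimates the effect of substituting 10 min of $k$ for $j$.

Because the ISM design spans the same column space as the partition
design, the substitution coefficient is exactly the difference of
partition coefficients, $\beta_{ISM}(k \mid j) = \beta_k - \beta_j$.
This identity is the package's central correctness oracle: the test
suite asserts it to $10^{-8}$ on arbitrary random data, with and
without covariates. It also forces the substitution matrix produced by
`substitution_matrix()` to be antisymmetric, and makes effects for a
duration $d$ scale linearly (`scale_effect()` multiplies the estimate
and both CI limits by $d/10$; the $p$-value of a positively rescaled
linear contrast is unchanged).

`fit_ism()` recomputes TPA internally as the exact sum of the four
band columns and refuses an input `tpa` column that disagrees beyond
$10^{-9}$: the substitution reading of the coefficients is a statement
about an exact linear dependence in the design, not about a measured
total. This also sidesteps rounding mismatches between a printed total
(587 vs 588 min) and the printed band means.

### Numerical choices

CIs are classical OLS $t$ intervals at 95% (the CI method is otherwise
unspecified in this literature's tables). Rank-deficient designs are
rejected with the aliased columns named; near-collinearity (condition
number above $10^8$) only warns, since ISM designs are legitimately
ill-conditioned when one band dominates. Zero residual variance (a
noise-free planted outcome) yields degenerate $p$-values; these are
reported as 0 with a warning rather than an error so that exactness
tests can still read the coefficient table.

## 2. The composite risk score

`build_cmr_z()` standardizes fasting insulin, fasting glucose, waist
circumference, total cholesterol, HDL cholesterol and mean arterial
pressure ($MAP = (SBP+DBP)/2$ here — the midpoint convention, not the
diastolic-weighted one) and sums the six z-scores. HDL is protective,
so it is multiplied by $-1$ **before** standardization; as the
z-transform is linear this equals negating the HDL z-score, and the
tests assert that identity exactly.

Two genuinely open choices are exposed as arguments:

* **Standardizing population** (`standardization`): pooled pre+post
  (default) or baseline-only. The source tables for this design report
  exactly symmetric pre/post score means (±1.39), which is an algebraic
  consequence of pooled centering and is only consistent with it, so
  pooled is the default; this is an inference from the printed
  symmetry, not a documented fact, and baseline standardization is
  retained for sensitivity analyses.
* **SD convention** (`sd_type`): sample ($n-1$, default) or population
  ($n$). The symmetry property holds either way; only the score's
  scale changes slightly.

The change convention is fixed as $\Delta = \text{post} - \text{pre}$
throughout (improvements are negative), resolving an ambiguity in how
"difference between pre and post" is often phrased.

`describe_changes()` reports mean ± SD per occasion, the paired change,
a one-way ANOVA $p$ across occasions (for two occasions this equals
the equal-variance $t$ test, an identity the tests check) and a
Shapiro–Wilk normality $p$ on the changes. `correlation_table()` gives
Pearson $r$ between each change variable and mean daily band minutes
with the usual star coding; constant columns give `NA` with a warning
rather than an error.

## 3. Accelerometer classification

Counts from a waist-worn tri-axial device, aggregated to 60-s epochs,
are scored by the Euclidean vector magnitude of the three axes and
banded by counts/min cut points (defaults SB 0–99, LPA 100–3686,
MPA 3687–5246, VPA ≥ 5247). The printed cut points are integer ranges,
so fractional magnitudes between bands are floored to the lower band
(a vm of 99.7 is SB); counts are integers in practice, so this rule
only matters for synthetic or rescaled inputs. One epoch contributes
one minute to its band; band minutes therefore always sum to wear
minutes, and increasing any single axis can never lower the assigned
band (both are tested properties).

`summarize_days()` defaults to `min_valid_days = 6` (a 3-days/week
floor over a 2-week minimum protocol). No non-wear detection is
applied by default — the intended protocol is supervised camp wear
09:00–21:00 — but a zero-run filter (`zero_run_nonwear`) is available
for unsupervised data. The upstream band labelled "MVPA" in some
descriptions of the 3687–5246 range is treated as MPA, matching how
every downstream table and model uses it. Only 60-s epochs are
supported; other epoch lengths and g-unit raw processing are out of
scope, as is any cut-point family beyond the configurable three
thresholds.

## 4. The synthetic world

No participant-level data are deposited with the source study, so the
generator *is* the package's data: it encodes the stated world and
plants known effects for recovery testing.

* **Demographics** — 196 participants, 106/196 boys; age 13.44 ± 1.71
  years; REE by gender (boys 1864.5 ± 232.4, girls 1632.7 ± 197.4
  kcal/d). Gender is coded 0 = girl, 1 = boy everywhere.
* **Activity composition** — band minutes are drawn from truncated
  normal marginals (SB 274 ± 53, LPA 241 ± 46, MPA 38 ± 14,
  VPA 35 ± 16 min/d), then proportionally rescaled and
  largest-remainder rounded so they sum *exactly* to a per-participant
  total drawn from 588 ± 67 min, capped at the 720-min wear window.
  Closing to a participant-specific total rather than to the wear
  window itself is deliberate: the monitored day leaves ~130 min of the
  wear window unclassified in the source tables, and closing to 720
  would inflate every band mean by ~22%. Marginal normals + rescaling
  were chosen over a Dirichlet because the stated world is given as
  per-band means and SDs, which the rescaled marginals reproduce.
* **Planted outcome** — $\Delta CMRz = \alpha + \sum_k \beta_k A_k/10
  + \gamma C + \varepsilon$, with default $\beta$ = (0.05, −0.05,
  −0.27, −0.34) per 10 min (the partition coefficients the recovery
  suites target), covariate effects $\gamma$ = (+0.02/yr, −0.10 for
  boys, +10⁻⁴ per kcal/d) — unstated upstream, chosen small and
  realistic — and $\varepsilon \sim N(0, 2.2)$ so that
  sd($\Delta CMRz$) lands near the reported 2.33. The intercept is set
  so the expected change at the configured means equals
  `delta_cmr_mean` (default −2.78).
* **Panels** — baseline factors are truncated normals at the reported
  baseline means/SDs (pulse pressure kept ≥ 10 mmHg). The post panel
  distributes each participant's planted score deviation across the
  six components in proportion to the reported mean change magnitudes
  (in z units), splits the MAP share between SBP and DBP, and adds
  small component noise. This keeps component-level changes realistic
  without claiming a mechanistic model; the consequence is that the
  panel-derived score change *tracks* the planted one (r > 0.9 in
  tests) but does not equal it. Exactness tests therefore use the
  planted outcome column (`analysis_table(..., outcome_source =
  "planted")`), and the pipeline defaults to the panel route — the one
  real data would take.
* **Epoch streams** — `generate_epoch_stream()` emits contiguous
  blocks per band in a fixed order with axis counts drawn inside the
  band (verified per epoch, with an exact in-band fallback), so that
  classification recovers the planted minutes with zero error. Bout
  structure is deliberately unrealistic: the substitution models
  consume only daily totals. Sleep, 30-Hz raw accelerations and
  missing-wear patterns beyond the optional zero-run mask are not
  simulated. Days per participant is a knob (`n_days`), since the
  wear-validity rule upstream is stated only as a weekly minimum.

What a green test does and does not establish: parameter recovery and
null calibration on this generator show the estimators are correct
*under the stated world* — independent Gaussian-ish marginals, a
linear outcome, one cohort, no measurement error in the minutes. They
do not validate the cut points themselves, cross-cohort
transportability, or causal readings of substitution coefficients.

## 5. Reproducibility

Every stochastic function takes an explicit seed (`cohort_config(seed=)`,
`generate_epoch_stream(seed=)`); `run_pipeline()` splits a single root
seed deterministically per stage, writes all report tables as CSV and
emits a manifest (config MD5, package and R versions, row counts). Two
runs with the same config and seed are byte-identical, which is itself
a test.

## 6. Known limitations

Compositional (log-ratio) time-use models, mixed-effects extensions,
sleep as a fifth compartment and age/sex-referenced external z-scores
are out of scope. The single-model rows are reported for comparison
but inherit that family's confounding; the partition/ISM identity, not
agreement with single models, is the correctness standard.
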