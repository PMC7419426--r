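---
title: "Task-based silica exposure modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based silica exposure modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicarisk)
```

This vignette is the package's own account of its statistical machinery:
the exposure model and its assumptions, the data-curation rules, the Monte
Carlo percentile construction, the adjustment factors, what the synthetic
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## Data curation

Archived respirable crystalline silica (RCS) measurements are heterogeneous
— peer-reviewed studies, technical reports, regulator holdings, industry
submissions — so every record passes a six-criterion QC screen before it
can enter the modelling database:

1. **Analyte** is RCS. Respirable-dust-only records are excluded; where a
   laboratory reports quartz and cristobalite masses separately,
   `consolidate_polymorphs()` sums the polymorph masses and divides by the
   air volume sampled, yielding one RCS concentration.
2. **Method** is a recognised standard (default set: NIOSH 7500 including
   its 8 LPM PPI variant, NIOSH 7602, OSHA ID-142). The list is a
   configurable argument because equivalent standard methods exist in other
   jurisdictions.
3. **Sampling parameters** (flow rate, duration) are reported and
   well-formed. Malformed numeric fields (negative concentration, a
   non-detect without a positive LOD) are reported under this criterion
   rather than raised as errors: validation must always return a complete
   report.
4. **QA/QC** adequacy and
5. **contextual completeness** ("equivalence" of operations) are
   curator-asserted booleans. The underlying judgements (calibration
   records, field blanks, sufficient task description) are not
   machine-checkable from the record itself, and inventing a proxy rule
   would hide the curatorial decision instead of recording it.
6. **Personal sampling** only; area samples do not represent breathing-zone
   exposure.

All six criteria are evaluated independently and every failure is reported,
so a QC report doubles as a data-quality audit. Non-detects are replaced by
half the limit of detection — the conventional substitution for lognormal
occupational data at modest censoring rates — and the substitution is
idempotent.

## De-aggregation of published summaries

Much of the usable literature reports only aggregates: $n$, a geometric or
arithmetic mean, and a GSD or SD. `deaggregate_summary()` converts an
aggregate into $n$ pseudo-observations by drawing from the implied
lognormal and then rescaling affinely in log space so that the empirical
geometric mean and GSD (log-SD with the $n-1$ denominator) match the
published values *exactly*, not just in expectation. Exact matching makes
downstream fits reproducible: two analysts de-aggregating the same table
with the same seeds obtain identical regression inputs. Arithmetic
summaries are first converted under the lognormal assumption,
$\ln^2 \mathrm{GSD} = \ln(1 + \mathrm{SD}^2/\mathrm{AM}^2)$, the standard
occupational-hygiene convention. Edge cases: $n = 1$ returns the GM itself;
$\mathrm{GSD} = 1$ returns $n$ identical values.

Pseudo-observations carry `source = "deaggregated"` and a `weight` field.
They enter the regression at equal weight by default: down-weighting would
require a principled variance model for the summarisation step, which is
better handled by a future hierarchical treatment than by an ad-hoc
constant.

## The exposure model

The response is $\ln C$ (mg/m³). Exposure data of this kind are
right-skewed and multiplicative: determinants scale exposure rather than
shift it, non-detects are handled multiplicatively, and a percentile
construction on the natural scale would be incoherent with either fact.
The linear predictor contains:

* an intercept (the reference scenario's log-GM);
* `log(sampling_duration)` in minutes — log-linear by default because
  duration effects on task-based averages are relative, with a `linear`
  option;
* one-hot indicators for CSP, sector, project type, environment and region,
  with the alphabetically first observed level as the reference
  (deterministic and configurable; no data-dependent tie-breaking);
* indicators for four engineering controls: local exhaust ventilation
  (LEV), tool-integrated LEV, material wetting, and tool-integrated water
  spray.

The fifth control, separation from source, is deliberately *not* a
regression term: data are too sparse to estimate it, so a fixed factor is
applied after prediction (below). `fit_exposure_model()` rejects it as a
fitted term.

Estimation is ordinary least squares via `stats::lm()` on a design matrix
built in-package (canonical term names `var=level`, `ctrl_<id>`,
`log_duration`). Term selection is configuration, not automation: the
parsimonious term list is an argument, because automated selection would
change silently as data accrue. Guard rails: a minimum cell count per
categorical level (default 5, warning below 10), constant control columns
dropped with a warning, and an explicit error listing aliased terms on
rank-deficient designs rather than silently propagating `NA` coefficients.
The fit is invariant to row order, and rescaling all concentrations by $k$
moves only the intercept by $\ln k$ — both covered by tests.

The fitted model is serialized to JSON with the term catalog, coefficient
estimates and standard errors at 17 significant digits (doubles round-trip
bit-exactly), reference levels, residual log-SD and a **database version
stamp**. Every risk estimate and ECP carries that stamp, so any archived
plan can be traced to the exact model that produced it.

## Monte Carlo upper 95th percentile

A single point estimate is deliberately conservative: the user sees the
upper 95th percentile of a Monte Carlo prediction distribution. Each of
`n_draws = 1000` draws samples every coefficient independently from
$\mathcal{N}(\hat\beta_j, \mathrm{se}_j^2)$, computes the scenario's linear
predictor, and exponentiates; the empirical 95th percentile of the draws is
reported. With all standard errors zero this reduces exactly to
$\exp(x^\top\hat\beta)$ for any seed, and for an intercept-only model it
converges to the analytic $\exp(\mu + 1.645\,s)$ — both are tested, the
latter at 200,000 draws within 1%.

Two readings of "the upper 95th percentile" are defensible: percentile of
the *parameter-uncertainty* distribution (default here), or of the
*predictive* distribution including residual variability. The default
represents uncertainty in the modelled scenario mean;
`include_residual = TRUE` adds a $\mathcal{N}(0, \hat\sigma)$ draw per
sample for the predictive reading. Coefficients are drawn independently —
only per-term means and SEs are carried in the model document — which
ignores off-diagonal covariance; for the balanced designs used here the
effect on the 95th percentile is small and conservative in the common case
of negatively correlated intercept/effect pairs.

Adjustments apply in a canonical audited order (all are scalar multipliers,
so the order affects only the audit trail, not the result):

1. fitted control terms (inside the linear predictor);
2. separation from source: × 0.75 when selected;
3. short-duration discount: × 0.5 when the stated task duration is
   *strictly* below 4 h (exactly 4.0 h is not discounted). The discount is
   applied to both presented estimates — they are the "final estimates" a
   user sees and compares to the OEL — and each factor can be applied at
   most once per assessment.

`assess()` computes the uncontrolled estimate by stripping the control set
(same seed, so a no-control scenario yields identical uncontrolled and
controlled values), compares both to the OEL (default 0.025 mg/m³,
jurisdiction-configurable), and recommends the smallest respirator class
whose assigned protection factor covers the residual hazard ratio
(default ladder: half-facepiece 10, full-facepiece 50, PAPR 100,
supplied-air 1000; ratios beyond the ladder escalate to "reassess
controls"). Whether the discount should apply before or after the OEL
comparison is not externally fixed; it is applied before, and the audit
trail records it.

## Model-vs-measured validation

`validate_against_measurements()` compares, per CSP with at least 3
measurements: the modelled GM (point-estimate linear predictor of each
record's covariates, geometrically averaged) against the empirical GM, and
the modelled p95 against the empirical p95, plus the mean modelled/measured
ratios, the fraction of CSPs where the modelled p95 is conservative
(≥ empirical), and the Pearson correlation of log modelled vs log
empirical GMs. Here the modelled p95 *includes* residual variability by
default: an empirical 95th percentile of measurements reflects
within-scenario variability, so a parameter-uncertainty-only p95 would be
systematically anticonservative in this comparison even for a perfect
model. The routine's self-consistency is tested by simulating validation
data from a fitted model itself: the mean GM ratio must sit in
[0.9, 1.1] and the conservative fraction at or above 50% — in fact the
coefficient-uncertainty inflation makes the modelled p95 strictly exceed
the generating p95, so at large per-CSP n the conservative fraction
approaches 100%.

## Synthetic data: what it does and does not emulate

`generate_database()` draws covariates from configurable level frequencies,
control indicators from Bernoulli prevalences, durations uniformly, and
concentrations from $\exp(x^\top\beta_{\mathrm{true}} +
\mathcal{N}(0, \sigma))$, flagging values below the LOD as non-detects
(the true value is retained on the record; substitution is the curation
module's job). The defaults describe a realistic curated construction RCS
database, chosen once: the 25 bundled CSPs uniformly, three sectors, three
project types, four environments, two regions; control prevalences
0.15–0.25; true control effects −0.5 to −1.1 on the log scale (roughly
40–67% reductions, the range dust-control measurements typically show);
intercept $\ln(0.05)$ mg/m³; residual log-SD 0.8 (GSD ≈ 2.2, typical
within-task spread); and a 15% non-detect fraction, matching the share
seen in curated RCS databases. When no fixed LOD is supplied, the LOD is
set at the empirical non-detect-fraction quantile of the generated values.

The generator emulates exactly the multiplicative structure the model
assumes. It does **not** emulate between-worker or within-worker variance
components, correlated determinants (e.g. certain CSPs occurring mostly
indoors), measurement error in covariates, reporting heterogeneity across
literature sources, or model misspecification. Passing parameter-recovery
and self-consistency tests therefore demonstrates that the estimation and
prediction machinery is correct *given the model class* — not that the
model class captures real construction-site data, which is what the
external validation routine is for.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk run: coverage checks
use 200 replicate fits of n = 1000 on a compact 9-term truth (per-term 95%
CI coverage must land in [90%, 99%]); the Monte-Carlo-vs-analytic check
uses 200,000 draws (1% tolerance); the self-consistency check trains on
n = 800 and validates on 12,000 records across 6 CSPs with 4,000 draws.
Percentiles use the default (type 7) sample quantile. De-aggregation moment
matching is exact to 1e-9 by construction. All randomness flows through
explicitly seeded, state-restoring draws (`withr::with_seed`): no function
reads or perturbs the caller's RNG state.

## Known limitations

* Estimates cover only the worker conducting the task; bystander exposure
  is addressed by boilerplate in the ECP, not by numbers.
* Single-task plans only; multi-task shifts require task-based
  time-weighted averaging outside the package.
* Administrative controls are printed in the ECP but never credited
  quantitatively.
* The 50% short-duration discount is a deliberately crude allowance; its
  empirical validation is an open question and the constant is
  configuration, not science.
* Half-LOD substitution biases the fitted GM slightly upward at high
  censoring; a censored-likelihood or Bayesian treatment is the natural
  next step and the model document format (per-term mean/SE plus residual
  SD) was chosen so such an engine could slot in behind the same
  prediction interface.
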