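---
title: "Trauma survival-probability models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trauma survival-probability models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntriss)
```

## The models

Every model in this package estimates a probability of survival for one
trauma admission,

$$\mathrm{Ps} = \frac{1}{1 + e^{-b}},$$

where $b$ is a linear predictor over coded admission covariates and the
coefficient set depends on the trauma mechanism (blunt or penetrating).
Four models are packaged:

* **adjusted TRISS** — $b = b_0 + b_1\,\mathrm{RTS} + b_2\,\mathrm{ISS} +
  b_3\,\mathrm{age}$;
* **NTRISS-like** — $b = b_0 + b_1\,\mathrm{BMR} + b_2\,\mathrm{SBP} +
  b_3\,\mathrm{NISS} + b_4\,\mathrm{age}$;
* **TRISS SpO2** — $b = b_0 + b_1\,\mathrm{GCS} + b_2\,\mathrm{SBP} +
  b_3\,\mathrm{SpO_2} + b_4\,\mathrm{ISS} + b_5\,\mathrm{age}$;
* **NTRISS-like SpO2** — $b = b_0 + b_1\,\mathrm{BMR} + b_2\,\mathrm{SBP} +
  b_3\,\mathrm{SpO_2} + b_4\,\mathrm{NISS} + b_5\,\mathrm{age}$.

The three variants exist because the RTS is increasingly incomputable at
admission: prehospital rapid-sequence intubation removes the GCS and the
respiratory rate. They substitute covariates that remain measurable — the
motor item of the GCS (BMR, 1–6), the RTS band code of systolic blood
pressure (0–4), pulse-oximetry saturation banded into five ordinal codes,
and the NISS, which unlike the ISS counts multiple severe lesions in the
same body region.

Covariate codings are frozen in `coding_tables()` (exportable as JSON for
audit): GCS 13–15→4, 9–12→3, 6–8→2, 4–5→1, 3→0; SBP >89→4, 76–89→3,
50–75→2, 1–49→1, 0→0; RR 10–29→4, >29→3, 6–9→2, 1–5→1, 0→0; SpO2 0 or not
measurable→0, 1–80→1, 81–90→2, 91–95→3, 96–100→4; age <55→0, ≥55→1.
Real-valued saturations band by interval membership (80.5 → 2), not by
prior rounding.

## The RTS scale ambiguity

The published account of the adjusted TRISS derivation describes the RTS as
the 0–12 coded sum, yet reports a cohort mean RTS of 7.4 ± 1.4 — which can
only be the *weighted* RTS
($0.9368\,\mathrm{GCS} + 0.7326\,\mathrm{SBP} + 0.2908\,\mathrm{RR}$,
maximum 7.8408). The two scales give materially different linear predictors
under the same slope. Rather than silently picking one, `score_registry()`
and `derive_model()` take `rts_scale = "weighted"` (default, consistent
with the reported cohort mean and with TRISS practice) or `"trts"`. Both
paths are test-covered; the switch affects only the adjusted TRISS model.

A related presentation detail: the published equation states the logistic
base as the truncated 2.718282. `survival_probability()` uses the true
Euler constant by default; `e_mode = "printed"` reproduces the truncated
base for byte-level replication, differing by less than $2\times10^{-7}$
in Ps.

## Missing physiology

SpO2 recorded as *not measurable* is a clinical finding (no perfusion
signal) and always codes to 0. Truly absent SpO2 is a recording failure and
is governed by the `policy` argument of `resolve_missing()`:

* `spo2_zero_if_unmeasurable` (default) — the record is refused for the two
  SpO2 models only and scored normally by the others;
* `complete_case` — the record is refused for every model (strictest,
  useful for sensitivity analysis);
* `spo2_zero_always` — absent SpO2 is coded 0, flagged
  `spo2_zero_by_policy` in the audit trail.

How the original derivation handled its 29.6% missing SpO2 is not stated
anywhere we could find; the default documents our choice without asserting
it was theirs. Absent GCS/BMR or SBP always refuse the models that need
them: these covariates cannot be neutralised by a zero code without
changing their meaning. BMR absent alongside a recorded GCS total is never
imputed from the total, because the decomposition of a GCS total into its
eye/verbal/motor items is not unique.

## Severity indices

ISS and NISS follow the universal definitions: the sum of squares of the
highest AIS severity in each of the three most severely injured distinct
body regions (ISS, over six regions) or of the three highest severities
overall (NISS); any AIS 6 sets the score to 75; AIS 9 or missing severity
makes the patient unscoreable (`scoreable = FALSE`) rather than silently
mis-scored. `severity_scores()` is a vectorised implementation pinned by
test to the per-patient reference functions `compute_iss()` /
`compute_niss()`, and those in turn to an exhaustive three-region
enumeration oracle.

## Coefficient derivation

`derive_model()` reproduces the published derivation design:

1. **Split** (`split_test_derived()`): a seeded uniform draw of 300
   patients per site forms the test database; the remainder is the derived
   database. The original study gives no seed, so reproducibility is at the
   artifact level, not the study level.
2. **Site weights** (`site_weights()`): with two sites of unequal size,
   minority-site records receive weight majority/minority so both hospitals
   contribute equally. `mode = "published"` rounds to two decimals
   (7872/2116 → 3.72); `mode = "exact"` (default) keeps the full ratio —
   on simulated cohorts of 12,000 the two differ by under $10^{-2}$ in
   every coefficient. Weights are computed on the full derived set before
   mechanism stratification (a `weights_scope = "per_stratum"` switch
   recomputes within stratum).
3. **Fit** (`fit_weighted_logistic()`): Newton/IRLS on the
   weight-multiplied Bernoulli log-likelihood from $\beta = 0$, with step
   halving, convergence at max absolute score $<10^{-8}$ or relative
   log-likelihood change $<10^{-10}$, cap 100 iterations. Mechanism strata
   are fitted separately (matching the two-column layout of the published
   sets); strata under 50 usable rows are refused with a warning.

Perfect separation — including the quiet kind where the score vanishes
because the data are perfectly classified — is reported as
`converged = FALSE` with diagnostic `"separation"`, never as silent giant
coefficients. Rank-deficient designs are rejected naming the collinear
columns.

Two standard errors are reported: the inverse weighted observed information
(`standard_errors`) and the sandwich variance
(`robust_standard_errors`). When case weights are not all one, the
estimator maximises a pseudo-likelihood and the information-based SE
understates its sampling variance (we observe z-score standard deviations
near 1.5 with the 3.72 site weight); the sandwich SE is the appropriate one
for coverage statements about weighted fits, and the package's recovery
tests use it.

## Discrimination analysis

Scores are survival probabilities and the positive class is "survived";
predicting death is a pure relabelling. `auc()` is the Mann–Whitney
statistic with ties counted one half, exactly equal (test-pinned) to
exhaustive pair counting and to the trapezoidal area under the
`roc_curve()` staircase. Confidence intervals: DeLong's closed-form
placement-value variance by default (deterministic; matches the pROC
reference implementation to $10^{-9}$ in the tests), or a seeded stratified
percentile bootstrap. The cutoff rule is Youden's index with ties broken
toward the higher threshold — the more specific rule when the clinical use
is flagging probable deaths; both the rule and the tie-break are explicit
because the published cutoffs (0.95–0.97) come with no stated selection
rule.

## The synthetic registry

`simulate_registry()` exists so the whole pipeline — coding, derivation,
scoring, evaluation — is testable end to end without access to any real
registry. Its defaults emulate the derivation cohort's published margins:
two sites mixed 2416:8172, 90.4% blunt trauma, age truncated-normal
(≥14 y) with mean 41.9 and SD 19.9, mean ISS 9.7, mean NISS 12.8, 2.1
injured body regions per patient, 82.8% GCS 13–15, SBP 133.7 ± 31.7, RR
18.1 ± 5.2, SpO2 ≈ 97 with a heavy lower tail, missingness 29.6% (SpO2),
8.3% (RR), 4.3% (GCS and BMR jointly), 0.9% (SBP), and overall mortality
5.9%.

Internally a latent per-patient acuity class (minor / moderate / severe /
critical) drives both the AIS severity distribution and conditional shifts
in every physiological variable, inducing the anatomical–physiological
correlation real cohorts show. The outcome is Bernoulli in the survival
probability of a configurable `truth_model` (default: NTRISS-like with the
packaged published sets) applied to the complete, pre-missingness
covariates; the generating $b$ and Ps are returned in a separate truth
table that is never written into the registry file. Missingness is
missing-at-random; "not measurable" SpO2 is a distinct rare state
concentrated among the most severe patients.

Only the *margins* above are calibrated. The joint distribution of anatomy
and physiology in the real cohorts is unknown, so the conditional
functional forms (class mixture, gamma saturation deficit, normal SBP/RR
shifts) are invented and documented as such. Passing tests therefore show
that the pipeline is correct under a plausible data-generating process with
the right margins — not that any particular real registry looks like this.
Randomness uses per-variable substreams drawn in patient order, so the
first $m$ records of a size-$n$ run are identical to a size-$m$ run with
the same seed.

## Problem sizes and tolerances in the test suite

The suite verifies, among others: coefficient recovery through the full
derivation pipeline (50 replicates of 20,000 blunt-only patients; every
coefficient within 3 robust SEs of truth in ≥90% of replicates),
comparable discrimination of all four packaged models on default synthetic
registries (n = 20,000; AUC range below 0.03), simulator margins at
n = 50,000 (blunt ±1.5 pp, mortality ±1 pp, SpO2 missingness ±1.5 pp, mean
ISS ±1.0, mean NISS ±1.2), AUC-vs-pair-counting equivalence on 1,000 random
sets with ties, and ISS-vs-enumeration equivalence on 10,000 random injury
sets. These sizes keep the full suite around two minutes on one CPU while
leaving Monte-Carlo error well inside each tolerance.

## Known limitations

* The packaged coefficient sets are faithful transcriptions of the
  published two-hospital values; the package cannot re-derive them without
  the (undeposited) registry, and the synthetic generator is not a
  substitute for it.
* Calibration statistics (Hosmer–Lemeshow), W/M/Z benchmarking and ICD-
  based mechanism classification are out of scope; mechanism is taken as a
  field.
* The penetrating stratum in realistic mixes is small (~10%), so derived
  penetrating coefficients on synthetic cohorts carry wide robust SEs —
  as they would on real cohorts of this composition.
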