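# ntriss

Survival-probability scoring for trauma registries: the adjusted TRISS model
and three variants built from routinely recorded admission variables, with
the full coefficient-derivation and ROC-evaluation pipeline and a calibrated
synthetic-registry generator.

## Who this is for

Trauma performance-improvement programs score every admitted patient with a
probability of survival (Ps) and audit deaths among patients predicted to
survive. The classic tool is TRISS, which combines the Revised Trauma Score
(RTS), the Injury Severity Score (ISS), age and trauma mechanism. TRISS is
hard to apply when patients arrive intubated (no Glasgow Coma Scale or
respiratory rate, hence no RTS). This package implements TRISS alongside
three models that avoid the RTS:

| model | covariates |
|---|---|
| adjusted TRISS | RTS, ISS, age indicator |
| NTRISS-like | Best Motor Response (BMR), coded SBP, NISS, age indicator |
| TRISS SpO2 | coded GCS, coded SBP, SpO2 band, ISS, age indicator |
| NTRISS-like SpO2 | BMR, coded SBP, SpO2 band, NISS, age indicator |

All four share the logistic form

```
Ps = 1 / (1 + exp(-b)),   b = b0 + b1 x1 + ... + bk xk
```

with separate published coefficient sets for blunt and penetrating trauma
(`default_coefficients()`), derived from a two-hospital cohort of 10,588
patients. Covariate codings: GCS/SBP/RR map to the standard RTS bands (0-4);
SpO2 maps to 0 (zero or not measurable), 1 (1-80), 2 (81-90), 3 (91-95),
4 (96-100); age codes 1 at >= 55 years; BMR is the GCS motor item (1-6);
ISS/NISS are the usual sums of squares of the three highest AIS severities
(per distinct body region for ISS).

## Worked example

Simulate a registry, filter it through the cohort eligibility rules, score
everyone with the NTRISS-like SpO2 model and evaluate discrimination:

```r
library(ntriss)
sim <- simulate_registry(5000, seed = 42)
reg <- apply_eligibility(sim$registry)
reg$report
#> eligibility: 5000 of 5000 retained (excluded: age 0, late 0, transfer 0, mechanism 0)

scored <- score_registry(reg$registry, "ntriss_like_spo2")
ok <- is.na(scored$refusal)          # records with every covariate codable
sum(ok)
#> 3345

i <- which(ok)[3]
score_record(reg$registry$patients[i, ],
             subset(reg$registry$injuries,
                    patient_id == reg$registry$patients$patient_id[i]),
             model_id = "ntriss_like_spo2")
#> ntriss_like_spo2 (blunt): b = 5.322261, Ps = 0.995142
#>   covariates: bmr=6 sbp=4 spo2=4 niss=6 age=0

evaluate_scores(scored$ps[ok], as.numeric(reg$registry$patients$survived[ok]))
#> AUC 0.897 (delong 95% CI 0.867-0.927), cutoff 0.923: sens 92.5%, spec 76.2%
```

The per-record output is an audit trail: the linear predictor `b`, `Ps`, the
exact covariate values used, and flags (e.g. SpO2 coded 0 because the reading
was "not measurable"). Records that cannot be scored carry an explicit
refusal reason instead of silently dropping out. The evaluation row mirrors
the usual reporting layout for these models: AUC with a DeLong 95%
confidence interval and the Youden-index cutoff with its sensitivity and
specificity.

Coefficient derivation for a new population follows the same design as the
published sets: a seeded 300-per-site test/derived split
(`split_test_derived()`), site-balancing weights (`site_weights()`), and a
weighted logistic fit per mechanism (`derive_model()`).

## Command line

A thin shell entry point wires the pipeline:

```sh
inst/cli/ntriss simulate --n 20000 --seed 7 --out registry.csv --injuries inj.csv
inst/cli/ntriss derive   --registry registry.csv --injuries inj.csv \
                         --model ntriss_like --out coeffs.json
inst/cli/ntriss score    --registry registry.csv --injuries inj.csv \
                         --model ntriss_like --coefficients coeffs.json --out scored.csv
inst/cli/ntriss evaluate --scored scored.csv --out report.json
```

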