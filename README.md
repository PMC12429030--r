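# axsurv

Axillary-surgery extent and breast-cancer-specific survival in
registry-like cohorts.

## What this package is for

Population cancer registries record how many axillary lymph nodes were
removed and how many were positive, but usually not *which operation* was
performed: a sentinel lymph node biopsy (SLNB, limited sampling of 1–5
nodes) or an axillary lymph node dissection (ALND, extensive removal of
typically ≥10 nodes). `axsurv` is a toolkit for epidemiologists and
biostatisticians who want to study whether the extent of axillary surgery
is associated with breast-cancer-specific survival under those constraints.
It provides the complete analysis chain as tested, composable functions:

* **Synthetic cohort generation** with known ground truth (latent
  procedure, planted hazard effects), calibrated to the marginal
  distributions of a large US registry population, so every stage of the
  pipeline is testable without access-controlled data.
* **Two-step exposure inference**: deterministic node-count rules
  (1–3 removed ⇒ SLNB; ≤4 removed and N0 ⇒ SLNB; ≥10 removed, ≥7 removed
  and node-positive, or N2/N3 ⇒ ALND), then a Bayesian logistic regression
  with informative priors — adaptive Metropolis or Laplace approximation —
  that resolves the remaining unknowns at a 0.50 posterior-probability
  threshold.
* **Multiple imputation** by chained equations with predictive mean
  matching, and Rubin's rules for pooling.
* **Propensity-score matching**: logistic propensity model, 1:1 nearest
  neighbour without replacement within a caliper of 0.2 × SD(logit score),
  standardized-mean-difference balance audit at the ≤ 0.1 threshold.
* **Survival analysis**: Kaplan–Meier, log-rank, multivariable Cox models
  (Efron ties) with matched-pair cluster-robust (sandwich) variance, and —
  for pN2/pN3 patients, where SLNB does not occur — Cox models in the
  removed-node count and the positive-to-removed node ratio
  `r = n_positive / n_removed`.

The model at the core is a cause-specific proportional-hazards model

```
h(t | x) = h0(t) · exp(β_ALND·ALND + β'z),    HR = exp(β),
```

estimated within propensity-matched pN0 and pN1 strata (pair-clustered
robust variance), and in the pN2/pN3 stratum as
`... exp(β_rem·n_removed + β_ratio·r + γ'z)`.

## Worked example

```r
library(axsurv)

cfg <- sim_config(n = 10000, seed = 3)
cfg$hazard$alnd <- log(1.16)   # plant a 16% hazard increase for ALND
report <- run_pipeline(cfg)
print(report)
```

```
axsurv pipeline report (seed 3, config f19625e3)
selection: 10000 -> 10000 included (0 excluded)
  tis_tmi        0
  m1             0
  t3_t4          0
  nonepithelial  0
  neoadjuvant    0
  no_surgery     0
  missing_data   0
final labels: ALND 3450, SLNB 6550 
median follow-up: 89.6 months
pN0: 1518 pairs, ALND HR 1.286 (95% CI 1.035-1.599), balance PASS
pN1: 628 pairs, ALND HR 1.026 (95% CI 0.696-1.512), balance PASS
pN2/pN3 nodes_removed: HR 1.055 (95% CI 1.007-1.106)
pN2/pN3 node_ratio: HR 1.757 (95% CI 0.521-5.929)
```

Reading this: 10,000 simulated patients pass selection untouched (the
default world is already analysis-ready); exposure inference labels 3,450
as ALND; within the matched pN0 stratum the estimated ALND hazard ratio is
1.286 (the planted truth, 1.16, sits inside the 95% CI — a single seed at
n = 10,000 is noisy; the recovery experiments below average over seeds at
n = 30,000), and the covariate balance audit passes (all post-match
standardized mean differences ≤ 0.1). The pN2/pN3 block reports the
node-count and node-ratio models for the high-burden stratum.

The exposure-inference step on its own:

```r
co <- generate_cohort(sim_config(n = 2000, seed = 1))
ex <- infer_exposure(co, seed = 1)
print(table(rule = ex$labels$rule_label, final = ex$labels$final_label))
cat(sprintf("accuracy vs latent truth: %.3f\n",
            mean(ex$labels$final_label == co$latent_procedure)))
```

```
         final
rule      ALND SLNB
  ALND     581    0
  SLNB       0 1174
  UNKNOWN   75  170
accuracy vs latent truth: 0.969
```

Rule labels are final; the 245 unknowns (4–6 removed nodes, mostly) are
resolved by the Bayesian model, for 96.9% overall agreement with the latent
truth.

## Command line

A verb-based CLI covers the common workflows
(`simulate | classify | impute | match | survival | run | recover`):

```sh
Rscript -e 'axsurv::axsurv_cli()' run --n 10000 --seed 3 --out-dir out/
```

See `?axsurv_cli`, and `vignettes/methods.Rmd` for the full methodological
account: model assumptions, priors, matching-order rationale, numerical
choices and known limitations.
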