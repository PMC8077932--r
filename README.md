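# pharmvig

Quasi-experimental digital pharmacovigilance from longitudinal text
timelines: who improved after starting an antidepressant, who did not, and
what side-effect language distinguishes them.

People disclose starting medications on social media, and their timelines
before and after that disclosure form naturalistic longitudinal data.
`pharmvig` implements the full observational pipeline for mining drug
side-effect language from such timelines:

- a packaged lexicon of **49 generic antidepressants** across the four
  major families (SNRI, SSRI, tricyclic, tetracyclic) with word-boundary
  mention matching;
- a **personal medication-intake classifier** (regularized logistic-loss
  linear model) separating "i took sertraline" from "sertraline is in the
  news";
- pretreatment **covariates** per user: structural features,
  psycholinguistic categories, top-V unigrams, and baseline rates of five
  symptomatic outcomes (depression, anxiety, stress, suicidal ideation,
  psychosis);
- **propensity scores** by L2-penalized IRLS logistic regression,
  stratified into **100 equal-width bins**, with balance diagnostics;
- the **relative treatment effect (RTE)** — the ratio of a symptomatic
  outcome's likelihood in the treated arm to the matched control arm —
  per drug, stratum and outcome; sorting strata on a composite of the five
  outcome RTEs selects the **most-improved** (top 10 strata) and
  **least-improved** (bottom 10 strata) cohorts;
- **SAGE** (sparse additive generative model) contrastive keyword
  extraction between the cohorts' post-treatment language, with a
  self-tuned (Jeffreys hyperprior) regularization that needs no hand-set
  penalty;
- Figure-style **normalized co-occurrence prevalence** of n-grams around
  seed terms for five side-effect domains: sleep, weight, eating, pain,
  sexual issues.

Because raw platform data cannot be redistributed, the package includes a
first-class synthetic-timeline generator (`sim_config()`,
`generate_population()`) with covariate-confounded treatment assignment,
heterogeneous post-treatment improvement and planted side-effect phrases —
so every stage is validated by recovering known ground truth. The methods
vignette (`vignettes/digital-pharmacovigilance.Rmd`) documents the models,
the generator's assumptions and the design choices.

## Worked example

```r
library(pharmvig)

corpus <- generate_population(sim_config(seed = 20260924))
result <- run_pipeline(corpus, pipeline_config(seed = 42))
print(result)
#> <pv_result> 1000 treated users, 91 strata retained, drugs: sertraline
```

The analysis drivers under `analysis/` run this end to end
(`Rscript analysis/01_simulate.R`, then `02_cohorts.R`, `03_keywords.R`,
`04_diagnostics.R`), writing tables under `results/`. On the corpus above,
`02_cohorts.R` prints:

```
retained strata: 91/100
cohorts: 199 most-improved, 35 least-improved users
composite log-RTE range over ranked strata: -0.73 .. -0.01
hidden improvement-effect gap (most - least): 0.167
```

so the treated users selected as most improved have a hidden
per-post improvement effect 0.167 larger, on average, than the
least-improved cohort (the truth sidecar is never visible to the
pipeline). `03_keywords.R` shows the side-effect language that separates
the cohorts — all five planted phrases per cohort surface in the SAGE
top-20:

```
keywords salient in the MOST improved cohort:        eta
  good night                                        0.77
  weight loss                                       0.77
  feeling better                                    0.77
  lose weight                                       0.77
  fall asleep                                       0.77
keywords salient in the LEAST improved cohort:
  panic attack                                      0.43
  chronic pain                                      0.41
  weight gain                                       0.38
  want eat                                          0.35
```

and `04_diagnostics.R` replicates the study 10 times:

```
means: gap 0.161, SMD 0.264 -> 0.029, recall 5.0/5
```

i.e. the planted follower-count confounding (standardized mean difference
0.26 before stratification) drops to 0.03 within strata, and planted
keyword recall is 5/5 in every replicate.

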