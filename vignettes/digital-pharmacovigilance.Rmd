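---
title: "Quasi-experimental pharmacovigilance from longitudinal text timelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-experimental pharmacovigilance from longitudinal text timelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Side effects of antidepressants are heterogeneous, under-reported in
clinical channels, and hard to anticipate for an individual patient.
Longitudinal social-media timelines of people who self-report starting a
medication offer an unobtrusive observational window on what changes after
intake — both in symptomatic language and in side-effect language.
`pharmvig` implements an end-to-end quasi-experimental pipeline over such
timelines:

1. **Lexicon matching** finds posts mentioning any of 49 generic
   antidepressants (or brand names) with word-boundary, longest-match-wins
   matching.
2. **Intake classification** separates posts that report *taking* a drug
   from posts that merely mention one, with a regularized logistic-loss
   linear classifier over token and first-person-pattern features.
3. **Covariates** are computed strictly on each user's pretreatment posts:
   structural features (log followers, log post count, tenure),
   psycholinguistic category frequencies, top-V unigram frequencies, and
   baseline rates of five symptomatic outcomes (depression, anxiety,
   stress, suicidal ideation, psychosis).
4. **Propensity scores** come from an L2-penalized logistic regression fit
   by IRLS; users are stratified into 100 equal-width score bins, so each
   retained stratum compares treated and control users with similar
   treatment propensity.
5. **Relative treatment effect (RTE)** per drug, stratum and outcome is the
   ratio of the treated arm's post-window symptomatic rate to the control
   arm's. Sorting strata on a composite of the five outcome RTEs yields the
   *most-improved* (top 10 strata) and *least-improved* (bottom 10 strata)
   cohorts.
6. **SAGE keyword extraction** contrasts the post-treatment language of the
   two cohorts with a sparse additive generative model, and **co-occurrence
   prevalence** profiles the n-grams around seed terms for five side-effect
   domains (sleep, weight, eating, pain, sexual issues).

Real platform data cannot be redistributed, so the package ships a
synthetic-timeline generator with known ground truth; every pipeline stage
is validated by recovering planted structure.

## The models

### Propensity model and stratification

Treatment status $T_i$ is modelled as
$\Pr(T_i = 1 \mid x_i) = \sigma(\beta_0 + \beta^\top x_i)$ with an L2
penalty $\tfrac{\lambda}{2}\lVert\beta\rVert^2$ on internally standardized
features ($\lambda = 1$ by default; the unigram block makes the design
high-dimensional and the penalty keeps it well-conditioned). The optimizer
is iteratively reweighted least squares, which for this objective is exactly
Newton's method; the test suite checks the fitted coefficients against an
independently coded Newton iteration to $10^{-6}$.

Scores are binned into `n_strata = 100` *equal-width* intervals of
$[0, 1]$ — equal length, not equal occupancy — left-closed, right-open,
with the top edge closed. A stratum is retained when both arms have at
least `min_per_arm` (default 1) users. Balance is reported as standardized
mean differences: before stratification, and after as the stratum-size
weighted mean of signed within-stratum mean differences over the overall
pooled SD. Signed aggregation matters: with many small strata, averaging
per-stratum *absolute* SMDs is biased upward by pure noise.

### RTE and cohort selection

Within stratum $s$, the arm likelihood for outcome $o$ is the mean over the
arm's users of the user's post-window positive-post fraction, and
$\mathrm{RTE}_{s,o} = p^{T}_{s,o} / p^{C}_{s,o}$. A zero arm likelihood is
floored at $1/(2\,n_{\text{posts}})$ of that arm and flagged. Since the
outcomes are *symptom* expressions, a lower symptomatic RTE means more
improvement relative to matched controls; the default ranking therefore
sorts ascending composite log-RTE (`invert_rte` flips the convention for
improvement-oriented outcome measures — the directionality of "descending
order of RTEs" is genuinely ambiguous when outcomes are symptoms, so both
conventions are first-class).

The composite is the unweighted mean over the five outcomes of
$\log \mathrm{RTE}_{s,o}$, *stabilized* by empirical-Bayes shrinkage: the
sampling variance of a stratum's composite scales with
$1/n_T + 1/n_C$, so one-user arms at the score tails would otherwise claim
the extreme ranks by noise alone. Each composite is pulled toward a
precision-weighted linear trend on the stratum's score midpoint with
residual weight $n_{\mathrm{eff}}/(n_{\mathrm{eff}} + m)$,
$n_{\mathrm{eff}} = (1/n_T + 1/n_C)^{-1}$, $m = 5$ (`shrink = 0` restores
the raw composite). At the scale the paper's design was run — hundreds of
thousands of users — this stabilization is inert because every stratum is
well populated; at desk scale it is what makes stratum ranking an estimator
rather than a lottery.

### SAGE with self-tuned regularization

A target corpus's term distribution is modelled as
$p(w) \propto \exp(m_w + \eta_w)$, where $m$ is the log of the smoothed
(add-0.01) background distribution and $\eta$ a sparse deviation vector.
Each $\eta_w$ has a zero-mean Normal prior with per-term variance $\tau_w$,
and $\tau_w$ carries the parameter-free Jeffreys hyperprior
$p(\tau) \propto 1/\tau$ — this is the "self-tuned" regularization: no
penalty constant is chosen by hand, and the implied shrinkage adapts per
term. EM alternates

- E-step: $\omega_w = \mathbb{E}[1/\tau_w \mid \eta_w] = 1/(\eta_w^2 +
  \varepsilon)$ with floor $\varepsilon = 10^{-8}$;
- M-step: damped Newton on the penalized multinomial log-likelihood with
  ridge weights $\omega$, using the exact Hessian inverse via
  Sherman–Morrison (the Hessian is diagonal plus rank one, so each round is
  linear in the vocabulary) and step-halving, iterated to surrogate
  convergence. Running the inner Newton loop to convergence is not a
  nicety: a single badly scaled coordinate can otherwise stall a global
  step-halved update, after which the Jeffreys weights pin every deviation
  at zero.

The tracked objective
$\ell(\eta) - \tfrac12 \sum_w \log(\eta_w^2 + \varepsilon)$ is provably
non-decreasing across EM rounds (the ridge surrogate majorizes the log
penalty), and the first ridge(1) update from $\eta = 0$ is defined as
initialization, not an EM round. The behaviour of this estimator is a soft
threshold: a deviation survives near its maximum-likelihood value roughly
when $|\hat\eta_{\mathrm{MLE}}| > 2/\sqrt{H_w}$ (with $H_w$ the expected
target count of the term) and collapses to numerical zero otherwise — on
null data more than 90% of terms end below $10^{-3}$, which the tests
assert.

For cohort contrasts, the background is the *equal-weight mixture* of the
two corpora's term distributions scaled to the pooled token count. Raw
summed counts would let the larger cohort — and the top-strata cohort is
routinely several times larger — dominate its own background and cap its
detectable enrichment. N-grams containing function words are dropped by
default (`pv_stopwords()`); reported keyword lists in this literature are
evidently filtered the same way.

### Co-occurrence prevalence

For each post containing a side-effect seed term, all n-grams
(n = 1, 2, 3) not overlapping a seed occurrence are collected once per
post; a term's normalized prevalence is the fraction of the cohort's posts
that are seed-co-occurring posts containing it. The normalization
denominator (per-cohort post count) keeps the two cohorts' bars comparable
and makes prevalence invariant to duplicating every post. Co-occurrence is
scoped to the same post: on a short-post platform a post is the natural
discourse unit.

## The synthetic data generator

`sim_config()` / `generate_population()` emulate the statistical structure
the analysis relies on, not English. Defaults (all overridable):

- **Population**: 1000 treated + 1000 control users, a 4-year window,
  posts per user $\sim 5 + \mathrm{NegBin}(\mu = 55, k = 4)$ (mean 60).
  Real longitudinal timelines in this setting average thousands of posts
  per user; 60 is a deliberately conservative desk scale.
- **Covariates**: followers log-normal, activity negative-binomial, tenure
  uniform, baseline per-post symptom probability $b_i \sim
  \mathrm{Beta}(3, 9)$ (mean 0.25 — high enough that outcome *ratios* stay
  away from the degenerate near-zero regime where a clamped rate can make a
  random stratum look spectacularly improved).
- **Confounding**: treatment assigned with probability
  $\sigma(\gamma^\top z_i)$ on standardized covariates,
  $\gamma = (0.5, 0, 0, 1.5)$ for (log-followers, activity, tenure,
  baseline), then quota-resampled to the requested arm sizes. Followers are
  the "planted confounder" whose balance the diagnostics track (SMD before
  stratification ≈ 0.25–0.35).
- **Improvement**: for treated users,
  $\delta_i = 0.10 + 0.7\,(b_i - \bar b) + \mathcal{N}(0, 0.05)$; the
  post-treatment per-post symptom probability is
  $\mathrm{clamp}(b_i - \delta_i,\ 0.01,\ 0.99)$, controls keep $b_i$. The
  baseline-linked slope encodes effect modification by baseline severity
  (users with more room to improve improve more, and low-baseline users can
  worsen — a spectrum from decrease to increase). It is also what makes
  stratum-level cohort selection informative about individuals: if
  improvement were independent of every covariate, the strata could differ
  in mean improvement only through sampling noise, and an a priori power
  calculation shows the selected cohorts could never exceed roughly a 65/35
  split of improved users at this scale, far too dilute for keyword
  recovery. Set `improvement_baseline_slope = 0` for the unstructured
  regime; the generator's own recoverability properties (Spearman
  correlation between realized post rates and $\delta$, quartile contrasts)
  are tested there, since with a positive slope the realized rate is by
  construction decoupled from the structured part of $\delta$.
- **Text**: Zipf-weighted draws from a 182-word common-word vocabulary;
  symptomatic posts carry one dedicated marker token per expressed outcome
  (the lexicon scorer consumes exactly these, decoupling text realism from
  statistical structure); each treated user has exactly one "i took <drug>"
  disclosure post, which belongs to neither analysis window. Users above
  the treated median of $\delta$ inject one of five planted improved-cohort
  phrases ("fall asleep", "weight loss", "good night", "lose weight",
  "feeling better") into a post-treatment post with probability 0.15 per
  post; users below the median inject worsened-cohort phrases ("want
  sleep", "weight gain", "want eat", "chronic pain", "panic attack") at the
  same rate. Markers and phrases are spliced at random positions (phrases
  kept contiguous) so construction leaves no token-order signature.
- **Determinism**: one seeded RNG stream in documented order; equal configs
  give byte-identical corpora.

What passing tests on these corpora show — and what they do not: the
pipeline recovers planted confounding, improvement ordering and side-effect
keywords under the generator's assumptions (marker-based outcomes,
single-post disclosure, stationary background language). They do not show
that the lexicon scorers approximate trained symptom classifiers on real
language, that intake classification survives creative phrasing, or that
real treatment effects are as large or as baseline-structured as the
simulated ones.

## Numerical choices and degenerate inputs

- Logistic fits: constant features dropped with a warning; single-class
  responses are errors; weights floored at $10^{-10}$; non-convergence is
  an error carrying iteration diagnostics, not a silent result.
- Stratification: score exactly 1 goes to the last bin; `n_strata < 2` is
  an error; dropped strata remain visible in the `strata` table.
- RTE: empty arms are errors; zero likelihoods floored and flagged; ties in
  the ranking key break by ascending stratum index; if fewer than $2k$
  strata are rankable, $k$ shrinks with a warning, and a single rankable
  stratum is an error (cohorts must be disjoint).
- SAGE: vocabulary requires a pooled count of at least `min_count = 5`
  (cap 5000 by pooled frequency, ties lexicographic); empty targets and
  disjoint vocabularies are errors; non-finite updates abort with an
  iteration dump; `top_terms` ties break lexicographically.
- Corpus I/O: JSON-lines round-trips are lossless (sidecar numerics written
  with 17 significant digits); a malformed line reports its line number.

## Scale of the shipped analyses

The bundled analysis scripts and the acceptance suite run the full pipeline
on corpora of 2000 users (about 120k posts) and use 10–20 replicates per
diagnostic; a replicate takes a few seconds on one core. These sizes were
chosen so the whole validation study runs comfortably on a laptop while
keeping every stratum-level estimator in its working regime; all of them
scale up linearly if larger studies are wanted.

## Known limitations

- The intake classifier is a functional stand-in trained on template
  text; production accuracy figures from manually annotated tweets are out
  of scope, and only the interface (score, threshold, JSON serialization)
  matches a production classifier.
- Outcome scoring is lexicon-based by design; the `scorer_config` interface
  accepts any per-post five-flag scorer, so trained classifiers can be
  plugged in without touching the pipeline.
- The shipped brand-name map is a small illustrative subset and is not a
  complete brand lexicon.
- RTE uncertainty (bootstrap confidence intervals) is a documented
  extension, not implemented.
- Equal-width strata are bins of $[0, 1]$; binning the observed score range
  instead is configurable upstream of `stratify()` by rescaling scores.
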