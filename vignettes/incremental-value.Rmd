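---
title: "Quantifying the incremental value of a continuous marker by Bayes risk updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the incremental value of a continuous marker by Bayes risk updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incrval)
```

## The problem

A new continuous diagnostic marker — in the motivating setting, a
malignancy probability that an image model assigns to a pulmonary nodule on
a CT scan — is rarely used in isolation. Clinicians already have validated
risk calculators built from patient characteristics and nodule features
(age, smoking history, nodule diameter, spiculation, ...). The question
that decides adoption is not "is the marker predictive?" but "does it add
anything to what the calculator already knows?" — its *incremental value*.

`incrval` implements one complete workflow for that question:

1. evaluate a configurable logistic risk calculator as the **prior**
   probability of disease, $P(D \mid X) = \operatorname{logit}^{-1}
   (\beta_0 + \sum_j \beta_j t_j(x_j))$;
2. estimate the marker's **likelihood ratio**
   $LR(y) = f(y \mid D{=}1) / f(y \mid D{=}0)$ from the cohort;
3. update each subject by **Bayes' rule** on the odds scale,
   $\text{posterior odds} = LR(y) \times \text{prior odds}$;
4. compare prior and posterior risk with **AUC**, the **integrated
   discrimination improvement (IDI)**, five-category **reclassification
   tables** with percent reclassified, and the category **NRI**;
5. when covariates are missing, repeat the analysis over multiply imputed
   datasets and pool the IDI with **Rubin's rules**.

Because the real cohorts behind this style of analysis are not publicly
distributable, the package carries a seeded synthetic-cohort generator
whose statistical structure matches what the pipeline assumes, so every
stage is testable end to end.

## The update model and its key assumption

For subject $i$ with prior $p_i$ and marker score $y_i \in [0,1]$:

$$
\frac{q_i}{1-q_i} = LR(y_i)\,\frac{p_i}{1-p_i},
$$

and the posterior probability $q_i$ is read back from the odds. Priors are
clamped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$
before the odds transform, so calculators that output exactly 0 or 1 do not
produce infinite odds; the identity update ($LR \equiv 1$) therefore
reproduces the prior only up to $\varepsilon$.

The update treats $LR$ as a function of the marker alone. Formally the
likelihood ratio in the decomposition is $f(y \mid D, X)/f(y \mid \bar D,
X)$; using a single marker-based LR assumes the marker is **conditionally
independent of the calculator covariates given disease status**. This is a
real assumption, not a technicality: if the image model mostly rediscovers
nodule size, and size is already in the calculator, the single-LR update
double-counts that information. Without covariate-stratified likelihoods no
weaker reading is estimable, so the package makes the assumption explicit
rather than hiding it.

### Estimating the likelihood ratio

Two estimators are provided, since the functional form is a genuinely open
choice:

* **binned** (default): five equal-width bins on $[0,1]$; the per-bin LR is
  the ratio of within-class bin frequencies. A continuity constant
  $c = 0.5$ enters numerator and denominator *only* for bins with a zero
  cell, so well-populated bins are unsmoothed maximum-likelihood ratios.
  Bins are left-closed, right-open, with the last bin closed; a score
  exactly on an interior edge belongs to the bin on its right.
* **binormal**: normal densities fit to the logit-transformed scores per
  class; the LR is the fitted density ratio. With equal class SDs this
  gives a monotone LR (log-LR linear in the logit score).

By default the LR is estimated on the same cohort being updated, matching
how this kind of case study is typically run. That choice is **optimistic**:
the estimated LR is correlated with the very labels the evaluation then
uses, which biases the apparent IDI upward — under a null marker the
in-sample estimate manufactures spurious improvement. `posterior_crossfit()`
estimates the LR on held-out folds instead and is the recommended option
when the IDI itself is the quantity of interest; even cross-fitting leaves
some shared estimation noise within folds, which is why the package's null
calibration check (below) uses a pre-specified LR mapping.

## Evaluation statistics

**AUC** uses the Mann-Whitney pair estimator (ties credit 0.5), which
equals the trapezoidal area under the empirical ROC curve exactly; the test
suite checks both the equality and agreement with a brute-force pair
enumeration oracle. AUC is invariant under strictly monotone score
transforms, so the latent-to-$[0,1]$ link of the generator does not move it.

**IDI** is the difference in mean risk gain between events and nonevents:
$(\bar d_{\text{ev}} - \bar d_{\text{ne}})$ with $d_i = q_i - p_i$. The
default standard error treats the $d_i$ as two independent samples,
$SE = \sqrt{\widehat{\operatorname{var}}(d \mid \text{ev})/n_{\text{ev}} +
\widehat{\operatorname{var}}(d \mid \text{ne})/n_{\text{ne}}}$, with a
normal 95% CI and two-sided p-value; a seeded within-class bootstrap
(percentile CI, $B = 2000$) is available since published analyses rarely
state which was used. Degenerate (zero-variance) inputs fall back to the
bootstrap with a warning.

**Reclassification tables** use the conventional five risk bands
$[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1]$ (configurable), with
the same edge convention as the LR bins. *Percent reclassified* per initial
category is $100 \times$ (off-diagonal count / row total), rounded to the
nearest integer with ties to even (base R `round()`), and `NA` for empty
rows. Half-even was chosen because it is the only nearest-integer rule that
reproduces every printed cell of the published tables the test suite checks
against — including a row where the exact value is 62.5 and the printed
cell is 62, which rules out half-up.

**Category NRI** is $[P(\text{up} \mid \text{ev}) - P(\text{down} \mid
\text{ev})] - [P(\text{up} \mid \text{ne}) - P(\text{down} \mid
\text{ne})]$ computed from the same table.

## Missing covariates

Validation cohorts for this analysis commonly miss a smoking covariate
(e.g. years since quitting). `impute_chained()` implements multiple
imputation by chained equations with proper posterior draws: per incomplete
covariate, a Bayesian linear regression (continuous) or a logistic draw
(binary) on all other covariates, the marker score and the outcome, swept
`iterations = 10` times after initialization from the observed marginals.
The outcome is always included as a predictor (standard MI guidance);
outcomes and marker scores are never imputed — subjects without a marker
score are excluded, mirroring the no-detection exclusion rule. Pooling uses
the classical Rubin formulas: $\bar q$, within-variance $\bar u$,
between-variance $b$, total $T = \bar u + (1 + 1/m) b$, degrees of freedom
$(m-1)(1 + \bar u / ((1+1/m) b))^2$ (infinite when $b = 0$; no small-sample
adjustment), with $t$-based CI and p-value.

## The synthetic-data generator

`generate_cohort()` draws a Bernoulli outcome at the configured prevalence
and independent covariate marginals chosen to look like a nodule-evaluation
population: age $\mathcal N(62, 8^2)$ years, pack-years gamma, nodule
diameter log-normal clamped to 3–30 mm, binary flags (sex, current smoker,
spiculation, upper lobe, prior cancer, family history, emphysema,
part-solid) at plausible rates. Cases are shifted modestly on age,
diameter, spiculation and related covariates so that calculator-style
priors are genuinely informative. The published study reports no covariate
distributions, so these defaults are the package's own choice of a
realistic regime, fixed once.

`generate_marker_scores()` draws a latent normal per class — the binormal
model — and maps it monotonically into $[0,1]$, either by affine rescale of
the $\pm 3$ SD range onto $(0.01, 0.99)$ with a hard clamp (default; looks
like a classifier's probability output) or by a logistic squash. Monotone
links leave the AUC at its closed form
$\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_1^2+\sigma_0^2}\big)$, which is the
oracle for the parameter-recovery tests ($\mu$-difference 1 with unit SDs
gives AUC $\approx 0.760$). A configurable `detection_miss_rate` leaves a
random fraction of subjects unscored, emulating scans with no detected
region; `exclude_unscored()` then removes them with exact accounting.

What the generator does **not** emulate: covariate correlation structure,
calibration drift of real calculators across populations, scan-quality
effects on the marker, or any image content. Passing tests demonstrate the
statistical machinery is correct under the assumed structure — they say
nothing about how a particular image model generalizes to a particular
population, which in the motivating study varied substantially between
cohorts.

## Null calibration of the IDI test

One acceptance-style check verifies that when the marker is pure noise, the
IDI test rejects at close to its nominal 5% level (band 0.03–0.07 over
1000 replicates of $n = 200$). The design matters: the update rule must be
independent of the labels under test, otherwise the check measures
estimation optimism rather than the test's size. The calibration therefore
updates through a *pre-specified* binned LR mapping
$(0.5, 0.8, 1, 1.3, 2)$ applied to an uninformative marker, with priors
from the Mayo-style example model. Estimating the LR from the same data —
in-sample or even 2-fold cross-fit — inflates the rejection rate well above
nominal, which the vignette's earlier warning about in-sample estimation is
based on; the test suite asserts the calibrated design only.

## Numerical and design choices, collected

* Prior clamp $\varepsilon = 10^{-6}$; LR values must be positive and
  finite; scores and risks validated to $[0,1]$.
* Bin/category edge convention: left-closed right-open, last bin closed.
* Percent-reclassified rounding: nearest integer, ties to even.
* Region-to-subject reduction: maximum malignancy probability across
  detections; first-seen region wins ties (recorded for audit only).
  Exclusion is the default for unscored subjects; a floor-score mode exists
  for sensitivity analyses.
* Risk-calculator coefficients are configuration, never code: the shipped
  YAML carries illustrative values for the Gould/Mayo/McWilliams covariate
  templates that must be verified against the original publications before
  applied use. A missing required covariate yields an `NA` prior (flagged),
  not an error, so the exclusion/imputation policy stays with the pipeline.
* One global seed; every stage (cohort, marker, missingness, folds,
  imputations, bootstrap) derives an independent substream from it, so
  stages re-run identically in isolation.
* Problem sizes in the test suite — $n = 2000$ for parameter recovery,
  1000 replicates of $n = 200$ for calibration, $m = 5$ imputations — were
  chosen so Monte-Carlo error is small relative to the asserted tolerances
  while the whole suite stays fast.

## A complete run

```{r example, eval = FALSE}
models <- load_model_spec(system.file("extdata", "example_risk_models.yaml",
                                      package = "incrval"))
cfg <- study_config(
  cohort = list(source = "synthetic", n_subjects = 2000, prevalence = 0.4,
                marker = list(mu_case = 1, mu_control = 0,
                              detection_miss_rate = 0.025)),
  models = models$mayo_example,
  seed = 1, out_dir = "study_out")
report <- run_study(cfg)
print(report)
print(report$models$mayo_example$reclassification)
```

Every number in the report is recomputable from the persisted
intermediates (`cohort_scored.csv`, `lr_model.json`, the reclassification
and ROC CSVs), and the test suite includes exactly that audit.

## Known limitations

* The conditional-independence assumption above is untestable from the
  marker and covariates alone at this interface.
* The default in-sample LR estimation is optimistic; use
  `posterior_crossfit()` when the IDI is the headline number.
* The IDI's asymptotic SE ignores estimation noise in the LR; p-values for
  in-sample-updated posteriors should be read as descriptive.
* Chained-equation imputation uses linear/logistic conditionals only (no
  predictive-mean matching), and classical Rubin degrees of freedom (no
  Barnard-Rubin small-sample adjustment).
* Decision-curve analysis / net benefit, continuous NRI and the Brier score
  are out of scope.
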