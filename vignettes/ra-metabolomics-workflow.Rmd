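---
title: "Diagnosing rheumatoid arthritis from serum metabolite profiles: models and design choices"
author: "rametab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing rheumatoid arthritis from serum metabolite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rametab)
```

## The problem

Rheumatoid arthritis (RA) lacks a single robust diagnostic metabolite, but the
disease perturbs serum concentrations of many metabolites at once. A
multivariate pattern over a semiquantitative metabolite profile — hundreds of
putative metabolites measured by GC-MS and LC-MS — can therefore discriminate
RA patients from healthy controls, and from patients with another inflammatory
joint disease (psoriatic arthritis, PsoA), even when no single metabolite is
decisive. `rametab` implements that diagnostic workflow end to end:
supervised latent-variable classification, cross-validated diagnosis,
external-cohort validation, and metabolite-level interpretation.

Because the clinical cohorts this workflow was designed around were never
deposited, the package ships a synthetic cohort generator that reproduces the
*statistical structure* of such a study — the group sizes, the metabolite
counts, the planted marker directions, and disease-unrelated systematic
variation — so that every stage is testable without any download.

## The model: OPLS-DA with a single predictive component

Let $X$ be the $n \times K$ matrix of preprocessed metabolite intensities and
$y \in \{+1, -1\}^n$ the class coding (disease group positive, by
convention). Orthogonal projections to latent structures discriminant
analysis (OPLS-DA) decomposes $X$ into

$$X = t\,p^\top + \sum_{j=1}^{A_o} t_{o,j}\,p_{o,j}^\top + E,$$

one *predictive* component $(t, p)$ whose score correlates with $y$, and
$A_o$ *orthogonal* components $(t_{o,j}, p_{o,j})$ that capture systematic
variation uncorrelated with the class contrast — sex, age, sampling and
experimental effects. With a single response every step is closed form; the
NIPALS iteration in `fit_opls()` is, per orthogonal round,

1. $w = X^\top y_c / (y_c^\top y_c)$, normalised ($y_c$ the centred response);
2. $t = Xw$, $p = X^\top t / (t^\top t)$;
3. $w_o = p - (w^\top p)\,w$, normalised; $t_o = X w_o$,
   $p_o = X^\top t_o/(t_o^\top t_o)$;
4. deflate $X \leftarrow X - t_o p_o^\top$;

and finally the predictive component and response loading
$c = t^\top y_c/(t^\top t)$ on the filtered matrix. Fitted models always
satisfy $w^\top w_{o,j} = 0$ and $\mathrm{corr}(t_{o,j}, y) = 0$ to numerical
precision, and the sums of squares of the predictive, orthogonal and residual
parts add up to that of $X$ exactly; the test suite asserts all three on
every fit.

Prediction of a new sample removes the fitted orthogonal variation
($t_o = x^\top w_o$, $x \leftarrow x - t_o\,p_o$ per component) and converts
the predictive score into a predicted response
$\hat y = t\,c + \bar y$. A direct consequence of this projection is that
adding any multiple of an orthogonal *loading* $p_{o,j}$ to a test sample —
i.e. contaminating it with exactly the kind of structured nuisance the model
has isolated — leaves $\hat y$ unchanged to machine precision. (The
orthogonal *weight* $w_{o,j}$ is not an invariance direction: the correction
step subtracts $t_o\,p_o$, so a weight-direction perturbation leaves behind
$\alpha(w_o - p_o)$, which has a non-zero projection on $w$ whenever
orthogonal variation exists. The invariance test therefore perturbs along
the loadings, where the mathematical property actually lives.)

### Decision rule and Q²

The decision threshold is the training mean of the coded response
(equivalently zero on the centred response): predicted responses at or above
it are called positive, with the exact-threshold tie deterministically
resolved toward the positive class. With the groups re-balanced (as in the
external validation design) this coincides with the midpoint convention of
reading negative predicted values as controls and positive values as
disease. Cross-validated predictive ability is summarised as
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}(y)$ over out-of-fold predictions.

### p(corr)

Interpretation uses the correlation loading
$p(\mathrm{corr})_k = \mathrm{corr}(t, X^{f}_{\cdot k})$, the Pearson
correlation between the predictive score and metabolite $k$'s column of the
orthogonality-filtered training matrix — a scale-free measure in $[-1, 1]$ of
each metabolite's discriminatory capability. Heat-map columns and report
tables are ordered by it, from the largest negative to the largest positive
correlation to the disease class.

## Preprocessing

Metabolite intensities are positive and right-skewed, so the default
pipeline takes natural logs and then autoscales (unit variance: centre by
the training mean, divide by the training standard deviation, $n-1$
denominator). Pareto scaling (divide by $\sqrt{\mathrm{SD}}$) and plain
centring are available because the scaling used by commercial chemometrics
software is not always reported; unit variance is the conventional default
for discriminant modelling of metabolomics tables. Missing values are
imputed by the half-minimum rule (half the smallest observed training value
of that metabolite) before any transform. Metabolites with zero training
variance get scale 1 and a warning rather than an error, since a constant
column carries no information either way.

Scalers are *always refitted inside each cross-validation training fold*:
fold models never see held-out samples, in preprocessing or in fitting. The
`leaky_scaling` flag of `crossval_predict()` restores whole-matrix scaling
for comparison with workflows that scale once up front, but the honest
design is the default, and the no-leakage property is verified by mutating
held-out samples and checking that fold models are bit-identical.

## Cross-validated diagnosis and external validation

Diagnosis is evaluated by sevenfold cross-validation: one seventh of the
samples are left out, a scaler and an OPLS-DA model are fitted on the rest,
the held-out samples are predicted, and the procedure rotates until every
sample has been left out once. Folds are stratified by class — at 21 RA
versus 9 controls an unstratified partition can easily leave a training fold
without controls — with `stratify = FALSE` available for the plain random
variant. Separate models are always fitted for the RA-versus-control and
RA-versus-PsoA contrasts.

External validation mirrors the follow-up-study design: the variables of the
two studies must be identical, so both tables are restricted to the
metabolites *identified in both studies* (matched by trimmed,
case-insensitive name; no synonym matching, since no synonym table exists),
the discovery cohort is subsampled to nine observations per group with a
fixed seed, one model is fitted, and every sample of the second study is
predicted. Per-sample predicted responses, the serialized model and the
confusion metrics are all emitted.

## The synthetic cohort generator

`generate_cohort()` draws log intensities as

$$\log x_{ik} = \mu_k + \delta_{g(i),k} + \lambda_k z_i + \varepsilon_{ik},$$

with metabolite baselines $\mu_k \sim N(5, 1)$ (log units, i.e. intensities
around $e^5$ with a realistic dynamic range), residual noise
$\varepsilon_{ik} \sim N(0, 0.3^2)$, and a rank-1 nuisance term: a
per-sample latent $z_i \sim N(0, 0.5^2)$ with loadings
$\lambda_k \sim N(0,1)$ shared across all metabolites. Defaults reproduce
the targeted study design: 21 RA / 9 control / 17 PsoA samples, 267
putative metabolites, 83 identified; the paired validation cohort has
14 RA / 20 controls, 240 putative metabolites, 58 identified, exactly 52 of
them shared by name with the first study. Shared metabolites keep their
baselines across the two studies (the profiles must be comparable for a
model to transfer), while noise and nuisance are drawn independently.

Three generator design choices deserve explanation:

* **Planted effects are contrast-faithful.** The 9 RA-versus-control markers
  (3 increased, 6 decreased in RA) and the 19 RA-versus-PsoA markers are
  planted so that each pairwise contrast differs *exactly* by its own
  marker set: controls sit at baseline, RA is shifted by the RA-vs-control
  effects, and PsoA sits at the RA level minus the RA-vs-PsoA effects. This
  matches how the two marker lists are defined (each against its own
  reference group) and keeps the two contrasts separately recoverable; it
  also implies PsoA shares part of the RA perturbation pattern relative to
  healthy controls, which is biologically the expected behaviour for two
  inflammatory joint diseases.
* **Effect magnitude 0.8 log units.** Only directions and P values of the
  markers are published, never effect sizes. 0.8 was chosen once so that the
  default group sizes give strong but imperfect separation, qualitatively in
  the 80–95% sensitivity/specificity regime of a realistic study; the
  reported P values are carried as metadata only.
* **The nuisance latent is orthogonal by construction.** $z$ is residualised
  against the group factor, so its group means are exactly zero and it is
  uncorrelated with every class contrast on every subset of groups. This is
  the strict sense in which sex/age/batch variation is "orthogonal
  variation": the generator cleanly separates the predictive and orthogonal
  subspaces so that each can be planted and recovered independently. Real
  confounders only approximate this — in a cohort of 30 a confounder
  correlates with diagnosis by chance at $|r| \sim 0.2$, which genuinely
  degrades marker ranking and is not something any method can undo — so
  passing recovery tests on synthetic data does not promise the same
  ranking fidelity on real, partially confounded cohorts. A side effect of
  the exact-orthogonality constraint is a slight pessimism of cross-validated
  metrics under the null (held-out samples' nuisance values are weakly
  anti-correlated with the training group means), visible as null
  sensitivities/specificities a few points below 50%; the chance-level test
  bands account for this.

The generator does *not* emulate chromatographic drift, batch alignment
artefacts, metabolite covariance networks, censored (limit-of-detection)
missingness, or platform-specific intensity distributions. Sex and age
covariates are derived from $z$ for interpretability, not calibrated to any
population.

## Univariate reporting and heat maps

The metabolite-level report uses two-sided Student's t-tests for samples
with equal variance (pooled variance) on raw intensities, with **no
correction for multiple testing** — the univariate P values illustrate each
metabolite's individual impact and the primary result is the multivariate
prediction, so uncorrected values are reported deliberately and flagged as
such. Direction is `increased`/`decreased` by the group-mean difference.
Standard scores for the heat maps are computed against the *reference
group's* mean and SD ($n-1$ denominator; the population-SD convention would
change nothing qualitatively) on raw intensities, truncated to $\pm 2$ for
display, with metabolites ordered by p(corr) and only identified metabolites
shown by default.

## Numerical choices and degenerate inputs

* Weight normalisation guards divide-by-zero at $10^{-12}$; if no orthogonal
  variation remains, extraction stops early with a warning.
* Zero-variance metabolites: scale 1 (scaler), p(corr) 0 (ranking), z = 0
  (standard scores), t = 0 / p = 1 (t-test) — all with warnings.
* A constant response, a single-class training set, or more orthogonal
  components than samples are hard errors.
* Ties at the decision threshold classify as positive, deterministically.
* All randomness (generator, fold assignment, balancing subsample) flows
  through explicit seeds; identical seeds give bit-identical artefacts.

## Problem sizes used by the test suite

Unit tests run on small synthetic cohorts (6–8 samples per group, 36–40
metabolites) where the full design adds nothing; the statistical
property tests run at the study design sizes (21/9 per cohort, 267
metabolites) over 20–50 replicate seeds, and the model-invariant tests use
100 random instances at $n = 30$, $K = 50$. These sizes were chosen to make
the Monte Carlo bands tight enough to be meaningful while keeping the whole
suite fast.

## Known limitations

* Single binary response only: multi-class OPLS-DA, O2PLS and kernel
  variants are out of scope, as are ROC analysis and variable selection.
* The generator's simplifications listed above mean that passing acceptance
  properties demonstrate correctness of the machinery, not clinical
  performance; the published operating points of the motivating study were
  computed on undeposited clinical cohorts and are not reproducible here.
* Metabolite identity matching across studies is by exact (case-folded)
  name; real cross-platform studies need curated identity mapping.
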