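---
title: "Methods: nested case-control biomarker analysis with measurement-error correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested case-control biomarker analysis with measurement-error correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocc)
```

`hemocc` implements the statistical machinery of a nested case-control study
of log-normally distributed hemostatic biomarkers — tissue plasminogen
activator (t-PA) antigen, D-dimer, and von Willebrand factor (VWF) — and
incident coronary heart disease, together with a meta-analytic layer that
harmonizes heterogeneous published estimates onto a common per-1-SD scale.
This vignette records the models, conventions and numerical choices in
enough detail to re-derive every number the package produces.

## 1. The synthetic cohort

Because participant-level data from such studies are not redistributable,
the package ships a generator with fully known ground truth. A cohort of
`n_participants` (default 18,912) adults aged 40–70 is simulated with:

* **Covariates** drawn independently: age uniform over the recruitment
  range, sex Bernoulli, recruitment period (5 stages), and the usual risk
  factors (smoking, diabetes, BMI, systolic blood pressure, total
  cholesterol, log triglycerides) with plausible moments.
* **Usual (long-term average) log marker levels** built as
  \(u = \mu + B(x - \mu_x) + \varepsilon\), where \(B\) contains the
  marker–covariate regression coefficients and
  \(\varepsilon \sim N(0,\ \Sigma_u - B\Sigma_x B^\top)\). Subtracting the
  covariate contribution makes the *marginal* covariance of \(u\) exactly
  the requested \(\Sigma_u\); the residual covariance must be positive
  definite or the constructor errors. Default marker–covariate coefficients
  are set to half the marginal associations one would tabulate in such a
  cohort, because correlated covariates jointly account for the remainder.
* **Baseline and repeat measurements** under the classical error model
  \(b = u + e_b\), \(r = u + e_r\), with
  \(\sigma_u^2 = \rho\,\sigma_b^2\) and
  \(\sigma_e^2 = (1-\rho)\,\sigma_b^2\), where \(\rho\) is the target
  regression dilution ratio (RDR) and \(\sigma_b\) the *baseline* SD of
  the log marker (defaults 0.5, 1.0, 0.4 — i.e. 1.6-, 2.7- and 1.5-fold
  differences per SD on the original scale). Repeat measurements are
  observed only in a subsample (default 371) about 11.6 years after
  baseline; an optional `rdr_decay_per_year` adds drift of usual levels.
* **Events** from
  \(\operatorname{logit} P(\text{case}) = \alpha +
    \sum_m \beta_m u_m/\sigma_{b,m} + \gamma^\top(x - \mu_x)\).
  Note the scaling convention: \(\beta_m\) (`true_log_or_per_sd`) is the
  log odds ratio per 1 **baseline** SD of the **usual** level. Under
  classical error this gives the two invariants the package tests: the
  naive fit on baseline levels estimates \(\approx \rho\,\beta_m\), and
  the measurement-error-corrected fit recovers \(\approx \beta_m\).

All randomness flows through named substreams
(`substream_seed()` / `with_substream()`), so e.g. drawing the
case-control sample never perturbs cohort generation.

```{r}
spec <- cohort_spec(n_participants = 3000, seed = 7)
cohort <- generate_cohort(spec)
round(c(sd_tpa = sd(cohort$tpa_log_base), cases = sum(cohort$is_case)), 3)
```

## 2. Nested case-control sampling and per-SD odds ratios

`sample_nested_case_control()` keeps every incident case and draws
`round(ratio × cases)` controls (default ratio 1.88) within frequency-matching
strata of sex × 5-year age band × recruitment period. Logistic models are
fit by a hand-written iteratively reweighted least squares (IRLS) routine
(`fit_logistic_irls()`): Newton scoring via QR-decomposed weighted least
squares, convergence when the largest coefficient change falls below 1e-8,
covariance from the inverse observed information, and explicit errors for
rank-deficient designs and perfect separation.

`or_per_sd_progressive()` standardizes the log marker (by the pooled SD by
default; the control-only SD is an option) and reports odds ratios per 1 SD
under nested adjustment tiers — minimal (age, sex, period), plus non-lipid
risk factors, plus lipids — restricting to complete cases at the widest
tier so \(n\) is constant across tiers. Effect modification is assessed by
likelihood-ratio tests of marker × modifier interactions.

## 3. Fifths with floated confidence intervals

Dose-response is summarized across fifths of the marker, with cut-offs
taken from the control distribution using R's default (type 7) quantiles
and ties assigned to the lower group. The grouped logistic fit yields
\(K-1\) contrasts against the bottom fifth with covariance \(V\).
*Floating absolute risk* re-expresses these so every group, including the
reference, carries its own variance: we seek
\(F = \operatorname{diag}(f_1,\dots,f_{K-1}) + f_0 J\) (the covariance the
contrasts would have if group-specific estimates were independent with
variances \(f_j\), sharing only the reference's \(f_0\)) that is closest to
\(V\) in Kullback–Leibler divergence,
\[
  \min_{f > 0}\; \tfrac12\!\left[\operatorname{tr}(F^{-1}V)
  + \log\det F - \log\det V - (K-1)\right].
\]
`float_variances()` minimizes this by BFGS on \(\log f\) with an analytic
gradient (using the Sherman–Morrison form of \(F^{-1}\)), started from the
moment heuristic \(f_0 = \overline{V_{j\ne k}}\),
\(f_j = V_{jj} - f_0\). \(K = 2\) is rejected as underdetermined. The
reported `se_ratio_range` — the range over group pairs of floated versus
conventional contrast SEs — should sit well within [0.9, 1.1] on balanced
designs, which the test suite verifies.

## 4. Regression dilution and correction to usual levels

`estimate_rdr()` regresses the repeat on the baseline measurement (plus age
and sex by default) in the serial subsample; the baseline coefficient is
the RDR. `corrected_or_per_sd()` then applies a two-stage correction:
predict usual levels for *every* participant from the calibration model,
refit the outcome model on predicted usual levels, and — crucially —
standardize by the **baseline** SD so that "per 1 SD" keeps its original
meaning. Under this convention corrected/naive log odds ratios equal
\(1/\text{RDR}\) up to sampling noise. The default confidence interval
bootstraps participants and repeats both stages (percentile interval, 500
replicates), propagating calibration uncertainty that the naive Wald
interval ignores. `rdr_time_trend()` regresses stability estimates on the
between-measurement gap by inverse-variance weighting.

## 5. Harmonizing and pooling published estimates

Published studies report on different scales. `harmonize_to_per_sd()`
converts each to a log risk ratio per 1 SD:

* `per_sd`: used as is;
* `extreme_quantiles` (top vs bottom third/quarter/fifth): divided by
  \(d_q = 2\varphi(\Phi^{-1}(1-q))/q\), the expected separation in SD units
  of the means of the top and bottom \(q\)-tails of a normal distribution
  (2.18, 2.54, 2.80 for thirds, quarters, fifths);
* `per_unit` / `per_log_unit`: multiplied by the study's reported SD on the
  corresponding scale.

Standard errors come from reported 95% CIs as
\((\log \text{hi} - \log \text{lo})/3.92\) and are transformed with the
estimate. Pooling uses DerSimonian–Laird random effects
(\(\tau^2 = \max\{0, (Q - df)/(\sum w - \sum w^2/\sum w)\}\),
\(I^2 = \max\{0, 100(Q-df)/Q\}\)), with REML optional. Heterogeneity
sources are explored by method-of-moments meta-regression, small-study
asymmetry by Egger's unweighted regression of \(y_i/se_i\) on \(1/se_i\)
(t-test, \(n-2\) df), and subgroup differences by a two-sample z-test on
subgroup-specific pooled estimates. `generate_study_estimates()` simulates
study sets by inverting the harmonization exactly, so round-trips are
lossless.

```{r}
d <- vapply(c(1/3, 1/4, 1/5), quantile_spacing, numeric(1))
round(d, 4)
```

## 6. Reproducible pipelines

`run_casecontrol_analysis()` and `run_meta_analysis()` run every stage and
write CSV tables plus a JSON manifest (seed, config hash, filtering counts,
file row counts) and a log of sample sizes at each step. The numbered
scripts under `analysis/` are thin drivers over these functions.

## Conventions worth restating

* Default generator parameters *are* the study conditions (cohort size,
  matching ratio 1.88, marker moments, RDR targets, repeat subsample 371).
* `true_log_or_per_sd` is per 1 baseline SD of usual levels (Section 1).
* Quantile cut-offs are type-7, control-based, ties to the lower group.
* Standardizing SD defaults to the pooled case+control sample.
* Floated variances require at least 3 groups.
* Bootstrap is the default CI for corrected odds ratios.
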