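# hemocc

Nested case-control analysis of hemostatic biomarkers — t-PA antigen,
D-dimer and von Willebrand factor — and incident coronary heart disease,
with measurement-error correction and meta-analytic harmonization.

## The scientific problem

Circulating hemostatic markers are measured once at baseline, but etiologic
interest is in *usual* (long-term average) levels. A single measurement
carries within-person variability, so naive per-1-SD odds ratios are
attenuated by the regression dilution ratio (RDR): if β is the log odds
ratio per baseline SD of the usual level, the naive fit on baseline levels
estimates ≈ RDR·β. The package implements the full analysis chain:

1. **Synthetic cohort** (`generate_cohort`) with known ground truth —
   covariates, correlated usual log marker levels, baseline/repeat
   measurements under the classical error model, and incident events — so
   every stage is testable without participant-level data.
2. **Nested case-control models** (`sample_nested_case_control`,
   `or_per_sd_progressive`, `interaction_lrt`) — frequency matching on
   sex × 5-year age band × period, hand-written IRLS logistic regression,
   odds ratios per 1 SD under progressive adjustment tiers.
3. **Floated risk** (`quantile_or_table`, `float_variances`) — odds ratios
   across control-defined fifths with floating absolute risk: the variance
   model F = diag(f₁…f_{K−1}) + f₀J closest to the contrast covariance V in
   Kullback–Leibler divergence, minimized by BFGS on log f with an analytic
   gradient.
4. **Regression dilution** (`estimate_rdr`, `corrected_or_per_sd`) —
   calibration regression of repeat on baseline measurements, prediction of
   usual levels for all participants, refit standardized by the baseline SD
   (so corrected/naive ≈ 1/RDR), bootstrap CIs that propagate calibration
   uncertainty.
5. **Meta-analytic harmonization** (`harmonize_to_per_sd`,
   `pool_random_effects`, `meta_regress`, `egger_test`,
   `subgroup_compare`) — converting per-unit, per-log-unit and
   extreme-quantile contrasts (top vs bottom q-tile divided by
   d_q = 2φ(Φ⁻¹(1−q))/q) to a per-1-SD scale, DerSimonian–Laird pooling,
   heterogeneity and small-study diagnostics.
6. **Pipelines** (`run_casecontrol_analysis`, `run_meta_analysis`) writing
   CSV tables with a JSON manifest and run log.

See `vignettes/hemocc-methods.Rmd` for the models and conventions in full.

## Worked example

```r
library(hemocc)

spec <- cohort_spec(seed = 1)              # defaults are the study conditions
cohort <- generate_cohort(spec)            # 18,912 participants, 2,341 cases
cc <- case_control_data(
  cohort, sample_nested_case_control(cohort, ratio = 1.88, seed = 1))
table(cc$is_case)
#>    0    1
#> 4400 2341

or_per_sd_progressive(cc, "tpa_log_base")[, c("tier", "or", "ci_low", "ci_high")]
#>            tier   or ci_low ci_high
#> 1       minimal 1.14  1.084    1.20
#> 2 plus_nonlipid 1.07  1.017    1.13
#> 3    plus_lipid 1.02  0.968    1.08

quantile_or_table(cc, "tpa_log_base", adjustment_tiers()$plus_lipid)[,
  c("fifth", "or", "ci_low", "ci_high")]
#>   fifth   or ci_low ci_high      (floated CIs; fifth 1 is the reference
#> 1     1 1.00  0.879    1.14       and still gets an interval)
#> 2     2 1.19  1.062    1.34
#> 3     3 1.08  0.965    1.22
#> 4     4 1.06  0.946    1.19
#> 5     5 1.19  1.068    1.34

corrected_or_per_sd(cc, "tpa", ci_method = "naive")[,
  c("marker", "or", "ci_low", "ci_high", "rdr")]
#>   marker   or ci_low ci_high  rdr
#> 1    tpa 1.04  0.941    1.15 0.54

est <- generate_study_estimates(18, true_log_rr_per_sd = log(1.13),
                                tau2 = 0.005, seed = 1)
h <- harmonize_to_per_sd(est)
p <- pool_random_effects(h$log_rr_per_sd, h$se)
exp(c(p$pooled, p$ci_low, p$ci_high)); c(p$i2, p$tau2)
#> [1] 1.137 1.068 1.210
#> [1] 39.288  0.006
```

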