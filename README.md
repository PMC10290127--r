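# lcarisk

Latent class analysis for competing-risks survival stratification of
cancer-registry cohorts.

## The problem

Registry cohorts of colorectal cancer patients mix two kinds of death:
death from the cancer and death from everything else. Classifications built
from molecular features stratify tumour biology but cannot separate these
causes, so their survival curves confound tumour aggressiveness with
background mortality. `lcarisk` implements the complementary approach:
learn a small number of latent patient classes from routine categorical
indicators (age group, sex, race/ethnicity, tumour site, stage), show that
the classes carry the cause-of-death signal, and then use them to de-bias
cause-specific incidence estimates and subtype survival comparisons. It is
aimed at biostatisticians and epidemiologists working with registry-style
survival data.

## What is inside

* **Latent class model.** `lca()` fits the finite mixture of products of
  multinomials
  P(Y_i) = Σ_c π_c Π_j ρ_{j,c,y_ij}
  by EM over collapsed response patterns (flat-Dirichlet random restarts,
  monotone log-likelihood), returning an S3 model object with `print`,
  `summary`, `coef`, `logLik`, `predict`, `plot` and `simulate` methods.
  `lca_scan()` selects K by BIC/SABIC (AIC for small n) subject to
  normalized entropy ≥ 0.8, mean posterior ≥ 0.5 per class and a 5%
  smallest-class rule; `lca_bootstrap_lrt()` is a parametric bootstrap K vs
  K−1 test. `assign_classes()` applies the 0.5-posterior modal assignment;
  `reorder_classes()` and `project_classes()` align and transfer a fitted
  model across cohorts.
* **Competing risks.** `aalen_johansen()` (multi-state cumulative
  incidence, S + F₁ + F₂ = 1 exactly), `naive_cif()` (the biased 1 − KM
  comparator), `km_curve()` (weighted product-limit), and
  `cause_specific_cox()` / `multi_state_model()` (per-cause
  proportional-hazards fits, Efron ties, sandwich variance under weights).
* **Correction layer.** `class_mixture_cif()` (class-stratified mixture
  estimator that approaches Aalen–Johansen when classes capture the
  competing-risk heterogeneity), `rescaled_weights()` (exact marginal
  balancing weights), `adjusted_km_curves()`, `robust_score_test()`
  (weighting-corrected log-rank), `concordance_index()` (Harrell's C with
  w_i·w_j pair weights) and `adjustment_report()` (before/after comparison
  per subtype pair).
* **Synthetic registry generator.** `simulate_cohort()` with
  `default_config()` — the published four-class profile (prevalences
  47.63/30.76/15.94/5.67%, the class-conditional indicator table, cancer
  vs other-cause hazard ratios (1, 1.20, 1.41, 1.12) and
  (1, 2.82, 0.72, 0.22)) with hazards calibrated so ~55% of patients die
  and the median follow-up is ~47 months — plus scenario configurations
  `competing_hazard_config()` and `confounded_subtype_config()`.
* **Pipeline and CLI.** `run_pipeline()` chains
  simulate → scan → fit → assign → survival → adjust → report
  deterministically from one seed; `inst/cli/lcarisk.R` exposes the same
  stages as shell subcommands.

## Worked example

```r
library(lcarisk)
cohort <- simulate_cohort(default_config(n_patients = 5000, seed = 7))
fit <- reorder_classes(lca(~ age_group + sex + race + site + stage,
                           cohort, K = 4, nrep = 10, tol = 1e-8, seed = 1))
summary(fit)
#> Latent class model (4 classes, 5000 observations)
#>   logLik -23900.46  free parameters 47
#>   class prevalences: 0.4719 0.3015 0.1529 0.0738
#>   indicators: age_group, sex, race, site, stage
#>   AIC 47894.92  BIC 48201.23  SABIC 48051.88
#>   entropy (normalized) 0.8498  raw 1040.90
#>   smallest modal class share 0.0536; unassigned fraction 0.0056
#>   mean posterior per assigned class: 0.924 0.929 0.937 0.995

hr <- multi_state_model(cohort$time_months, cohort$event,
                        factor(cohort$true_class))
as.data.frame(hr)[, c("cause", "level", "hr", "ci_low", "ci_high")]
#>   cause level    hr ci_low ci_high
#> 1     1     1 1.000     NA      NA
#> 2     1     2 1.347  1.193   1.522
#> 3     1     3 1.469  1.286   1.679
#> 4     1     4 1.028  0.837   1.262
#> 5     2     1 1.000     NA      NA
#> 6     2     2 2.817  2.486   3.194
#> 7     2     3 0.679  0.543   0.849
#> 8     2     4 0.214  0.126   0.365
```

The fitted prevalences recover the generating mixture (0.4763, 0.3076,
0.1594, 0.0567) up to sampling error at n = 5000; normalized entropy 0.85
indicates clear class separation, and every class keeps a mean assigned
posterior above 0.9. The multi-state fit recovers the generating hazard
structure: cancer-death risk is elevated in classes 2–3 while other-cause
death is concentrated in class 2 (HR 2.82) and nearly absent in class 4
(HR 0.21) — the pattern that makes class-adjustment of subtype curves
worthwhile.

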