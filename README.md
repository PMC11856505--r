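# kidlb — live-birth prediction from Day 2 embryo morphokinetics

`kidlb` builds and stress-tests penalized additive logistic models of
known-implantation live birth (KID_LB) after Day 2 embryo transfer, from
time-lapse morphokinetic annotations. It is written for reproductive
biostatisticians and embryologists who want to understand — on fully
reproducible synthetic cohorts — what maternal age does and does not
contribute to an embryo-scoring model.

## The model

For embryo *i* in treatment cycle *c(i)*:

```
logit P(y_i = 1) = b0 + f_t2(t2_i) + [ f_age(age_c(i)) ] +
                   g_cc2(i) + b_MN * MN_i + u_c(i),    u_c ~ N(0, s_u^2)
```

* `t2` — time to the two-cell stage (hours post insemination), as a
  P-spline smooth (cubic B-splines, 10 basis functions, second-order
  difference penalty);
* `cc2 = t3 − t2` — second cell cycle duration, categorised short /
  medium / long (defaults 9.33 h and 11.45 h, configurable);
* `MN` — multinucleation flag;
* `u_c` — cycle-level random intercept, because double embryo transfers
  (DET) contribute two embryos sharing one pregnancy outcome;
* `f_age` — maternal-age smooth, present in the **Age Model** and absent
  in the **Base Model**.

Smoothing parameters and `s_u` are selected by Laplace-approximate REML;
model comparison uses `AIC = deviance + 2 × effective df`. Validation is a
clustered 5-fold cross-validation with 200 bootstrap resamples of the
held-out cycles per fold (1,000 AUC values), splitting cycles so DET pairs
are never separated. A 3×3 age-by-score tertile stratification with an
age-averaged counterfactual isolates how much of the Age Model's AUC is
between-stratum age separation rather than embryo ranking, and a ±2 h
ICSI t2 manipulation probes robustness to fertilisation-timing
uncertainty.

No clinical data ships with the package; a seeded generator
(`generate_cohort()`) produces cohorts with the study's structure
(865 SET + 641 DET cycles, 2,147 embryos, concordant DET outcomes,
nonlinear age and t2 effects, missing t4).

## Worked example

```r
library(kidlb)

coh  <- generate_cohort(generator_config(n_cycles = 400, seed = 11))
filt <- apply_det_concordance_filter(coh$cycles, coh$embryos)

fit_base <- fit_penalized_additive_logistic(base_model_spec(),
                                            filt$cycles, filt$embryos)
fit_age  <- fit_penalized_additive_logistic(age_model_spec(),
                                            filt$cycles, filt$embryos)
print(fit_age)
#> Penalized additive logistic model
#>   n = 570 embryos, deviance = 41.27, edf = 193.99, AIC = 429.25
#>   s(t2)              edf  2.01  p = 0.158
#>   s(maternal_age)    edf  2.00  p = 0.0762
#>   cc2_category       edf  2.00  p = 0.998
#>   multinucleated     edf  1.00  p = 0.955
#>   sigma_u = 5.279 (random intercept edf 188.0)

mf <- prepare_model_frame(filt$cycles, filt$embryos)
sprintf("in-sample AUC: base %.3f, age %.3f",
  auc_mann_whitney(predict_probability(fit_base, mf), mf$live_birth),
  auc_mann_whitney(predict_probability(fit_age,  mf), mf$live_birth))
#> "in-sample AUC: base 0.602, age 0.683"

cv <- bootstrap_cv_auc(age_model_spec(), filt$cycles, filt$embryos,
                       cv_config(k_folds = 5, n_resamples = 200, seed = 2))
print(cv)
#> Clustered 5-fold CV (within_fold_bootstrap), 1000 AUC values (0 degenerate)
#>   mean AUC 0.640, 95% CI [0.421, 0.827]

st <- build_stratification(fit_age, fit_base, filt$cycles, filt$embryos)
round(st$observed_lb, 3)
#>              score
#> age           lowest_score medium_score highest_score
#>   lowest_age         0.000        0.222         0.228
#>   medium_age         0.058        0.138         0.324
#>   highest_age        0.067        0.078         0.000
```

Reading the output: adding age lifts the in-sample AUC from 0.602 to
0.683, and the cross-validated mean (0.640) sits below the in-sample
value, as it should. The stratified observed live-birth rates fall with
age and rise with score; at this small example size (400 cycles) two
corner strata are empty or one-class. The counterfactual table
(`st$auc_age_averaged`) shows that fixing age at its tier mean collapses
the Age Model's within-stratum discrimination to the Base Model's — the
package's central observation: age separates patients, it does not rank a
patient's embryos.

`run_pipeline(run_config(output_dir = "out", seed = 1))` chains cohort
generation, screening, AIC selection, both model fits, cross-validation,
stratification and the sensitivity curves into one deterministic run with
all tables written as CSV/JSON.

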