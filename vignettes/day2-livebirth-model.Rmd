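---
title: "Modelling live birth after Day 2 embryo transfer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling live birth after Day 2 embryo transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Embryos transferred on Day 2 of in-vitro fertilisation carry a handful of
non-invasive time-lapse markers: the time to the two-cell stage (`t2`, in
hours post insemination), the duration of the second cell cycle
(`cc2 = t3 - t2`, categorised short / medium / long), and a multinucleation
flag. The clinical question this package addresses is twofold: how well do
these markers predict a known-implantation live birth (KID_LB), and what
does adding maternal age to the model actually buy? Age is a strong
marginal predictor of IVF success, but within one patient's cohort of
embryos it is a constant — so a model that leans on age may look far better
on paper than it is for the task of ranking sibling embryos.

Two model variants are therefore kept side by side throughout: a **Base
Model** (t2 smooth, cc2 category, multinucleation, cycle random intercept)
and an **Age Model** (Base plus a maternal-age smooth).

## The model

Both variants are penalized additive logistic models. For embryo $i$ in
treatment cycle $c(i)$,

$$
\operatorname{logit}\, P(y_i = 1) =
\beta_0 + f_{t2}(t2_i) + [\,f_{age}(a_{c(i)})\,] +
\gamma_{cc2(i)} + \beta_{MN}\,MN_i + u_{c(i)},
\qquad u_c \sim N(0, \sigma_u^2).
$$

The smooths are P-splines: cubic B-spline bases with 10 basis functions on
equally spaced knots over the observed range, penalized by the squared
second differences of their coefficients. Each smooth is reparameterised
with a sum-to-zero constraint so its level is absorbed by the intercept,
which keeps a model with two smooths identifiable; the penalty null space
of the constrained block is the straight line, so an infinitely penalized
smooth degrades gracefully to a linear effect. Outside the training range
the basis is continued linearly.

The cycle-level random intercept is the unit of clustering because a
double embryo transfer (DET) contributes two embryos that share one
pregnancy outcome — the cohort inclusion rule keeps only DET cycles where
both or neither embryo implanted. The random intercepts are treated as
ridge-penalized coefficients (penalty $1/\sigma_u^2$), i.e. a
Laplace/PQL-type approximation rather than exact integration; this is
documented as an approximation wherever it surfaces.

### Fitting

The penalized log-likelihood is maximized by iteratively reweighted least
squares with step-halving, so the penalized deviance never increases
across accepted steps; convergence is declared when the largest
coefficient change falls below $10^{-8}$ (at most 200 iterations), and
non-convergence sets a flag rather than raising an error. Because the
random-intercept cross-products are diagonal, each IRLS step is solved
through the Schur complement of the small fixed-effect block — the cost
per step is linear in the number of cycles, which is what makes the
bootstrap and sensitivity loops affordable.

Numerical safeguards: the linear predictor is clamped to $\pm 15$ before
forming weights, a ridge of $10^{-8}$ (escalated only if the system
degenerates) stabilizes the normal equations, and complete separation is
diagnosed from a near-zero deviance with diverging coefficients.

### Smoothing selection

Smoothing parameters and $\sigma_u$ are chosen by maximizing a
Laplace-approximate restricted likelihood (REML) over their logs with
Nelder–Mead, started from $\lambda = 1$, $\sigma_u = 0.5$; the inner loop
is the penalized IRLS fit, warm-started between criterion evaluations.
Hyperparameters are clamped to $e^{\pm 18}$ (with $\sigma_u \le 20$) and a
mild quadratic penalty beyond the clamps keeps the simplex from stalling
on the flat clamped plateau. If the optimizer fails outright, a log-spaced
grid search takes over and says so. The criterion can be multimodal in
near-flat directions; with the fixed start the procedure is deterministic,
which the test suite asserts.

### Effective degrees of freedom, AIC, p-values

Per-coefficient effective degrees of freedom are diagonal entries of the
influence matrix; the AIC used everywhere (including forward selection) is
`deviance + 2 * edf_total` with `edf_total` the full trace, random
intercepts included. A smooth's reported edf adds one for the level it
donates to the intercept, so a smooth shrunk to a line reports edf 2.
Term p-values are Wald statistics on the penalized coefficients with the
term's edf as degrees of freedom — approximate by construction, and
labelled as such. No multiple-testing correction is applied.

## Validation design

AUC is the Mann–Whitney probability that a random positive outranks a
random negative, computed from midranks (ties count one half) and verified
in the tests against an exhaustive pairwise oracle.

Cross-validation splits **cycles**, never embryos, into five folds of
near-equal cycle counts, so DET pairs are never separated. Within each
fold the model is fitted once to the training cycles and the held-out
embryos are scored at the population level (random intercept zero — a
held-out cycle has no fitted intercept); 200 bootstrap resamples of the
held-out cycles then each contribute one AUC, giving $5 \times 200 =
1{,}000$ values summarised by their mean and percentile 95% interval.
An alternative reading of the same design — repeating the whole 5-fold
split 200 times — is available as `cv_config(mode = "repeated_cv")`; the
within-fold bootstrap is the default. Resampling is always at cycle level
because embryo-level resampling would break the DET concordance structure
and be anti-conservative. A resample that contains a single outcome class
has no defined AUC; it is recorded as missing, excluded from the summary,
and counted.

## Stratification and the age-averaged counterfactual

Embryo-level maternal age and Age-Model scores are each cut into tertiles
(edges at the order statistics of ranks $\lceil n/3 \rceil$ and
$\lceil 2n/3 \rceil$; ties never split), giving nine strata. Per stratum
the package tabulates counts, observed live-birth rate, mean predicted
probability, and the AUCs of the Age Model, the Base Model, and a
counterfactual Age Model in which every embryo's age is replaced by its
age-tier's mean before re-scoring. If age acts additively, fixing it
within a stratum leaves only the morphokinetic ranking — so the
counterfactual AUCs should essentially reproduce the Base Model's, and the
Age Model's apparent advantage is revealed as between-stratum separation.
That is the package's headline phenomenon, asserted in the acceptance
tests with a 0.03 per-cell tolerance (the two models are fitted
independently, so exact equality is not expected).

Scores for these tables are in-sample, matching how the corresponding
analysis is usually presented; the optimism this entails is the reason the
cross-validated AUCs are reported alongside. Tier means are arithmetic
means of embryo-level ages.

One caveat worth stating plainly: population-level predicted
*probabilities* (random intercept set to zero) are conditional, not
marginal, quantities. When $\hat\sigma_u$ is large the mean predicted
probability in a stratum can sit well below the observed rate even though
the *ranking* — and hence every AUC — is unaffected. $\hat\sigma_u$ is
estimated large here for a structural reason: after the concordance
filter, the two embryos of any DET cycle carry identical labels, which is
exactly the signature of strong cycle-level heterogeneity. Calibration of
absolute probabilities under this design is therefore not a claim this
package makes.

## ICSI t2 timing sensitivity

ICSI embryos have a precisely known fertilisation time; conventional IVF
does not, which delays the apparent morphokinetic clock. To probe whether
this threatens t2's usefulness, the ICSI embryos' t2 is displaced over a
±2 h grid (0.1 h steps), the model is refitted at each displacement, and
the in-sample AUC traced. By default the smoothing parameters are selected
once at displacement zero and held fixed along the grid, so the curve's
very small AUC differences are not swamped by smoothing-parameter jitter;
full REML refitting and a rescore-without-refit mode are available as
options. cc2 is recomputed as $\max(0, t3 - t2)$ after the shift, with
affected rows flagged.

Two properties of this curve matter for interpretation. First, it is very
flat: on the default cohort the total AUC range across ±2 h is below about
0.01, so t2 is robust to realistic clock uncertainty — the practical
conclusion. Second, *because* it is flat, the argmax is a noisy estimator
of a planted clock offset, and refitting at every shift adds a tilt toward
zero (a misaligned mixture gives the smooth more in-sample room, and any
nonzero shift corrupts the recomputed cc2 covariate). The planted-offset
recovery experiment in the acceptance tests therefore uses a clean design:
SET-only cycles, no random intercept, balanced ICSI/IVF arms, a
t2-smooth-only specification, and the argmax averaged over three
replicate cohorts.

## The synthetic cohort generator

No clinical data ships with the package (the motivating data cannot be
shared), so every analysis runs on seeded synthetic cohorts built to carry
the structure the pipeline must handle:

* 1,506 cycles, 865 SET / 641 DET, hence 2,147 embryos, by default;
* maternal age from a truncated Normal(33.5, 4.5) on [24, 43] years — the
  bell shape of a clinical population. (A uniform option exists; it was
  not kept as the default because it concentrates the Age-Model score
  tertiles onto the age tertiles and empties the corner strata of the
  3×3 table, which real cohorts do not show.)
* t2 ~ Normal(26, 3) truncated above 18 hpi; cc2 from a three-component
  mixture putting ~70% of mass in the medium band (9.33–11.45 h);
  t4 = t3 + Normal(1, 0.8) truncated positive; tPNf below t2; ~10% of t4
  missing; all timings recorded to 0.01 h before outcomes are drawn;
* true effects (log-odds): decreasing sigmoids for age (span 2.4, centre
  33.5 y) and t2 (span 3.7, centre 26 hpi), −0.5 for multinucleation,
  −0.55/−0.5 for short/long cc2, intercept −1.68, cycle random intercept
  SD 0.6. These were calibrated once so the default cohort has a marginal
  live-birth rate near 0.165, age leading the single-variable screen with
  t2 second, and all nine age-by-score strata populated — and then frozen.
  Fragmentation is generated but carries no effect, so forward selection
  should reject it;
* DET outcomes are drawn once per cycle at the cycle-mean linear
  predictor, so both embryos share the label and the concordance rule
  holds by construction (a per-embryo mode with discordant cycles exists
  for exercising the filter);
* optional knobs for the sensitivity analysis: a uniform IVF clock delay,
  and an ICSI misalignment that makes recorded ICSI t2 understate the
  outcome-relevant timing.

One tension deserves the record: in a purely additive generative model,
the printed single-variable age discrimination of the motivating study and
the near-flat occupancy of its nine strata imply incompatible score–age
correlations. The defaults here favour stratum occupancy (which the
stratification analysis structurally requires) and accept a weaker age
effect; age still ranks first in the screen at most seeds, but at roughly
AUC 0.65 rather than 0.73.

What the generator does **not** emulate: morphology grading, Day 3+
kinetics, patient-level (multi-cycle) correlation, age-correlated
morphokinetics, selection of which embryos get transferred, or calibration
drift between clinics. Passing tests on these cohorts show the pipeline's
machinery is correct under its stated assumptions — they do not certify
performance numbers on real clinical data.

## Problem sizes and runtime choices

The test suite fits models at 1,506 cycles (the default cohort), runs
parameter-recovery at 2,000 cycles × 20 replicates, the full 5×200
bootstrap at the default size, and sensitivity curves at 1,500 cycles —
sizes chosen to keep the whole suite comfortably within a coffee break on
one core while leaving Monte-Carlo error small relative to every asserted
tolerance. `scripts/acceptance.R` regenerates everything from scratch at
the same sizes in a few minutes.

## Known limitations

* The random-effect treatment is PQL-like; variance components under
  perfect within-cluster label concordance are reported as fitted, not as
  estimates of a generative SD.
* Wald p-values on penalized terms are approximate.
* Absolute predicted probabilities are conditional (see above); use the
  scores for ranking and the stratified observed rates for calibration
  reading.
* The REML surface can be near-flat in single directions; different basins
  give nearly identical fits but different reported $\lambda$.
* Percentile CIs only; no BCa, no DeLong variance.
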