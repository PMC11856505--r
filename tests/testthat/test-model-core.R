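test_that("unpenalized linear-only fit matches an independent Newton solver", {
  for (seed in 1:5) {
    coh <- tiny_cohort(n_cycles = 150, seed = seed, set_fraction = 1,
                       random_intercept_sd = 0)
    mf <- prepare_model_frame(coh$cycles, coh$embryos)
    spec <- model_spec(list(linear_term("multinucleated"),
                            linear_term("fragmentation_pct"),
                            linear_term("t2")),
                       random_intercept = NULL)
    fit <- fit_penalized_additive_logistic(spec, coh$cycles, coh$embryos,
                                           lambda_mode = "fixed")
    X <- cbind(1, mf$multinucleated, mf$fragmentation_pct, mf$t2)
    oracle <- newton_logistic(X, mf$live_birth)
    expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-6)
  }
})

test_that("an infinitely penalized smooth collapses to a straight line", {
  coh <- tiny_cohort(n_cycles = 300, seed = 10)
  spec <- model_spec(list(smooth_term("t2")), random_intercept = NULL)
  fit <- fit_penalized_additive_logistic(spec, coh$cycles, coh$embryos,
                                         lambda_mode = "fixed",
                                         lambdas = list(`s(t2)` = 1e9))
  mf <- prepare_model_frame(coh$cycles, coh$embryos)
  ix <- fit$term_cols[["s(t2)"]]
  smooth_vals <- drop(eval_spline_basis(fit$blocks[["s(t2)"]],
                                        mf$t2) %*% fit$coefficients[ix])
  line <- fitted(lm(smooth_vals ~ mf$t2))
  expect_lt(max(abs(smooth_vals - line)), 1e-4)
  # and the reported smooth edf is the null-space dimension
  expect_lt(abs(fit$edf$terms[["s(t2)"]] - 2), 0.05)
})

test_that("the AIC identity holds exactly and edf ranges are respected", {
  coh <- tiny_cohort(n_cycles = 250, seed = 20)
  fit <- fit_penalized_additive_logistic(age_model_spec(), coh$cycles,
                                         coh$embryos)
  expect_equal(fit$aic, fit$deviance + 2 * fit$edf$total)
  for (lab in c("s(t2)", "s(maternal_age)")) {
    expect_gte(fit$edf$terms[[lab]], 2 - 1e-6)   # penalty null space
    expect_lte(fit$edf$terms[[lab]], 10)         # basis dimension
  }
  expect_true(fit$converged)
})

test_that("the penalized objective never increases across IRLS steps", {
  coh <- tiny_cohort(n_cycles = 300, seed = 30)
  fit <- fit_penalized_additive_logistic(base_model_spec(), coh$cycles,
                                         coh$embryos)
  expect_true(all(diff(fit$obj_trace) <= 1e-8))
})

test_that("REML smoothing selection is deterministic and shrinks null variance", {
  coh <- tiny_cohort(n_cycles = 200, seed = 40)
  s1 <- select_smoothing_reml(base_model_spec(), coh$cycles, coh$embryos)
  s2 <- select_smoothing_reml(base_model_spec(), coh$cycles, coh$embryos)
  expect_identical(s1$lambdas, s2$lambdas)
  expect_identical(s1$sigma_u, s2$sigma_u)

  # all-SET cohort generated without a random intercept: sigma_u -> 0
  coh0 <- generate_cohort(generator_config(n_cycles = 3000,
                                           set_fraction = 1,
                                           random_intercept_sd = 0,
                                           seed = 41))
  s0 <- select_smoothing_reml(age_model_spec(), coh0$cycles, coh0$embryos)
  expect_lt(s0$sigma_u, 0.1)
})

test_that("a truly linear effect is smoothed to roughly two degrees of freedom", {
  eff <- true_effects(f_t2 = function(t) -0.25 * (t - 26),
                      f_age = function(a) rep(0, length(a)))
  coh <- generate_cohort(generator_config(n_cycles = 2500, set_fraction = 1,
                                          random_intercept_sd = 0, seed = 21,
                                          true_effects = eff))
  spec <- model_spec(list(smooth_term("t2")), random_intercept = "cycle_id")
  fit <- fit_penalized_additive_logistic(spec, coh$cycles, coh$embryos)
  expect_lt(abs(fit$edf$terms[["s(t2)"]] - 2), 0.5)
})

test_that("population-level scores behave as probabilities and rank correctly", {
  coh <- tiny_cohort(n_cycles = 200, seed = 50)
  fit <- fit_penalized_additive_logistic(base_model_spec(), coh$cycles,
                                         coh$embryos)
  mf <- prepare_model_frame(coh$cycles, coh$embryos)
  p <- predict_probability(fit, mf)
  expect_true(all(p > 0 & p < 1))
  # row-order invariance
  perm <- sample(nrow(mf))
  expect_equal(predict_probability(fit, mf[perm, ]), p[perm])
  # zeroed coefficients score exactly 0.5 everywhere
  fit0 <- fit
  fit0$coefficients[] <- 0
  fit0$u[] <- 0
  expect_equal(predict_probability(fit0, mf), rep(0.5, nrow(mf)))
  # monotonicity in a linear term with nonzero coefficient
  mf1 <- mf; mf1$multinucleated <- 0L
  mf2 <- mf; mf2$multinucleated <- 1L
  d <- predict_probability(fit, mf2) - predict_probability(fit, mf1)
  b_mn <- fit$coefficients[["multinucleated"]]
  expect_true(all(sign(d) == sign(b_mn)))
  # unseen factor level is rejected by name
  mf_bad <- mf
  mf_bad$cc2_category <- as.character(mf_bad$cc2_category)
  mf_bad$cc2_category[1] <- "ultra_long"
  expect_error(predict_probability(fit, mf_bad), "ultra_long")
})

test_that("fitted-cycle predictions require training cycles", {
  coh <- tiny_cohort(n_cycles = 100, seed = 60)
  fit <- fit_penalized_additive_logistic(base_model_spec(), coh$cycles,
                                         coh$embryos)
  mf <- prepare_model_frame(coh$cycles, coh$embryos)
  p_fit <- predict_probability(fit, mf, use_random_effect = "fitted")
  expect_equal(length(p_fit), nrow(mf))
  mf_new <- mf
  mf_new$cycle_id[1] <- "C99999"
  expect_error(predict_probability(fit, mf_new,
                                   use_random_effect = "fitted"),
               "absent from training")
})

test_that("scores agree with an independent additive-model implementation", {
  skip_if_not_installed("mgcv")
  coh <- generate_cohort(generator_config(n_cycles = 400, set_fraction = 1,
                                          random_intercept_sd = 0,
                                          seed = 70))
  mf <- prepare_model_frame(coh$cycles, coh$embryos)
  spec <- model_spec(list(smooth_term("t2"), linear_term("multinucleated")),
                     random_intercept = NULL)
  fit <- fit_penalized_additive_logistic(spec, coh$cycles, coh$embryos)
  ours <- predict_probability(fit, mf)
  ref <- mgcv::gam(live_birth ~ s(t2, k = 10, bs = "ps", m = c(2, 2)) +
                     multinucleated,
                   family = stats::binomial(), data = mf, method = "REML")
  theirs <- as.numeric(predict(ref, type = "response"))
  expect_lt(max(abs(ours - theirs)), 0.02)
})

test_that("models survive a serialization round trip", {
  coh <- tiny_cohort(n_cycles = 150, seed = 80)
  fit <- fit_penalized_additive_logistic(age_model_spec(), coh$cycles,
                                         coh$embryos)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  mf <- prepare_model_frame(coh$cycles, coh$embryos)
  expect_equal(predict_probability(back, mf), predict_probability(fit, mf),
               tolerance = 1e-12)
  expect_equal(back$aic, fit$aic)
  expect_identical(back$train_fingerprint, fit$train_fingerprint)
})

test_that("forward selection keeps real effects and drops the null candidate", {
  coh <- tiny_cohort(n_cycles = 600, seed = 90)
  base <- model_spec(list(), random_intercept = "cycle_id")
  sel <- aic_forward_selection(
    list(smooth_term("t2"), linear_term("multinucleated"),
         linear_term("fragmentation_pct")),
    base, coh$cycles, coh$embryos)
  labs <- vapply(sel$terms, `[[`, "", "label")
  expect_true("s(t2)" %in% labs)
  expect_false("fragmentation_pct" %in% labs)
  log <- attr(sel, "selection_log")
  expect_true(all(diff(log$aic[log$accepted]) <= 0))
  # duplicated candidate is a precondition error
  expect_error(
    aic_forward_selection(list(smooth_term("t2")), base_model_spec(),
                          coh$cycles, coh$embryos),
    "already in base")
  # empty candidate list returns the base spec
  expect_identical(
    aic_forward_selection(list(), base_model_spec(), coh$cycles,
                          coh$embryos, lambda_mode = "reml")$terms,
    base_model_spec()$terms)
})

test_that("one-class outcomes are rejected up front", {
  coh <- tiny_cohort(n_cycles = 50, seed = 95)
  coh$embryos$live_birth <- 0L
  expect_error(
    fit_penalized_additive_logistic(base_model_spec(), coh$cycles,
                                    coh$embryos),
    "both outcome classes")
})
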