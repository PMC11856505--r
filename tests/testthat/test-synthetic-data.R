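test_that("default cohort composition matches the study design", {
  coh <- generate_cohort(generator_config(seed = 9))
  expect_equal(nrow(coh$cycles), 1506)
  expect_equal(sum(coh$cycles$transfer_type == "SET"), 865)
  expect_equal(nrow(coh$embryos), 865 + 2 * 641)   # 2147 embryos
  expect_setequal(unique(table(coh$embryos$cycle_id)[
    coh$cycles$cycle_id[coh$cycles$transfer_type == "DET"]]), 2)
})

test_that("generation is bit-identical under the same config and seed", {
  a <- generate_cohort(generator_config(n_cycles = 120, seed = 77))
  b <- generate_cohort(generator_config(n_cycles = 120, seed = 77))
  expect_identical(a$cycles, b$cycles)
  expect_identical(a$embryos, b$embryos)
  c2 <- generate_cohort(generator_config(n_cycles = 120, seed = 78))
  expect_false(identical(a$embryos, c2$embryos))
})

test_that("morphokinetic ordering invariants hold for every embryo", {
  emb <- generate_cohort(generator_config(n_cycles = 400, seed = 3))$embryos
  expect_true(all(emb$t2 > 0))
  expect_true(all(emb$t3 >= emb$t2))
  expect_true(all(emb$t4 >= emb$t3, na.rm = TRUE))
  expect_true(all(emb$tPNf <= emb$t2))
  expect_true(all(emb$fragmentation_pct >= 0 & emb$fragmentation_pct <= 100))
})

test_that("null scenario recovers the configured marginal live-birth rate", {
  cfg <- generator_config(n_cycles = 5000, true_effects = null_effects(0.2),
                          random_intercept_sd = 0, seed = 123)
  coh <- generate_cohort(cfg)
  # outcomes are cycle-level draws; Monte-Carlo SE on the cycle scale
  rate <- mean(tapply(coh$embryos$live_birth, coh$embryos$cycle_id, max))
  se <- sqrt(0.2 * 0.8 / 5000)
  expect_lt(abs(rate - 0.2), 3 * se)
})

test_that("a strong t2 effect alone yields discriminating timings", {
  eff <- true_effects(f_age = function(a) rep(0, length(a)))
  coh <- generate_cohort(generator_config(n_cycles = 2000, seed = 17,
                                          true_effects = eff))
  emb <- coh$embryos
  auc_t2 <- auc_mann_whitney(-emb$t2, emb$live_birth)
  expect_gt(auc_t2, 0.5)
})

test_that("concordance filter removes only discordant DET cycles", {
  coh <- generate_cohort(generator_config(n_cycles = 60, seed = 5))
  # generator enforces concordance: the filter must be a no-op
  filt <- apply_det_concordance_filter(coh$cycles, coh$embryos)
  expect_equal(filt$n_removed, 0)
  expect_identical(filt$embryos, coh$embryos)

  # plant one discordant DET cycle
  det_id <- coh$cycles$cycle_id[coh$cycles$transfer_type == "DET"][1]
  rows <- which(coh$embryos$cycle_id == det_id)
  coh$embryos$live_birth[rows] <- c(0L, 1L)
  expect_message(
    filt2 <- apply_det_concordance_filter(coh$cycles, coh$embryos),
    "removed 1 discordant")
  expect_equal(filt2$n_removed, 1)
  expect_false(det_id %in% filt2$cycles$cycle_id)
  expect_false(any(filt2$embryos$cycle_id == det_id))

  # all-SET cohorts pass through untouched
  set_coh <- generate_cohort(generator_config(n_cycles = 40,
                                              set_fraction = 1, seed = 2))
  filt3 <- apply_det_concordance_filter(set_coh$cycles, set_coh$embryos)
  expect_identical(filt3$cycles, set_coh$cycles)
})

test_that("per-embryo outcome mode produces discordance that the filter cleans", {
  coh <- generate_cohort(generator_config(n_cycles = 300, seed = 8,
                                          det_outcome_mode = "per_embryo"))
  filt <- apply_det_concordance_filter(coh$cycles, coh$embryos)
  expect_gt(filt$n_removed, 0)
  det <- filt$cycles$cycle_id[filt$cycles$transfer_type == "DET"]
  spread <- tapply(filt$embryos$live_birth[filt$embryos$cycle_id %in% det],
                   filt$embryos$cycle_id[filt$embryos$cycle_id %in% det],
                   function(v) length(unique(v)))
  expect_true(all(spread == 1))
})

test_that("DET cycle with a missing embryo is a data-integrity error", {
  coh <- generate_cohort(generator_config(n_cycles = 30, seed = 4))
  det_id <- coh$cycles$cycle_id[coh$cycles$transfer_type == "DET"][1]
  emb <- coh$embryos[-which(coh$embryos$cycle_id == det_id)[1], ]
  expect_error(apply_det_concordance_filter(coh$cycles, emb),
               "exactly 2 embryos")
})

test_that("t4 missingness injection respects its rate", {
  emb <- generate_cohort(generator_config(n_cycles = 800, seed = 31,
                                          t4_missing_rate = 0))$embryos
  expect_identical(inject_t4_missingness(emb, 0, seed = 1), emb)
  expect_true(all(is.na(inject_t4_missingness(emb, 1, seed = 1)$t4)))
  n <- nrow(emb)
  miss <- sum(is.na(inject_t4_missingness(emb, 0.3, seed = 99)$t4))
  expect_gte(miss, qbinom(0.005, n, 0.3))
  expect_lte(miss, qbinom(0.995, n, 0.3))
  expect_error(inject_t4_missingness(emb, 1.2, seed = 1), "rate")
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(n_cycles = 1), "n_cycles")
  expect_error(generator_config(set_fraction = 1.4), "set_fraction")
  expect_error(generator_config(age_range = c(40, 30)), "age_range")
  expect_error(generator_config(icsi_fraction = -0.1), "icsi_fraction")
  expect_error(generator_config(random_intercept_sd = -1),
               "random_intercept_sd")
  expect_error(generator_config(t4_missing_rate = 2), "t4_missing_rate")
})

test_that("IVF clock delay shifts all IVF timings and only those", {
  cfg0 <- generator_config(n_cycles = 200, seed = 55, t4_missing_rate = 0)
  cfg1 <- generator_config(n_cycles = 200, seed = 55, t4_missing_rate = 0,
                           ivf_delay = 1.4)
  a <- generate_cohort(cfg0); b <- generate_cohort(cfg1)
  ivf_rows <- a$embryos$cycle_id %in%
    a$cycles$cycle_id[a$cycles$insemination == "IVF"]
  expect_equal(b$embryos$t2[ivf_rows], a$embryos$t2[ivf_rows] + 1.4)
  expect_equal(b$embryos$t3[ivf_rows], a$embryos$t3[ivf_rows] + 1.4)
  expect_equal(b$embryos$t2[!ivf_rows], a$embryos$t2[!ivf_rows])
})
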