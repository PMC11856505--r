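#' True generative effects for the synthetic cohort
#'
#' Log-odds contributions used by [generate_cohort()]. The defaults were
#' chosen once so that the default cohort reproduces the qualitative
#' structure the analysis assumes: a marginal live-birth rate near 0.165, a
#' nonlinear decreasing maternal-age effect that dominates single-variable
#' discrimination, a weaker nonlinear t2 effect, and small deselection
#' penalties for multinucleation and short/long second cell cycles.
#' Fragmentation carries no true effect, so it should be screened out.
#'
#' @param f_age function years -> log-odds (default: decreasing sigmoid
#'   centred at 33.5 y with total span 2.4, sized so that the nine
#'   age-by-score strata all stay populated while age still leads the
#'   single-variable screen).
#' @param f_t2 function hours -> log-odds (default: decreasing sigmoid
#'   centred at 26 hpi with span 3.7).
#' @param beta_mn log-odds penalty for multinucleation.
#' @param beta_cc2_short,beta_cc2_long log-odds versus a medium cc2.
#' @param intercept baseline log-odds.
#' @return object of class `true_effects`.
#' @export
true_effects <- function(
    f_age = function(a) 2.4 * (0.5 - stats::plogis((a - 33.5) / 3)),
    f_t2 = function(t) 3.7 * (0.5 - stats::plogis((t - 26) / 3)),
    beta_mn = -0.5, beta_cc2_short = -0.55, beta_cc2_long = -0.5,
    intercept = -1.68) {
  stopifnot(is.function(f_age), is.function(f_t2))
  structure(list(f_age = f_age, f_t2 = f_t2, beta_mn = beta_mn,
                 beta_cc2_short = beta_cc2_short,
                 beta_cc2_long = beta_cc2_long, intercept = intercept),
            class = "true_effects")
}

#' Synthetic cohort generator configuration
#'
#' Defaults mirror the composition of the study cohort the analysis is
#' designed for: 1,506 treatment cycles of which 865 are single embryo
#' transfers (SET) and the rest double transfers (DET), giving
#' 865 + 2 x 641 = 2,147 transferred embryos.
#'
#' @param n_cycles number of treatment cycles (>= 2).
#' @param set_fraction fraction of SET cycles in \[0, 1\] (applied by
#'   rounding).
#' @param age_range maternal age range in years.
#' @param age_distribution `"truncnorm"` (default): ages drawn from a
#'   Normal(`age_mean`, `age_sd`) truncated to `age_range`, the bell shape
#'   of a clinical IVF population; `"uniform"` spreads ages evenly instead.
#' @param age_mean,age_sd location and spread of the truncated-normal age
#'   draw (years).
#' @param icsi_fraction probability that a cycle is ICSI (vs IVF).
#' @param true_effects a [true_effects()] object.
#' @param random_intercept_sd SD of the cycle-level log-odds intercept
#'   (>= 0). Note that label sharing within DET cycles induces additional
#'   within-cycle correlation on top of this.
#' @param t4_missing_rate probability each t4 annotation is missing.
#' @param det_outcome_mode `"shared_latent"` (default) draws one live-birth
#'   label per DET cycle from the logistic probability at the cycle-mean
#'   linear predictor, so cohort size is deterministic and the concordance
#'   rule holds by construction; `"per_embryo"` draws independent labels per
#'   embryo (discordant DET cycles then exist until
#'   [apply_det_concordance_filter()] removes them).
#' @param ivf_delay hours added to all IVF morphokinetic timings (tPNf, t2,
#'   t3, t4): conventional insemination delays the apparent clock relative
#'   to ICSI. Default 0; 1.4 h is the literature estimate for early
#'   cleavage.
#' @param icsi_misalignment hours by which recorded ICSI t2 understates the
#'   outcome-relevant timing (the outcome uses `t2 + icsi_misalignment` for
#'   ICSI embryos). Default 0; nonzero values plant a recoverable offset for
#'   the timing-sensitivity analysis.
#' @param seed integer RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_cycles = 1506L, set_fraction = 865 / 1506,
                             age_range = c(24, 43),
                             age_distribution = c("truncnorm", "uniform"),
                             age_mean = 33.5, age_sd = 4.5,
                             icsi_fraction = 0.7,
                             true_effects = kidlb::true_effects(),
                             random_intercept_sd = 0.6,
                             t4_missing_rate = 0.1,
                             det_outcome_mode = c("shared_latent",
                                                  "per_embryo"),
                             ivf_delay = 0, icsi_misalignment = 0,
                             seed = 1L) {
  if (!(is.numeric(n_cycles) && length(n_cycles) == 1L && n_cycles >= 2))
    stop_named("n_cycles", "must be an integer >= 2")
  if (!(is.numeric(set_fraction) && set_fraction >= 0 && set_fraction <= 1))
    stop_named("set_fraction", "must be in [0, 1]")
  if (!(length(age_range) == 2L && age_range[1] < age_range[2]))
    stop_named("age_range", "lower bound must be below upper bound")
  if (!(is.numeric(icsi_fraction) && icsi_fraction >= 0 &&
        icsi_fraction <= 1))
    stop_named("icsi_fraction", "must be in [0, 1]")
  if (!inherits(true_effects, "true_effects"))
    stop_named("true_effects", "must be a true_effects() object")
  if (!(is.numeric(random_intercept_sd) && random_intercept_sd >= 0))
    stop_named("random_intercept_sd", "must be >= 0")
  if (!(is.numeric(t4_missing_rate) && t4_missing_rate >= 0 &&
        t4_missing_rate <= 1))
    stop_named("t4_missing_rate", "must be in [0, 1]")
  structure(list(n_cycles = as.integer(n_cycles),
                 set_fraction = set_fraction, age_range = age_range,
                 age_distribution = match.arg(age_distribution),
                 age_mean = age_mean, age_sd = age_sd,
                 icsi_fraction = icsi_fraction, true_effects = true_effects,
                 random_intercept_sd = random_intercept_sd,
                 t4_missing_rate = t4_missing_rate,
                 det_outcome_mode = match.arg(det_outcome_mode),
                 ivf_delay = ivf_delay,
                 icsi_misalignment = icsi_misalignment,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a seeded synthetic IVF cohort
#'
#' Produces cycle and embryo tables with the statistical structure the
#' downstream analysis assumes. Cycle-level draws: maternal age uniform on
#' `age_range`, insemination method Bernoulli(`icsi_fraction`), random
#' intercept Normal(0, `random_intercept_sd`^2). Embryo-level draws: t2
#' truncated Normal(26, 3) above 18 hpi; cc2 from a three-component mixture
#' placing ~70% of mass in the medium band; t3 = t2 + cc2;
#' t4 = t3 + truncated Normal(1, 0.8) above 0; tPNf below t2;
#' multinucleation Bernoulli(0.25); fragmentation Beta-distributed with no
#' effect on outcome. All timings are recorded to 0.01 h (ages to 0.1 y),
#' the precision of time-lapse annotation, before the outcome is drawn.
#' Live birth is Bernoulli(logistic(linear predictor)) with DET labels
#' shared per cycle (see [generator_config()]).
#'
#' @param config a [generator_config()].
#' @return list with data frames `cycles` (cycle_id, maternal_age,
#'   transfer_type, insemination) and `embryos` (embryo_id, cycle_id, tPNf,
#'   t2, t3, t4, vp_duration, fragmentation_pct, multinucleated,
#'   live_birth); the generating config is attached as attribute `config`.
#' @examples
#' coh <- generate_cohort(generator_config(n_cycles = 20, seed = 7))
#' table(coh$cycles$transfer_type)
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop_named("config", "must be a generator_config() object")
  eff <- config$true_effects
  out <- withr::with_seed(config$seed, {
    nc <- config$n_cycles
    n_set <- round(config$set_fraction * nc)
    transfer <- rep(c("SET", "DET"), c(n_set, nc - n_set))
    insem <- ifelse(stats::runif(nc) < config$icsi_fraction, "ICSI", "IVF")
    age <- if (config$age_distribution == "truncnorm")
      rnorm_trunc(nc, config$age_mean, config$age_sd,
                  config$age_range[1], config$age_range[2])
    else
      stats::runif(nc, config$age_range[1], config$age_range[2])
    age <- round(age, 1)
    u <- stats::rnorm(nc, 0, config$random_intercept_sd)
    cycle_id <- sprintf("C%05d", seq_len(nc))
    n_emb <- ifelse(transfer == "SET", 1L, 2L)
    ci <- rep(seq_len(nc), n_emb)
    n <- length(ci)

    t2 <- rnorm_trunc(n, 26, 3, lower = 18)
    comp <- sample.int(3L, n, replace = TRUE, prob = c(0.15, 0.70, 0.15))
    cc2 <- numeric(n)
    cc2[comp == 1] <- rnorm_trunc(sum(comp == 1), 8.3, 0.8, 4, 9.32)
    cc2[comp == 2] <- rnorm_trunc(sum(comp == 2), 10.3, 0.5, 9.33, 11.45)
    cc2[comp == 3] <- rnorm_trunc(sum(comp == 3), 12.6, 1.2, 11.46, 20)
    t3 <- t2 + cc2
    t4 <- t3 + rnorm_trunc(n, 1, 0.8, lower = 0.05)
    tPNf <- t2 - rnorm_trunc(n, 2.5, 0.6, lower = 0.3)
    vp <- rnorm_trunc(n, 8, 1.2, lower = 2)
    vp[stats::runif(n) < 0.05] <- NA_real_
    mn <- stats::rbinom(n, 1L, 0.25)
    frag <- round(100 * stats::rbeta(n, 1.2, 8), 1)

    # IVF clock delay applies to every hpi annotation of IVF embryos
    is_ivf <- insem[ci] == "IVF"
    delay <- ifelse(is_ivf, config$ivf_delay, 0)
    t2 <- t2 + delay; t3 <- t3 + delay; t4 <- t4 + delay
    tPNf <- tPNf + delay

    # record to annotation precision before the outcome is drawn
    t2 <- round(t2, 2); t3 <- round(t3, 2); t4 <- round(t4, 2)
    tPNf <- round(tPNf, 2); vp <- round(vp, 2)

    t2_eff <- t2 + ifelse(is_ivf, 0, config$icsi_misalignment)
    ccterm <- ifelse(comp == 1, eff$beta_cc2_short,
                     ifelse(comp == 3, eff$beta_cc2_long, 0))
    eta <- eff$intercept + eff$f_age(age[ci]) + eff$f_t2(t2_eff) +
      eff$beta_mn * mn + ccterm + u[ci]
    if (any(!is.finite(eta)))
      stop_named("true_effects", "produced non-finite log-odds")

    if (config$det_outcome_mode == "shared_latent") {
      p_cyc <- stats::plogis(as.numeric(tapply(eta, ci, mean)))
      y <- stats::rbinom(nc, 1L, p_cyc)[ci]
    } else {
      y <- stats::rbinom(n, 1L, stats::plogis(eta))
    }

    emb_seq <- sequence(n_emb)
    embryos <- data.frame(
      embryo_id = sprintf("%s_E%d", cycle_id[ci], emb_seq),
      cycle_id = cycle_id[ci], tPNf = tPNf, t2 = t2, t3 = t3, t4 = t4,
      vp_duration = vp, fragmentation_pct = frag,
      multinucleated = as.integer(mn), live_birth = as.integer(y),
      stringsAsFactors = FALSE)
    cycles <- data.frame(cycle_id = cycle_id, maternal_age = age,
                         transfer_type = transfer, insemination = insem,
                         stringsAsFactors = FALSE)
    list(cycles = cycles, embryos = embryos)
  })
  out$embryos <- inject_t4_missingness(out$embryos, config$t4_missing_rate,
                                       derive_seed(config$seed, 101L))
  attr(out, "config") <- config
  out
}

#' Remove DET cycles with discordant outcomes
#'
#' The analysis includes a double transfer only when both embryos implanted
#' or neither did, so both carry the same live-birth label. This filter
#' drops every DET cycle whose two embryos disagree; SET cycles pass
#' through untouched.
#'
#' @param cycles,embryos cohort tables.
#' @return list with filtered `cycles`, `embryos`, and `n_removed`.
#' @export
apply_det_concordance_filter <- function(cycles, embryos) {
  if (!all(embryos$cycle_id %in% cycles$cycle_id))
    stop("embryos reference unknown cycle ids", call. = FALSE)
  det_ids <- cycles$cycle_id[cycles$transfer_type == "DET"]
  cnt <- table(factor(embryos$cycle_id, levels = det_ids))
  if (any(cnt != 2L))
    stop("data integrity: DET cycle(s) without exactly 2 embryos: ",
         paste(utils::head(names(cnt)[cnt != 2L], 5L), collapse = ", "),
         call. = FALSE)
  lab_spread <- tapply(embryos$live_birth[embryos$cycle_id %in% det_ids],
                       embryos$cycle_id[embryos$cycle_id %in% det_ids],
                       function(v) length(unique(v)))
  bad <- names(lab_spread)[lab_spread > 1L]
  if (length(bad))
    message(sprintf("concordance filter removed %d discordant DET cycle(s)",
                    length(bad)))
  list(cycles = cycles[!cycles$cycle_id %in% bad, , drop = FALSE],
       embryos = embryos[!embryos$cycle_id %in% bad, , drop = FALSE],
       n_removed = length(bad))
}

#' Inject missingness into t4 annotations
#'
#' @param embryos embryo table.
#' @param rate probability in \[0, 1\] that each t4 is set to missing.
#' @param seed integer seed.
#' @return the embryo table with some `t4` entries replaced by `NA`.
#' @export
inject_t4_missingness <- function(embryos, rate, seed) {
  if (!(is.numeric(rate) && rate >= 0 && rate <= 1))
    stop_named("rate", "must be in [0, 1]")
  if (rate == 0) return(embryos)
  withr::with_seed(as.integer(seed), {
    drop <- stats::runif(nrow(embryos)) < rate
    embryos$t4[drop] <- NA_real_
  })
  embryos
}
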