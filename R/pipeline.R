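#' Full-run configuration
#'
#' Bundles the settings of every pipeline stage. Exactly one input source is
#' allowed: a generator configuration (the default) or a pair of cohort CSV
#' paths.
#'
#' @param generate a [generator_config()], or `NULL` when reading a cohort.
#' @param cohort_paths length-2 character vector (cycles.csv, embryos.csv),
#'   or `NULL` when generating.
#' @param cc2_cutoffs a [cc2_cutoffs()].
#' @param n_basis smooth basis dimension for both models.
#' @param cv a [cv_config()].
#' @param sensitivity_grid shift grid in hours for the ICSI t2 curve.
#' @param models which models to run: `"both"`, `"base"` or `"age"`.
#' @param do_selection run the AIC forward-selection stage (fragmentation as
#'   the null candidate).
#' @param output_dir directory for the artifact bundle.
#' @param seed master seed; each stochastic stage consumes a derived
#'   sub-seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `kidlb_run_config`.
#' @export
run_config <- function(generate = generator_config(), cohort_paths = NULL,
                       cc2_cutoffs = kidlb::cc2_cutoffs(), n_basis = 10L,
                       cv = cv_config(), sensitivity_grid = seq(-2, 2, 0.1),
                       models = c("both", "base", "age"),
                       do_selection = TRUE, output_dir, seed = 1L,
                       log_level = c("info", "quiet")) {
  if (is.null(generate) == is.null(cohort_paths))
    stop_named("input", "exactly one of `generate` or `cohort_paths`")
  structure(list(generate = generate, cohort_paths = cohort_paths,
                 cc2_cutoffs = cc2_cutoffs, n_basis = as.integer(n_basis),
                 cv = cv, sensitivity_grid = sensitivity_grid,
                 models = match.arg(models), do_selection = do_selection,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "kidlb_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `generate` and
#' `cv` keys take nested maps of [generator_config()] / [cv_config()]
#' arguments.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. `seed = 42`).
#' @return a `kidlb_run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generate)) y$generate <- do.call(generator_config, y$generate)
  if (!is.null(y$cv)) y$cv <- do.call(cv_config, y$cv)
  if (!is.null(y$cc2_cutoffs))
    y$cc2_cutoffs <- do.call(cc2_cutoffs, y$cc2_cutoffs)
  if (!is.null(y$cohort_paths)) y$cohort_paths <- unlist(y$cohort_paths)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort generation (or reading) and the DET
#' concordance filter; the single-variable screen; AIC forward selection of
#' the null candidate (fragmentation); fitting of the Base and Age models;
#' clustered bootstrap cross-validation; the age-by-score stratification;
#' and the ICSI t2 sensitivity curves. All outputs are written under
#' `config$output_dir` as CSV/JSON plus a deterministic `run_log.txt`
#' (package version, config hash, stage sub-seeds, convergence flags). A
#' stage failure raises an error naming the stage; outputs of completed
#' stages are preserved.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kidlb_run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list()
  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  say("kidlb %s | config %s",
      as.character(utils::packageVersion("kidlb")),
      digest::digest(utils::capture.output(utils::str(cfg_for_hash)),
                     algo = "xxhash64"))

  stage("cohort", {
    if (!is.null(config$generate)) {
      gen_cfg <- config$generate
      gen_cfg$seed <- derive_seed(config$seed, 1L)
      coh <- generate_cohort(gen_cfg)
      say("cohort: generated %d cycles / %d embryos (sub-seed %d)",
          nrow(coh$cycles), nrow(coh$embryos), gen_cfg$seed)
    } else {
      coh <- read_cohort(config$cohort_paths[1], config$cohort_paths[2])
      say("cohort: read %d cycles / %d embryos", nrow(coh$cycles),
          nrow(coh$embryos))
    }
    filt <- apply_det_concordance_filter(coh$cycles, coh$embryos)
    say("cohort: concordance filter removed %d DET cycle(s)",
        filt$n_removed)
    res$cohort <- coh
    res$cycles <- filt$cycles
    res$embryos <- filt$embryos
    write_cohort(coh, dir = file.path(out_dir, "cohort"))
  })
  cycles <- res$cycles; embryos <- res$embryos

  stage("screening", {
    scr <- single_variable_screen(cycles, embryos,
                                  cutoffs = config$cc2_cutoffs)
    res$screening <- scr
    utils::write.csv(scr, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    say("screening: top variable %s (AUC %.3f); t4 threshold %.1f h",
        scr$variable[nrow(scr)], scr$auc[nrow(scr)],
        attr(scr, "t4_threshold"))
  })

  if (config$do_selection) stage("selection", {
    sel <- aic_forward_selection(
      list(linear_term("fragmentation_pct")),
      base_model_spec(config$cc2_cutoffs, config$n_basis),
      cycles, embryos)
    res$selection_log <- attr(sel, "selection_log")
    utils::write.csv(attr(sel, "selection_log"),
                     file.path(out_dir, "selection_log.csv"),
                     row.names = FALSE)
    say("selection: final terms = %s",
        paste(vapply(sel$terms, `[[`, "", "label"), collapse = " + "))
  })

  stage("models", {
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    mf <- prepare_model_frame(cycles, embryos, config$cc2_cutoffs)
    summ <- list()
    if (config$models != "age") {
      fb <- fit_penalized_additive_logistic(
        base_model_spec(config$cc2_cutoffs, config$n_basis),
        cycles, embryos)
      res$model_base <- fb
      write_model(fb, file.path(out_dir, "models", "base_model.json"))
      a <- auc_mann_whitney(predict_probability(fb, mf), mf$live_birth)
      res$auc_base_insample <- a
      summ$base <- data.frame(model = "base", aic = fb$aic,
                              auc_insample = a, edf_total = fb$edf$total,
                              sigma_u = fb$sigma_u, converged = fb$converged)
      say("models: base AUC %.3f (AIC %.1f, converged %s)", a, fb$aic,
          fb$converged)
    }
    if (config$models != "base") {
      fa <- fit_penalized_additive_logistic(
        age_model_spec(config$cc2_cutoffs, config$n_basis),
        cycles, embryos)
      res$model_age <- fa
      write_model(fa, file.path(out_dir, "models", "age_model.json"))
      a <- auc_mann_whitney(predict_probability(fa, mf), mf$live_birth)
      res$auc_age_insample <- a
      summ$age <- data.frame(model = "age", aic = fa$aic, auc_insample = a,
                             edf_total = fa$edf$total, sigma_u = fa$sigma_u,
                             converged = fa$converged)
      say("models: age AUC %.3f (AIC %.1f, converged %s)", a, fa$aic,
          fa$converged)
    }
    utils::write.csv(do.call(rbind, summ),
                     file.path(out_dir, "models", "model_summary.csv"),
                     row.names = FALSE)
  })

  stage("validation", {
    dir.create(file.path(out_dir, "cv"), showWarnings = FALSE)
    cvc <- config$cv
    cvc$seed <- derive_seed(config$seed, 5L)
    for (m in intersect(c("base", "age"),
                        if (config$models == "both") c("base", "age")
                        else config$models)) {
      sp <- if (m == "base")
        base_model_spec(config$cc2_cutoffs, config$n_basis)
      else age_model_spec(config$cc2_cutoffs, config$n_basis)
      cvr <- bootstrap_cv_auc(sp, cycles, embryos, cvc)
      res[[paste0("cv_", m)]] <- cvr
      jsonlite::write_json(
        list(model = m, mode = cvr$mode, mean_auc = cvr$mean_auc,
             ci95 = as.list(cvr$ci95), n_values = length(cvr$auc_values),
             n_degenerate = cvr$n_degenerate),
        file.path(out_dir, "cv", paste0("cv_report_", m, ".json")),
        digits = NA, auto_unbox = TRUE, pretty = TRUE)
      utils::write.csv(data.frame(auc = cvr$auc_values),
                       file.path(out_dir, "cv",
                                 paste0("auc_values_", m, ".csv")),
                       row.names = FALSE)
      say("validation: %s model mean CV AUC %.3f [%.3f, %.3f] (%d values)",
          m, cvr$mean_auc, cvr$ci95[["lo"]], cvr$ci95[["hi"]],
          length(cvr$auc_values))
    }
  })

  if (config$models == "both") stage("stratification", {
    strat <- build_stratification(res$model_age, res$model_base, cycles,
                                  embryos)
    res$stratification <- strat
    write_stratification(strat, file.path(out_dir, "stratification"))
    say("stratification: marginal counts %s",
        paste(c(rowSums(strat$counts), colSums(strat$counts)),
              collapse = "/"))
  })

  stage("sensitivity", {
    dir.create(file.path(out_dir, "sensitivity"), showWarnings = FALSE)
    for (m in intersect(c("base", "age"),
                        if (config$models == "both") c("base", "age")
                        else config$models)) {
      sp <- if (m == "base")
        base_model_spec(config$cc2_cutoffs, config$n_basis)
      else age_model_spec(config$cc2_cutoffs, config$n_basis)
      curve <- auc_vs_shift_curve(sp, cycles, embryos,
                                  grid = config$sensitivity_grid)
      res[[paste0("shift_curve_", m)]] <- curve
      utils::write.csv(data.frame(shift = curve$shifts, auc = curve$auc),
                       file.path(out_dir, "sensitivity",
                                 paste0("shift_curve_", m, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(model = m, optimal_shift = curve$optimal_shift,
             auc_at_zero = curve$auc_at_zero,
             max_abs_delta = curve$max_abs_delta),
        file.path(out_dir, "sensitivity", paste0("summary_", m, ".json")),
        digits = NA, auto_unbox = TRUE, pretty = TRUE)
      say("sensitivity: %s model optimal shift %+.2f h, max |dAUC| %.4f",
          m, curve$optimal_shift, curve$max_abs_delta)
    }
  })

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
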