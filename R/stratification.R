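#' Tertile edges of an embryo-level variable
#'
#' Edges are the order statistics at ranks ceiling(n/3) and ceiling(2n/3),
#' i.e. empirical 1/3 and 2/3 quantiles; tiers are the intervals
#' \[min, e1\], (e1, e2\], (e2, max\]. Ties are never split: equal values
#' always map to the same tier, so group sizes are as equal as the ties
#' permit (within 1 for all-distinct input).
#'
#' @param values numeric vector, length >= 3.
#' @return numeric vector `c(e1, e2)`.
#' @examples
#' tertile_edges(1:9)  # c(3, 6)
#' @export
tertile_edges <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values for tertiles", call. = FALSE)
  s <- sort(values)
  c(s[ceiling(n / 3)], s[ceiling(2 * n / 3)])
}

#' Assign values to tertile tiers
#'
#' @param values numeric vector.
#' @param edges edges from [tertile_edges()].
#' @return factor with levels `lower`, `middle`, `upper`.
#' @export
assign_tertile <- function(values, edges = tertile_edges(values)) {
  factor(ifelse(values <= edges[1], "lower",
                ifelse(values <= edges[2], "middle", "upper")),
         levels = c("lower", "middle", "upper"))
}

#' Counterfactual scores with tier-averaged age
#'
#' Replaces every embryo's maternal age by the (embryo-level) mean age of
#' its age tier and re-evaluates the age-inclusive model, leaving all other
#' covariates untouched. Comparing the stratified AUC of these scores with
#' the age-free model isolates how much of the age model's discrimination
#' comes from between-tier age separation rather than embryo ranking.
#'
#' @param model_age a `kidlb_fit` including a maternal-age smooth.
#' @param newdata embryo-level model frame with `maternal_age`.
#' @param age_tiers factor from [assign_tertile()] on `newdata$maternal_age`.
#' @return numeric vector of counterfactual probabilities.
#' @export
counterfactual_average_age_scores <- function(model_age, newdata,
                                              age_tiers) {
  if (!spec_has_term(model_age$spec, "s(maternal_age)"))
    stop("model has no maternal age term; use the base model directly",
         call. = FALSE)
  stopifnot(length(age_tiers) == nrow(newdata))
  tier_means <- tapply(newdata$maternal_age, age_tiers, mean)
  newdata$maternal_age <- as.numeric(tier_means[as.character(age_tiers)])
  predict_probability(model_age, newdata)
}

#' Age-by-score tertile stratification report
#'
#' Crosses maternal-age tertiles with Age Model score tertiles into nine
#' strata and tabulates, per stratum: embryo counts, observed live-birth
#' rate, mean predicted probability, and the within-stratum AUC of (a) the
#' Age Model, (b) the Base Model, and (c) the Age Model with tier-averaged
#' age. All scores are in-sample population-level predictions from models
#' fitted to the full cohort, matching how the study tables are built; a
#' stratum with a single outcome class gets a missing AUC.
#'
#' @param model_age,model_base fitted `kidlb_fit` objects (with and without
#'   the age smooth), both trained on this cohort.
#' @param cycles,embryos cohort tables.
#' @return object of class `kidlb_strat` with 3x3 matrices `counts`,
#'   `observed_lb`, `predicted_lb`, `auc_age_model`, `auc_base_model`,
#'   `auc_age_averaged`, plus `age_edges`, `score_edges`, `tier_mean_ages`.
#' @export
build_stratification <- function(model_age, model_base, cycles, embryos) {
  mf <- prepare_model_frame(cycles, embryos, model_age$spec$cc2_cutoffs)
  scores <- predict_probability(model_age, mf)
  scores_base <- predict_probability(model_base, mf)
  age_edges <- tertile_edges(mf$maternal_age)
  score_edges <- tertile_edges(scores)
  age_t <- assign_tertile(mf$maternal_age, age_edges)
  score_t <- assign_tertile(scores, score_edges)
  scores_cf <- counterfactual_average_age_scores(model_age, mf, age_t)

  dims <- list(age = c("lowest_age", "medium_age", "highest_age"),
               score = c("lowest_score", "medium_score", "highest_score"))
  mk <- function() matrix(NA_real_, 3, 3, dimnames = dims)
  counts <- matrix(0L, 3, 3, dimnames = dims)
  observed <- mk(); predicted <- mk()
  auc_age <- mk(); auc_base <- mk(); auc_cf <- mk()
  cell_auc <- function(s, y) {
    if (length(unique(y)) < 2L) NA_real_ else auc_mann_whitney(s, y)
  }
  for (i in 1:3) for (j in 1:3) {
    sel <- as.integer(age_t) == i & as.integer(score_t) == j
    counts[i, j] <- sum(sel)
    if (!any(sel)) next
    y <- mf$live_birth[sel]
    observed[i, j] <- mean(y)
    predicted[i, j] <- mean(scores[sel])
    auc_age[i, j] <- cell_auc(scores[sel], y)
    auc_base[i, j] <- cell_auc(scores_base[sel], y)
    auc_cf[i, j] <- cell_auc(scores_cf[sel], y)
  }
  n_missing_auc <- sum(is.na(auc_age) | is.na(auc_base) | is.na(auc_cf))
  if (n_missing_auc)
    message(sprintf("%d stratum/strata with undefined AUC (one class)",
                    n_missing_auc))
  structure(list(age_edges = age_edges, score_edges = score_edges,
                 counts = counts, observed_lb = observed,
                 predicted_lb = predicted, auc_age_model = auc_age,
                 auc_base_model = auc_base, auc_age_averaged = auc_cf,
                 tier_mean_ages = as.numeric(
                   tapply(mf$maternal_age, age_t, mean)),
                 n = nrow(mf)),
            class = "kidlb_strat")
}

#' @export
print.kidlb_strat <- function(x, ...) {
  cat(sprintf("Age x score stratification of %d embryos\n", x$n))
  cat("counts:\n"); print(x$counts)
  cat("observed LB:\n"); print(round(x$observed_lb, 3))
  cat("Age Model AUC:\n"); print(round(x$auc_age_model, 3))
  invisible(x)
}

#' Export the stratification report as CSV tables and JSON
#'
#' Writes the six 3x3 tables (counts, observed and predicted live-birth
#' rates, and the three stratified AUC variants) as CSV files named after
#' the analysis tables they correspond to, plus a JSON bundle.
#'
#' @param strat a `kidlb_strat`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stratification <- function(strat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(table4_observed = strat$observed_lb,
               table5_predicted = strat$predicted_lb,
               table6_counts = strat$counts,
               table7_auc_age_model = strat$auc_age_model,
               table8_auc_base_model = strat$auc_base_model,
               table9_auc_age_averaged = strat$auc_age_averaged)
  for (nm in names(tabs))
    utils::write.csv(as.data.frame(tabs[[nm]]),
                     file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(
    lapply(strat[c("age_edges", "score_edges", "counts", "observed_lb",
                   "predicted_lb", "auc_age_model", "auc_base_model",
                   "auc_age_averaged", "tier_mean_ages", "n")],
           function(v) if (is.matrix(v)) as.data.frame(v) else v),
    file.path(dir, "stratification.json"), digits = NA, pretty = TRUE)
  invisible(dir)
}
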