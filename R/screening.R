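#' Second cell cycle (cc2) category cutoffs
#'
#' Boundaries, in hours, separating short / medium / long second cell cycles
#' (cc2 = t3 - t2). The defaults follow the published time-lapse selection
#' window for the medium band; clinics calibrate these locally, so both are
#' configurable.
#'
#' @param short_max upper boundary of the short band (hours); values strictly
#'   below are `short`.
#' @param long_min lower boundary of the long band (hours); values strictly
#'   above are `long`. Both boundaries themselves fall in `medium`.
#' @return an object of class `cc2_cutoffs`.
#' @export
cc2_cutoffs <- function(short_max = 9.33, long_min = 11.45) {
  if (!(short_max > 0)) stop_named("short_max", "must be > 0")
  if (long_min < short_max) stop_named("long_min", "must be >= short_max")
  structure(list(short_max = short_max, long_min = long_min),
            class = "cc2_cutoffs")
}

#' Categorize cc2 durations into short / medium / long
#'
#' @param cc2 numeric vector of second cell cycle durations (hours), >= 0.
#' @param cutoffs a [cc2_cutoffs()] object.
#' @return factor with levels `short`, `medium`, `long` (boundaries inclusive
#'   to `medium`).
#' @examples
#' categorize_cc2(c(5, 10, 12), cc2_cutoffs())
#' @export
categorize_cc2 <- function(cc2, cutoffs = cc2_cutoffs()) {
  if (any(is.na(cc2)) || any(cc2 < 0))
    stop("cc2 values must be non-negative and non-missing", call. = FALSE)
  out <- ifelse(cc2 < cutoffs$short_max, "short",
                ifelse(cc2 > cutoffs$long_min, "long", "medium"))
  factor(out, levels = c("short", "medium", "long"))
}

#' Binary t4 threshold indicator
#'
#' Positive (1) when t4 is observed and strictly below the threshold;
#' everything else, including missing t4, is 0. Missing four-cell times are
#' deliberately coded as negative results rather than dropped, so the
#' indicator is total on the cohort.
#'
#' @param t4 numeric vector of four-cell times (hours post insemination),
#'   `NA` allowed.
#' @param threshold threshold in hours (> 0).
#' @return integer vector of 0/1.
#' @examples
#' binarize_t4(c(39, 40.5, NA), threshold = 40.5)
#' @export
binarize_t4 <- function(t4, threshold) {
  if (!(is.numeric(threshold) && length(threshold) == 1L && threshold > 0))
    stop_named("threshold", "must be a single positive number")
  as.integer(!is.na(t4) & t4 < threshold)
}

#' Grid search for the best t4 threshold
#'
#' For each candidate threshold the t4 indicator is formed with
#' [binarize_t4()] and its AUC against live birth is computed; the threshold
#' with maximal AUC is returned (ties resolved to the smallest threshold).
#'
#' @param embryos embryo table with columns `t4` and `live_birth`.
#' @param grid numeric vector of candidate thresholds (hours); default
#'   30--50 h in 0.5 h steps, covering the support of Day 2 four-cell times.
#' @return list with `threshold`, `auc`, and the full `grid_auc` data frame.
#' @export
optimal_t4_threshold <- function(embryos, grid = seq(30, 50, by = 0.5)) {
  if (!length(grid)) stop_named("grid", "must be non-empty")
  y <- embryos$live_birth
  if (length(unique(y)) < 2L)
    stop("AUC undefined: only one outcome class present", call. = FALSE)
  aucs <- vapply(grid, function(g)
    auc_mann_whitney(binarize_t4(embryos$t4, g), y), numeric(1))
  best <- which(aucs == max(aucs))[1L]  # grid assumed sorted; smallest wins
  list(threshold = grid[best], auc = aucs[best],
       grid_auc = data.frame(threshold = grid, auc = aucs))
}

#' Single-variable predictive screen
#'
#' Fits, for each candidate variable, a one-covariate penalized additive
#' logistic model (intercept, the variable's term, and a cycle-level random
#' intercept) and reports the in-sample AUC of its population-level scores
#' together with the term's approximate Wald p-value. Continuous
#' morphokinetic timings and maternal age enter as penalized smooths,
#' fragmentation and binary markers as linear terms, and the cc2 category as
#' a factor. In-sample AUCs are optimistic by construction; they rank
#' variables, they do not validate them.
#'
#' @param cycles,embryos cohort tables as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param variables character vector of variables to screen. `"t4_threshold"`
#'   triggers the binary indicator at the grid-optimal threshold.
#' @param cutoffs [cc2_cutoffs()] used for the cc2 category.
#' @param t4_grid threshold grid passed to [optimal_t4_threshold()].
#' @param lambda_mode smoothing selection mode passed to the fitter.
#' @return data frame (class `kidlb_screen`) with columns `variable`, `auc`,
#'   `pvalue`, sorted by ascending AUC; the chosen t4 threshold is attached
#'   as attribute `t4_threshold` when screened.
#' @export
single_variable_screen <- function(cycles, embryos,
                                   variables = c("fragmentation_pct",
                                                 "cc2_category",
                                                 "multinucleated",
                                                 "t4_threshold", "t2",
                                                 "maternal_age"),
                                   cutoffs = cc2_cutoffs(),
                                   t4_grid = seq(30, 50, by = 0.5),
                                   lambda_mode = "reml") {
  mf <- prepare_model_frame(cycles, embryos, cutoffs)
  t4_thr <- NULL
  rows <- lapply(variables, function(v) {
    mfv <- mf
    term <- switch(v,
      t2 = smooth_term("t2"),
      maternal_age = smooth_term("maternal_age"),
      cc2_category = categorical_term("cc2_category", ref = "medium"),
      multinucleated = linear_term("multinucleated"),
      fragmentation_pct = linear_term("fragmentation_pct"),
      t4_threshold = {
        opt <- optimal_t4_threshold(embryos, t4_grid)
        t4_thr <<- opt$threshold
        mfv$t4_flag <- binarize_t4(mfv$t4, opt$threshold)
        linear_term("t4_flag")
      },
      stop(sprintf("unknown screening variable '%s'", v), call. = FALSE))
    spec <- model_spec(terms = list(term), random_intercept = "cycle_id",
                       cc2_cutoffs = cutoffs)
    fit <- fit_penalized_additive_logistic(spec, cycles, embryos,
                                           lambda_mode = lambda_mode,
                                           model_frame = mfv)
    sc <- predict_probability(fit, mfv)
    data.frame(variable = v,
               auc = auc_mann_whitney(sc, mfv$live_birth),
               pvalue = unname(fit$term_pvalues[term$label]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$auc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kidlb_screen", "data.frame")
  attr(out, "t4_threshold") <- t4_thr
  out
}
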