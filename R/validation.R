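#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half: computed from midranks in
#' O(n log n), exactly equal to the exhaustive pairwise count.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical) of equal length.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(0.9, 0.1), c(1, 0))
#' @export
auc_mann_whitney <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (any(is.na(scores)) || any(is.na(labels)))
    stop("missing values in scores or labels", call. = FALSE)
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be binary", call. = FALSE)
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: only one outcome class present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validation configuration
#'
#' @param k_folds number of folds (>= 2, default 5).
#' @param n_resamples bootstrap resamples per fold (or full-CV repeats),
#'   default 200, so the default run yields 5 x 200 = 1,000 AUC values.
#' @param mode `"within_fold_bootstrap"` (default): one model per fold,
#'   bootstrap over held-out cycles; `"repeated_cv"`: the whole k-fold split
#'   repeated `n_resamples` times with fresh seeds.
#' @param seed integer seed; all resampling randomness derives from it.
#' @param lambda_mode smoothing selection used for each fold's fit.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k_folds = 5L, n_resamples = 200L,
                      mode = c("within_fold_bootstrap", "repeated_cv"),
                      seed = 1L, lambda_mode = "reml") {
  if (!(is.numeric(k_folds) && k_folds >= 2))
    stop_named("k_folds", "must be an integer >= 2")
  if (!(is.numeric(n_resamples) && n_resamples >= 1))
    stop_named("n_resamples", "must be an integer >= 1")
  structure(list(k_folds = as.integer(k_folds),
                 n_resamples = as.integer(n_resamples),
                 mode = match.arg(mode), seed = as.integer(seed),
                 lambda_mode = lambda_mode),
            class = "cv_config")
}

#' Cycle-clustered k-fold split
#'
#' Partitions treatment cycles (never individual embryos) into k folds of
#' near-equal cycle counts, so the two embryos of a double transfer always
#' land in the same fold.
#'
#' @param cycles cycle table.
#' @param k number of folds (<= number of cycles).
#' @param seed integer seed.
#' @return list of k character vectors of cycle ids.
#' @export
clustered_kfold_split <- function(cycles, k, seed) {
  ids <- cycles$cycle_id
  if (k > length(ids))
    stop("k exceeds the number of cycles", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    perm <- sample(ids)
  })
  fold <- rep(seq_len(k), length.out = length(ids))  # sizes differ by <= 1
  split(perm, fold)
}

#' Empirical percentile confidence interval
#'
#' @param values nonempty numeric vector.
#' @param level coverage in (0, 1), default 0.95.
#' @return named vector `c(lo, hi)` of linearly interpolated empirical
#'   quantiles.
#' @examples
#' percentile_ci(1:100)  # (3.475, 97.525)
#' @export
percentile_ci <- function(values, level = 0.95) {
  if (!length(values)) stop("empty value vector", call. = FALSE)
  if (!(is.numeric(level) && level > 0 && level < 1))
    stop_named("level", "must be strictly inside (0, 1)")
  q <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 7, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Clustered bootstrap cross-validated AUC
#'
#' In the default `within_fold_bootstrap` mode a model is fitted once per
#' fold on the training cycles, held-out embryos are scored at the
#' population level, and `n_resamples` bootstrap resamples of the held-out
#' *cycles* (with replacement, so DET pairs move together) each contribute
#' one AUC - k x B values in total. In `repeated_cv` mode the full k-fold
#' split is instead repeated `n_resamples` times with fresh derived seeds,
#' one AUC per held-out fold. A resample containing a single outcome class
#' yields a missing AUC, excluded from the mean and CI but counted.
#'
#' @param spec a [model_spec()].
#' @param cycles,embryos cohort tables.
#' @param cv a [cv_config()].
#' @param lambdas,sigma_u optional fixed smoothing parameters used when
#'   `cv$lambda_mode == "fixed"`.
#' @return object of class `kidlb_cv`: `auc_values` (length k x B, `NA` for
#'   degenerate resamples), `mean_auc`, `ci95`, `mode`, `n_degenerate`, and
#'   `per_fold` diagnostics.
#' @export
bootstrap_cv_auc <- function(spec, cycles, embryos, cv = cv_config(),
                             lambdas = NULL, sigma_u = NULL) {
  stopifnot(inherits(cv, "cv_config"))
  if (cv$k_folds > nrow(cycles))
    stop("k_folds exceeds the number of cycles", call. = FALSE)
  mf_all <- prepare_model_frame(cycles, embryos, spec$cc2_cutoffs)
  fit_fold <- function(train_ids) {
    fit_penalized_additive_logistic(
      spec, cycles[cycles$cycle_id %in% train_ids, , drop = FALSE],
      embryos[embryos$cycle_id %in% train_ids, , drop = FALSE],
      lambda_mode = if (cv$lambda_mode == "fixed") "fixed" else "reml",
      lambdas = lambdas, sigma_u = sigma_u)
  }
  if (cv$mode == "within_fold_bootstrap") {
    folds <- clustered_kfold_split(cycles, cv$k_folds,
                                   derive_seed(cv$seed, 1L))
    per_fold <- vector("list", cv$k_folds)
    auc_values <- numeric(0)
    for (i in seq_len(cv$k_folds)) {
      test_ids <- folds[[i]]
      fit <- fit_fold(setdiff(cycles$cycle_id, test_ids))
      held <- mf_all[mf_all$cycle_id %in% test_ids, , drop = FALSE]
      sc <- predict_probability(fit, held)
      by_cycle <- split(seq_len(nrow(held)), held$cycle_id)
      draws <- withr::with_seed(derive_seed(cv$seed, 100L + i), {
        matrix(sample(length(by_cycle), length(by_cycle) * cv$n_resamples,
                      replace = TRUE), ncol = cv$n_resamples)
      })
      aucs <- apply(draws, 2L, function(ix) {
        rows <- unlist(by_cycle[ix], use.names = FALSE)
        if (length(unique(held$live_birth[rows])) < 2L) return(NA_real_)
        auc_mann_whitney(sc[rows], held$live_birth[rows])
      })
      auc_values <- c(auc_values, aucs)
      per_fold[[i]] <- data.frame(fold = i, n_test_cycles = length(test_ids),
                                  converged = fit$converged,
                                  auc_heldout = if (length(unique(held$live_birth)) > 1L)
                                    auc_mann_whitney(sc, held$live_birth)
                                  else NA_real_)
    }
    per_fold <- do.call(rbind, per_fold)
  } else {
    auc_values <- numeric(0)
    per_fold <- NULL
    for (b in seq_len(cv$n_resamples)) {
      folds <- clustered_kfold_split(cycles, cv$k_folds,
                                     derive_seed(cv$seed, 1000L + b))
      for (i in seq_len(cv$k_folds)) {
        test_ids <- folds[[i]]
        fit <- fit_fold(setdiff(cycles$cycle_id, test_ids))
        held <- mf_all[mf_all$cycle_id %in% test_ids, , drop = FALSE]
        auc_values <- c(auc_values,
          if (length(unique(held$live_birth)) < 2L) NA_real_
          else auc_mann_whitney(predict_probability(fit, held),
                                held$live_birth))
      }
    }
  }
  ok <- !is.na(auc_values)
  if (any(!ok))
    message(sprintf("%d degenerate resample(s) excluded from the CV summary",
                    sum(!ok)))
  structure(list(auc_values = auc_values,
                 mean_auc = mean(auc_values[ok]),
                 ci95 = percentile_ci(auc_values[ok], 0.95),
                 mode = cv$mode, n_degenerate = sum(!ok),
                 k_folds = cv$k_folds, n_resamples = cv$n_resamples,
                 per_fold = per_fold),
            class = "kidlb_cv")
}

#' @export
print.kidlb_cv <- function(x, ...) {
  cat(sprintf(
    "Clustered %d-fold CV (%s), %d AUC values (%d degenerate)\n",
    x$k_folds, x$mode, length(x$auc_values), x$n_degenerate))
  cat(sprintf("  mean AUC %.3f, 95%% CI [%.3f, %.3f]\n", x$mean_auc,
              x$ci95[["lo"]], x$ci95[["hi"]]))
  invisible(x)
}
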