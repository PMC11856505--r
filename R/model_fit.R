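# Core fitting machinery: penalized IRLS for an additive logistic model with
# a cycle-level random intercept treated as ridge-penalized coefficients, and
# Laplace-approximate REML selection of smoothing parameters and the random
# intercept SD. The random-intercept block is solved by a Schur complement
# (its cross-products are diagonal), so each IRLS step costs O(n p^2) in the
# small fixed-effect dimension regardless of the number of cycles.

build_design <- function(spec, mf, blocks = NULL) {
  training <- is.null(blocks)
  cols <- list(`(Intercept)` = matrix(1, nrow(mf), 1L))
  term_cols <- list()
  pen <- list()
  new_blocks <- list()
  xlevels <- list()
  idx <- 1L
  for (tm in spec$terms) {
    x <- mf[[tm$var]]
    if (is.null(x))
      stop(sprintf("variable '%s' not found in model frame", tm$var),
           call. = FALSE)
    if (tm$type == "smooth") {
      if (training) {
        blk <- build_spline_basis(x, tm$n_basis, tm$degree, tm$penalty_order)
        X <- blk$X
      } else {
        blk <- blocks[[tm$label]]
        X <- eval_spline_basis(blk, x)
      }
      new_blocks[[tm$label]] <- blk
      colnames(X) <- paste0(tm$label, ".", seq_len(ncol(X)))
      pen[[tm$label]] <- list(S = blk$S, rank = blk$rank,
                              cols = idx + seq_len(ncol(X)))
    } else if (tm$type == "categorical") {
      if (training) {
        lev <- levels(factor(x))
        lev <- c(tm$ref, setdiff(lev, tm$ref))
      } else {
        lev <- blocks$xlevels[[tm$var]]
        bad <- setdiff(unique(as.character(x)), lev)
        if (length(bad))
          stop(sprintf("unseen level(s) for '%s': %s", tm$var,
                       paste(bad, collapse = ", ")), call. = FALSE)
      }
      xlevels[[tm$var]] <- lev
      f <- factor(as.character(x), levels = lev)
      X <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(X) <- paste0(tm$var, lev[-1])
    } else {
      if (!is.numeric(x))
        stop(sprintf("linear term '%s' must be numeric", tm$var),
             call. = FALSE)
      X <- matrix(x, ncol = 1L, dimnames = list(NULL, tm$var))
    }
    term_cols[[tm$label]] <- idx + seq_len(ncol(X))
    idx <- idx + ncol(X)
    cols[[tm$label]] <- X
  }
  F <- do.call(cbind, cols)
  new_blocks$xlevels <- if (training) xlevels else blocks$xlevels
  list(F = F, term_cols = term_cols, pen = pen,
       blocks = if (training) new_blocks else blocks)
}

penalized_deviance <- function(F, y, beta, Slam, u, ci, inv_su2) {
  eta <- drop(F %*% beta) + if (length(u)) u[ci] else 0
  eta <- pmin(pmax(eta, -15), 15)
  mu <- stats::plogis(eta)
  dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  dev + drop(crossprod(beta, Slam %*% beta)) +
    (if (length(u)) inv_su2 * sum(u^2) else 0)
}

# penalized IRLS; ci = NULL for no random intercept
pirls <- function(F, y, Slam, ci = NULL, inv_su2 = NULL, beta0 = NULL,
                  u0 = NULL, tol = 1e-8, maxit = 200L) {
  n <- nrow(F); p <- ncol(F)
  nc <- if (is.null(ci)) 0L else max(ci)
  beta <- if (is.null(beta0) || length(beta0) != p) numeric(p) else beta0
  u <- if (nc == 0L) numeric(0L)
       else if (is.null(u0) || length(u0) != nc) numeric(nc) else u0
  obj <- penalized_deviance(F, y, beta, Slam, u, ci, inv_su2)
  trace <- obj
  conv <- FALSE; it <- 0L; stalled <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(F %*% beta) + if (nc) u[ci] else 0
    eta <- pmin(pmax(eta, -15), 15)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    wF <- F * w
    A0 <- crossprod(F, wF)
    b1 <- drop(crossprod(F, w * z))
    ridge <- 1e-8
    repeat {  # escalate the stabilizing ridge if the system degenerates
      A <- A0 + Slam
      diag(A) <- diag(A) + ridge
      sol <- tryCatch({
        if (nc) {
          Du <- as.numeric(rowsum(w, ci)) + inv_su2
          Bm <- t(rowsum(wF, ci))
          b2 <- as.numeric(rowsum(w * z, ci))
          Sc <- A - Bm %*% (t(Bm) / Du)
          beta_new <- drop(solve(Sc, b1 - Bm %*% (b2 / Du)))
          list(beta = beta_new,
               u = (b2 - drop(crossprod(Bm, beta_new))) / Du)
        } else {
          list(beta = drop(solve(A, b1)), u = u)
        }
      }, error = function(e) NULL)
      if (!is.null(sol) || ridge > 1e-2) break
      ridge <- ridge * 1e3
    }
    if (is.null(sol))
      stop("IRLS system singular despite ridge stabilization", call. = FALSE)
    beta_new <- sol$beta; u_new <- sol$u
    step <- 1
    repeat {  # step-halving: the penalized deviance never increases
      bt <- beta + step * (beta_new - beta)
      ut <- if (nc) u + step * (u_new - u) else u
      ot <- penalized_deviance(F, y, bt, Slam, ut, ci, inv_su2)
      if (ot <= obj + 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    delta <- max(abs(c(bt - beta, if (nc) ut - u else numeric(0))))
    drop_obj <- obj - ot
    beta <- bt; u <- ut; obj <- ot
    trace <- c(trace, obj)
    if (delta < tol) { conv <- TRUE; break }
    # objective stationary: coefficients only creep along a flat penalized
    # direction; the fit is numerically converged
    stalled <- if (drop_obj < 1e-10 * (abs(obj) + 1)) stalled + 1L else 0L
    if (stalled >= 2L) { conv <- TRUE; break }
  }
  eta <- drop(F %*% beta) + if (nc) u[ci] else 0
  mu <- stats::plogis(pmin(pmax(eta, -15), 15))
  dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(beta = beta, u = u, dev = dev, pen_obj = obj, converged = conv,
       iters = it, w = pmax(mu * (1 - mu), 1e-10), obj_trace = trace)
}

assemble_penalty <- function(pen, lambdas, p) {
  Slam <- matrix(0, p, p)
  for (lab in names(pen)) {
    ix <- pen[[lab]]$cols
    Slam[ix, ix] <- Slam[ix, ix] + lambdas[[lab]] * pen[[lab]]$S
  }
  Slam
}

# negative Laplace REML criterion, up to additive constants free of
# (lambda, sigma_u); warm is an environment carrying beta/u starts
neg_reml_criterion <- function(rho, F, y, pen, ci, warm) {
  J <- length(pen)
  lam <- exp(pmin(pmax(rho[seq_len(J)], -18), 18))
  names(lam) <- names(pen)
  su <- if (is.null(ci)) 1 else min(max(exp(rho[J + 1L]), 1e-4), 20)
  p <- ncol(F)
  Slam <- assemble_penalty(pen, as.list(lam), p)
  fit <- tryCatch(
    pirls(F, y, Slam, ci, 1 / su^2, beta0 = warm$beta, u0 = warm$u),
    error = function(e) NULL)
  if (is.null(fit)) return(1e10)
  warm$beta <- fit$beta; warm$u <- fit$u
  w <- fit$w
  wF <- F * w
  A <- crossprod(F, wF) + Slam
  diag(A) <- diag(A) + 1e-8
  if (!is.null(ci)) {
    nc <- max(ci)
    Du <- as.numeric(rowsum(w, ci)) + 1 / su^2
    Bm <- t(rowsum(wF, ci))
    Sc <- A - Bm %*% (t(Bm) / Du)
    ldH <- sum(log(Du)) +
      as.numeric(determinant(Sc, logarithm = TRUE)$modulus)
    ldS <- sum(vapply(pen, function(pj) pj$rank, 0) * log(lam)) +
      nc * log(1 / su^2)
  } else {
    ldH <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
    ldS <- sum(vapply(pen, function(pj) pj$rank, 0) * log(lam))
  }
  pen_quad <- fit$pen_obj - fit$dev
  # mild quadratic penalty beyond the hyperparameter clamps keeps the
  # simplex off the flat clamped plateau and converging to the boundary
  bpen <- sum(pmax(abs(rho) - 18, 0)^2)
  0.5 * fit$dev + 0.5 * pen_quad + 0.5 * ldH - 0.5 * ldS + bpen
}

#' Select smoothing parameters and random-intercept SD by Laplace REML
#'
#' Maximizes the Laplace-approximate restricted likelihood of the penalized
#' additive logistic model over the log smoothing parameters and log random
#' intercept SD with Nelder--Mead, starting from lambda = 1 and
#' sigma_u = 0.5; the inner loop is the penalized IRLS fit, warm-started
#' across criterion evaluations. If the optimizer fails, a log-spaced grid
#' search (lambda in 10^-3..10^3) is used instead and a message is emitted.
#'
#' @inheritParams fit_penalized_additive_logistic
#' @param control list: `reltol`, `maxit` for [stats::optim()].
#' @return list with `lambdas` (named per smooth), `sigma_u`, `criterion`
#'   (minimized negative REML), and `optim` diagnostics.
#' @export
select_smoothing_reml <- function(spec, cycles, embryos, control = list(),
                                  model_frame = NULL) {
  mf <- model_frame %||% prepare_model_frame(cycles, embryos, spec$cc2_cutoffs)
  des <- build_design(spec, mf)
  y <- mf$live_birth
  ci <- if (is.null(spec$random_intercept)) NULL
        else as.integer(factor(mf[[spec$random_intercept]],
                               levels = unique(mf[[spec$random_intercept]])))
  J <- length(des$pen)
  if (J == 0L && is.null(ci))
    return(list(lambdas = list(), sigma_u = NA_real_, criterion = NA_real_,
                optim = list(convergence = 0L, evals = 0L)))
  warm <- new.env(parent = emptyenv()); warm$beta <- NULL; warm$u <- NULL
  start <- c(rep(0, J), if (!is.null(ci)) log(0.5))
  ctl <- list(reltol = control$reltol %||% 1e-5,
              maxit = control$maxit %||% 400L)
  opt <- tryCatch(
    if (length(start) == 1L)
      stats::optim(start, neg_reml_criterion, F = des$F, y = y,
                   pen = des$pen, ci = ci, warm = warm, method = "Brent",
                   lower = -14, upper = 14)
    else
      stats::optim(start, neg_reml_criterion, F = des$F, y = y,
                   pen = des$pen, ci = ci, warm = warm,
                   method = "Nelder-Mead", control = ctl),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    message("REML optimizer failed; falling back to log-grid search")
    grid_l <- log(10^seq(-3, 3, by = 1))
    grid_s <- log(c(0.05, 0.1, 0.25, 0.5, 1, 2))
    combos <- as.matrix(do.call(expand.grid,
                                c(rep(list(grid_l), J),
                                  if (!is.null(ci)) list(grid_s))))
    vals <- apply(combos, 1L, neg_reml_criterion, F = des$F, y = y,
                  pen = des$pen, ci = ci, warm = warm)
    best <- which.min(vals)
    opt <- list(par = combos[best, ], value = vals[best],
                convergence = NA_integer_, counts = c(nrow(combos), NA))
  }
  lam <- exp(pmin(pmax(opt$par[seq_len(J)], -18), 18))
  names(lam) <- names(des$pen)
  list(lambdas = as.list(lam),
       sigma_u = if (is.null(ci)) NA_real_
                 else min(max(exp(opt$par[J + 1L]), 1e-4), 20),
       criterion = opt$value,
       optim = list(convergence = opt$convergence, evals = opt$counts[1]))
}

#' Fit the penalized additive logistic model
#'
#' Maximizes the binomial log-likelihood minus half the sum of smooth
#' penalties \eqn{\lambda_j \beta^T S_j \beta} minus half
#' \eqn{u^T u / \sigma_u^2}, with the cycle random intercepts `u` treated as
#' ridge-penalized coefficients (a Laplace / PQL-type approximation -- the
#' random effect integral is not computed exactly). Convergence is declared
#' when the largest coefficient change drops below `1e-8` (at most 200
#' iterations); non-convergence is flagged, not raised. Per-term effective
#' degrees of freedom are the corresponding diagonal entries of the
#' influence matrix; smooth-term edf additionally counts the level absorbed
#' into the intercept by the sum-to-zero constraint, so a smooth shrunk to a
#' straight line reports edf 2. The AIC is `deviance + 2 * edf_total` where
#' `edf_total` is the full influence-matrix trace (including the random
#' intercepts). Term p-values are approximate Wald tests on the penalized
#' coefficients.
#'
#' @param spec a [model_spec()].
#' @param cycles,embryos cohort tables.
#' @param lambda_mode `"reml"` (default) selects smoothing parameters and
#'   sigma_u by [select_smoothing_reml()]; `"fixed"` uses the supplied
#'   `lambdas` / `sigma_u`.
#' @param lambdas named list of smoothing parameters (one per smooth term);
#'   required for `lambda_mode = "fixed"` when the spec has smooths.
#' @param sigma_u random intercept SD for `lambda_mode = "fixed"`.
#' @param control optimizer control passed to [select_smoothing_reml()].
#' @param model_frame optional pre-built model frame (advanced use; must
#'   match `prepare_model_frame(cycles, embryos)` row order).
#' @return an object of class `kidlb_fit`.
#' @export
fit_penalized_additive_logistic <- function(spec, cycles, embryos,
                                            lambda_mode = c("reml", "fixed"),
                                            lambdas = NULL, sigma_u = NULL,
                                            control = list(),
                                            model_frame = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  mf <- model_frame %||% prepare_model_frame(cycles, embryos, spec$cc2_cutoffs)
  y <- mf$live_birth
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  des <- build_design(spec, mf)
  has_re <- !is.null(spec$random_intercept)
  cyc_levels <- if (has_re) unique(mf[[spec$random_intercept]]) else NULL
  ci <- if (has_re) as.integer(factor(mf[[spec$random_intercept]],
                                      levels = cyc_levels)) else NULL
  J <- length(des$pen)
  if (lambda_mode == "reml" && (J > 0L || has_re)) {
    sel <- select_smoothing_reml(spec, cycles, embryos, control, mf)
    lambdas <- sel$lambdas
    sigma_u <- sel$sigma_u
    reml_info <- sel[c("criterion", "optim")]
  } else {
    if (J > 0L && is.null(lambdas))
      stop("lambda_mode = 'fixed' requires `lambdas`", call. = FALSE)
    if (has_re && is.null(sigma_u))
      stop("lambda_mode = 'fixed' requires `sigma_u`", call. = FALSE)
    reml_info <- NULL
  }
  p <- ncol(des$F)
  Slam <- if (J) assemble_penalty(des$pen, lambdas, p) else matrix(0, p, p)
  inv_su2 <- if (has_re) 1 / max(sigma_u, 1e-4)^2 else NULL
  fit <- pirls(des$F, y, Slam, ci, inv_su2)

  # influence diagnostics via the same Schur-complement blocks
  w <- fit$w
  wF <- des$F * w
  A <- crossprod(des$F, wF) + Slam
  diag(A) <- diag(A) + 1e-8
  if (has_re) {
    nc <- max(ci)
    Du <- as.numeric(rowsum(w, ci)) + inv_su2
    Bm <- t(rowsum(wF, ci))
    Sc <- A - Bm %*% (t(Bm) / Du)
    M <- solve(Sc)                               # H^-1, fixed-effect block
    g <- colSums(Bm * (M %*% Bm)) / Du^2
    diag_Hinv_u <- 1 / Du + g
    edf_u <- nc - inv_su2 * sum(diag_Hinv_u)
  } else {
    M <- solve(A)
    edf_u <- 0
  }
  diag_HinvS_f <- rowSums(M * Slam)              # Slam symmetric
  edf_i <- 1 - diag_HinvS_f                      # per fixed coefficient
  edf_total <- sum(edf_i) + edf_u
  edf_terms <- vapply(names(des$term_cols), function(lab) {
    e <- sum(edf_i[des$term_cols[[lab]]])
    if (lab %in% names(des$pen)) e + 1 else e    # count the absorbed level
  }, numeric(1))
  pvals <- vapply(names(des$term_cols), function(lab) {
    ix <- des$term_cols[[lab]]
    b <- fit$beta[ix]
    V <- M[ix, ix, drop = FALSE]
    stat <- tryCatch(drop(crossprod(b, solve(V, b))), error = function(e) NA)
    df <- if (lab %in% names(des$pen))
      max(1, sum(edf_i[ix])) else length(ix)
    stats::pchisq(stat, df, lower.tail = FALSE)
  }, numeric(1))

  separation <- fit$dev < 1e-6 && max(abs(fit$beta)) > 15
  if (separation)
    warning("complete separation suspected: deviance ~ 0 with diverging ",
            "coefficients", call. = FALSE)
  coefs <- fit$beta
  names(coefs) <- colnames(des$F)
  u <- fit$u
  if (has_re) names(u) <- as.character(cyc_levels)
  structure(list(
    spec = spec, coefficients = coefs, u = u,
    lambdas = lambdas, sigma_u = if (has_re) sigma_u else NA_real_,
    term_cols = des$term_cols, blocks = des$blocks, pen_ranks =
      vapply(des$pen, function(pj) pj$rank, 0),
    edf = list(terms = edf_terms, random_intercept = edf_u,
               total = edf_total),
    deviance = fit$dev, aic = fit$dev + 2 * edf_total,
    term_pvalues = pvals, converged = fit$converged,
    iterations = fit$iters, obj_trace = fit$obj_trace,
    separation = separation, n = nrow(mf),
    reml = reml_info, train_fingerprint = data_fingerprint(mf)),
    class = "kidlb_fit")
}

#' @export
print.kidlb_fit <- function(x, ...) {
  cat("Penalized additive logistic model\n")
  cat(sprintf("  n = %d embryos, deviance = %.2f, edf = %.2f, AIC = %.2f\n",
              x$n, x$deviance, x$edf$total, x$aic))
  for (lab in names(x$edf$terms))
    cat(sprintf("  %-18s edf %5.2f  p = %.3g\n", lab, x$edf$terms[[lab]],
                x$term_pvalues[[lab]]))
  if (!is.na(x$sigma_u))
    cat(sprintf("  sigma_u = %.3f (random intercept edf %.1f)\n",
                x$sigma_u, x$edf$random_intercept))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' Predict live-birth probabilities
#'
#' Population-level scores (`use_random_effect = "zero"`, the default) set
#' the cycle random intercept to zero: this is how new or held-out embryos
#' are scored, since their cycles have no fitted intercept. `"fitted"` adds
#' the training cycles' estimated intercepts and is only meaningful for
#' training-data diagnostics.
#'
#' @param model a `kidlb_fit`.
#' @param newdata embryo-level data frame carrying all model variables
#'   (typically from [prepare_model_frame()]).
#' @param use_random_effect `"zero"` or `"fitted"`.
#' @return numeric vector of probabilities in (0, 1), one per row.
#' @export
predict_probability <- function(model, newdata,
                                use_random_effect = c("zero", "fitted")) {
  use_random_effect <- match.arg(use_random_effect)
  if (!("cc2_category" %in% names(newdata)) &&
      spec_has_term(model$spec, "cc2_category") &&
      all(c("t2", "t3") %in% names(newdata))) {
    newdata$cc2 <- pmax(0, newdata$t3 - newdata$t2)
    newdata$cc2_category <- categorize_cc2(newdata$cc2,
                                           model$spec$cc2_cutoffs)
  }
  des <- build_design(model$spec, newdata, blocks = model$blocks)
  eta <- drop(des$F %*% model$coefficients)
  if (use_random_effect == "fitted") {
    grp <- as.character(newdata[[model$spec$random_intercept]])
    if (any(!grp %in% names(model$u)))
      stop("fitted random effects requested for cycles absent from training",
           call. = FALSE)
    eta <- eta + model$u[grp]
  }
  unname(stats::plogis(eta))
}

#' Greedy forward selection on AIC
#'
#' Starting from `base`, repeatedly adds the candidate term with the largest
#' AIC decrease; stops when no candidate lowers the AIC. The AIC is the
#' effective-degrees-of-freedom form used throughout the package.
#'
#' @param candidates list of term descriptors disjoint from the base terms.
#' @param base a [model_spec()].
#' @inheritParams fit_penalized_additive_logistic
#' @return the selected `kidlb_spec` with a per-step log in attribute
#'   `selection_log` (data frame: step, term, aic, accepted).
#' @export
aic_forward_selection <- function(candidates, base, cycles, embryos,
                                  lambda_mode = "reml", control = list()) {
  base_labels <- vapply(base$terms, `[[`, "", "label")
  cand_labels <- vapply(candidates, `[[`, "", "label")
  dup <- intersect(base_labels, cand_labels)
  if (length(dup))
    stop("candidate term(s) already in base: ",
         paste(dup, collapse = ", "), call. = FALSE)
  mf <- prepare_model_frame(cycles, embryos, base$cc2_cutoffs)
  fit0 <- fit_penalized_additive_logistic(base, cycles, embryos,
                                          lambda_mode, control = control,
                                          model_frame = mf)
  cur <- base; cur_aic <- fit0$aic
  log <- data.frame(step = 0L, term = "(base)", aic = cur_aic,
                    accepted = TRUE)
  step <- 0L
  while (length(candidates)) {
    step <- step + 1L
    aics <- vapply(candidates, function(tm) {
      sp <- model_spec(c(cur$terms, list(tm)), cur$random_intercept,
                       cur$cc2_cutoffs)
      fit_penalized_additive_logistic(sp, cycles, embryos, lambda_mode,
                                      control = control,
                                      model_frame = mf)$aic
    }, numeric(1))
    best <- which.min(aics)
    log <- rbind(log, data.frame(
      step = step, term = cand_labels[best], aic = aics[best],
      accepted = aics[best] < cur_aic))
    if (aics[best] >= cur_aic) break
    cur <- model_spec(c(cur$terms, list(candidates[[best]])),
                      cur$random_intercept, cur$cc2_cutoffs)
    cur_aic <- aics[best]
    candidates <- candidates[-best]
    cand_labels <- cand_labels[-best]
  }
  attr(cur, "selection_log") <- log
  cur
}
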