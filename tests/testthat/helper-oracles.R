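# Independent oracles used to cross-check package computations.
# These deliberately re-derive results from first principles and must not
# call the package code paths they verify.

# exhaustive pairwise AUC: every positive-negative pair, ties count 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# textbook Newton-Raphson for unpenalized logistic regression
newton_logistic <- function(X, y, tol = 1e-12, maxit = 100L) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# small default-scenario cohort for fitting tests
tiny_cohort <- function(n_cycles = 250, seed = 1, ...) {
  generate_cohort(generator_config(n_cycles = n_cycles, seed = seed, ...))
}

# effects with everything switched off (null scenario)
null_effects <- function(rate = 0.2) {
  true_effects(f_age = function(a) rep(0, length(a)),
               f_t2 = function(t) rep(0, length(t)),
               beta_mn = 0, beta_cc2_short = 0, beta_cc2_long = 0,
               intercept = qlogis(rate))
}
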