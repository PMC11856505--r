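#' Model term constructors
#'
#' Terms of a penalized additive logistic model specification: `smooth_term`
#' declares a P-spline smooth, `linear_term` an unpenalized linear (or
#' binary) effect, `categorical_term` a factor with treatment contrasts
#' against a reference level.
#'
#' @param var variable name resolvable in the model frame.
#' @param n_basis,degree,penalty_order P-spline settings, see
#'   [build_spline_basis()].
#' @param ref reference level of a categorical term.
#' @return a term descriptor list with a `label` used in coefficient and
#'   p-value names.
#' @export
smooth_term <- function(var, n_basis = 10L, degree = 3L, penalty_order = 2L) {
  structure(list(type = "smooth", var = var, n_basis = as.integer(n_basis),
                 degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order),
                 label = paste0("s(", var, ")")),
            class = "kidlb_term")
}

#' @rdname smooth_term
#' @export
linear_term <- function(var) {
  structure(list(type = "linear", var = var, label = var),
            class = "kidlb_term")
}

#' @rdname smooth_term
#' @export
categorical_term <- function(var, ref) {
  structure(list(type = "categorical", var = var, ref = ref, label = var),
            class = "kidlb_term")
}

#' Penalized additive logistic model specification
#'
#' @param terms list of term descriptors ([smooth_term()], [linear_term()],
#'   [categorical_term()]).
#' @param random_intercept grouping variable for the cycle-level random
#'   intercept (default `"cycle_id"`), or `NULL` for none. Grouping is by
#'   treatment cycle: double transfers share one pregnancy outcome, so the
#'   cycle is the independent unit.
#' @param cc2_cutoffs [cc2_cutoffs()] used when the cc2 category enters.
#' @return object of class `kidlb_spec`.
#' @seealso [base_model_spec()], [age_model_spec()]
#' @export
model_spec <- function(terms, random_intercept = "cycle_id",
                       cc2_cutoffs = kidlb::cc2_cutoffs()) {
  labels <- vapply(terms, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicated model terms: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  structure(list(terms = terms, random_intercept = random_intercept,
                 cc2_cutoffs = cc2_cutoffs),
            class = "kidlb_spec")
}

#' The two study model specifications
#'
#' `base_model_spec()` is the age-free embryo scoring model: a smooth of t2,
#' the cc2 category (reference `medium`), multinucleation, and a cycle random
#' intercept. `age_model_spec()` adds a smooth of maternal age.
#'
#' @inheritParams model_spec
#' @param n_basis basis dimension of each smooth.
#' @return a `kidlb_spec`.
#' @export
base_model_spec <- function(cc2_cutoffs = kidlb::cc2_cutoffs(),
                            n_basis = 10L) {
  model_spec(list(smooth_term("t2", n_basis = n_basis),
                  categorical_term("cc2_category", ref = "medium"),
                  linear_term("multinucleated")),
             random_intercept = "cycle_id", cc2_cutoffs = cc2_cutoffs)
}

#' @rdname base_model_spec
#' @export
age_model_spec <- function(cc2_cutoffs = kidlb::cc2_cutoffs(),
                           n_basis = 10L) {
  model_spec(list(smooth_term("t2", n_basis = n_basis),
                  smooth_term("maternal_age", n_basis = n_basis),
                  categorical_term("cc2_category", ref = "medium"),
                  linear_term("multinucleated")),
             random_intercept = "cycle_id", cc2_cutoffs = cc2_cutoffs)
}

spec_has_term <- function(spec, label) {
  label %in% vapply(spec$terms, `[[`, "", "label")
}

#' Assemble the embryo-level model frame
#'
#' Joins embryo and cycle tables, computes cc2 = t3 - t2 (clamped at 0 when a
#' timing manipulation has pushed t2 past t3) and its category.
#'
#' @inheritParams single_variable_screen
#' @param cutoffs [cc2_cutoffs()].
#' @return data frame with one row per embryo carrying all model covariates.
#' @export
prepare_model_frame <- function(cycles, embryos, cutoffs = cc2_cutoffs()) {
  mf <- merge(embryos, cycles, by = "cycle_id", sort = FALSE)
  mf <- mf[order(match(mf$embryo_id, embryos$embryo_id)), , drop = FALSE]
  rownames(mf) <- NULL
  mf$cc2 <- pmax(0, mf$t3 - mf$t2)
  mf$cc2_category <- categorize_cc2(mf$cc2, cutoffs)
  mf
}
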