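#' Serialize a fitted model to versioned JSON
#'
#' Writes everything needed to reproduce predictions: the term structure,
#' spline knots and constraint maps, coefficients, smoothing parameters,
#' random-intercept SD and fitted intercepts, effective degrees of freedom,
#' and the training-data fingerprint.
#'
#' @param model a `kidlb_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  spec <- model$spec
  terms <- lapply(spec$terms, function(tm) tm[setdiff(names(tm), "class")])
  blocks <- lapply(model$blocks[setdiff(names(model$blocks), "xlevels")],
                   function(b) list(knots = b$knots, degree = b$degree,
                                    Z = b$Z, S = b$S, rank = b$rank,
                                    penalty_order = b$penalty_order,
                                    n_basis = b$n_basis, xrange = b$xrange))
  payload <- list(
    format = "kidlb_fit", version = 1L,
    spec = list(terms = terms, random_intercept = spec$random_intercept,
                cc2_cutoffs = unclass(spec$cc2_cutoffs)),
    coefficients = as.list(model$coefficients),
    u = as.list(model$u),
    lambdas = model$lambdas, sigma_u = model$sigma_u,
    term_cols = model$term_cols, pen_ranks = as.list(model$pen_ranks),
    blocks = blocks, xlevels = model$blocks$xlevels,
    edf = model$edf, deviance = model$deviance, aic = model$aic,
    term_pvalues = as.list(model$term_pvalues),
    converged = model$converged, n = model$n,
    train_fingerprint = model$train_fingerprint)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON file written by [write_model()].
#' @return a `kidlb_fit` usable with [predict_probability()].
#' @export
read_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "kidlb_fit"))
    stop("not a serialized kidlb model: ", path, call. = FALSE)
  terms <- lapply(seq_len(nrow(pl$spec$terms)), function(i) {
    tm <- as.list(pl$spec$terms[i, ])
    tm <- tm[!vapply(tm, function(v) is.na(v) %in% TRUE, TRUE)]
    structure(tm, class = "kidlb_term")
  })
  spec <- model_spec(terms, pl$spec$random_intercept,
                     do.call(cc2_cutoffs, as.list(pl$spec$cc2_cutoffs)))
  blocks <- lapply(pl$blocks, function(b) {
    b$Z <- as.matrix(b$Z); b$S <- as.matrix(b$S)
    structure(b, class = "spline_block")
  })
  blocks$xlevels <- as.list(pl$xlevels)
  structure(list(
    spec = spec, coefficients = unlist(pl$coefficients),
    u = unlist(pl$u), lambdas = as.list(pl$lambdas), sigma_u = pl$sigma_u,
    term_cols = lapply(pl$term_cols, as.integer),
    pen_ranks = unlist(pl$pen_ranks), blocks = blocks,
    edf = pl$edf, deviance = pl$deviance, aic = pl$aic,
    term_pvalues = unlist(pl$term_pvalues), converged = pl$converged,
    n = pl$n, train_fingerprint = pl$train_fingerprint),
    class = "kidlb_fit")
}
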