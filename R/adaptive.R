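## Adaptive-lasso detectors: per-drug penalty multipliers built from a first
## stage (lasso-cv, univariate coefficients, lasso-bic, or CISL) and a second
## weighted-lasso stage with BIC- or cross-validation-based selection.

#' Construct adaptive penalty weights
#'
#' @param w numeric vector of per-drug penalty multipliers in `(0, Inf]`;
#'   `Inf` excludes the drug from the adaptive stage.
#' @param gamma weight exponent. Only `gamma = 1` is implemented (the usual
#'   choice for two-stage lasso weights); any other value errors.
#' @param source construction tag: `"lcv"`, `"univ"`, `"lb"` or `"cisl"`.
#' @return An object of class `adaptive_weights`.
#' @export
adaptive_weights <- function(w, gamma = 1, source = c("lcv", "univ", "lb", "cisl")) {
  source <- match.arg(source)
  w <- as.numeric(w)
  if (any(is.na(w)) || any(w <= 0)) stop("adaptive weights must be positive (Inf allowed)")
  if (!identical(gamma, 1) && !isTRUE(gamma == 1))
    stop("gamma != 1 is not implemented")
  structure(list(w = w, gamma = gamma, source = source),
            class = "adaptive_weights")
}

#' @export
print.adaptive_weights <- function(x, ...) {
  cat(sprintf("adaptive_weights [%s]: %d finite, %d excluded (Inf)\n",
              x$source, sum(is.finite(x$w)), sum(!is.finite(x$w))))
  invisible(x)
}

#' Adaptive weights from a cross-validated lasso
#'
#' First stage of the classical two-stage (iterated) lasso: `w_p =
#' 1/|beta_p|` for drugs selected by [cv_select()], infinite (exclusion)
#' otherwise. An empty first-stage support yields all-infinite weights and an
#' empty final signal set downstream.
#'
#' @inheritParams cv_select
#' @return An `adaptive_weights` object, with the first-stage result in
#'   `attr(, "first_stage")`.
#' @export
weights_lcv <- function(X, y, n_f = 5, seed = NULL, ...) {
  sel <- cv_select(X, y, n_f = n_f, seed = seed, ...)
  w <- ifelse(sel$coef != 0, 1 / abs(sel$coef), Inf)
  out <- adaptive_weights(w, source = "lcv")
  attr(out, "first_stage") <- sel
  out
}

#' Adaptive weights from univariate coefficients
#'
#' Fits one single-drug logistic regression (intercept + drug) per drug and
#' sets `w_p = 1/|beta_p|`. For a binary exposure this MLE is the log
#' odds-ratio of the 2x2 drug-by-event table; tables with an empty cell are
#' separated and refitted with a tiny ridge, and a never-reported drug gets an
#' infinite weight and a flag. There is no exclusion branch: an exactly-zero
#' univariate coefficient maps to the finite cap `w_max`.
#'
#' @inheritParams lambda_max
#' @param w_max cap applied when `|beta| < 1e-10` (default 1e10).
#' @return An `adaptive_weights` object with per-drug flags in
#'   `attr(, "flags")`.
#' @export
weights_univ <- function(X, y, w_max = 1e10) {
  rm <- as_report_matrix(X)
  y <- as_outcome(y, rm$N)
  a <- as.numeric(Matrix::crossprod(rm$X, y))
  n_drug <- Matrix::colSums(rm$X)
  n1 <- sum(y)
  b <- n_drug - a
  c <- n1 - a
  d <- rm$N - n_drug - c
  beta <- log(a * d / (b * c))
  flags <- character()
  degenerate <- which(!is.finite(beta) | a + b == 0)
  for (j in degenerate) {
    if (n_drug[j] == 0) {
      beta[j] <- NA_real_
      flags <- c(flags, sprintf("drug %d never reported", j))
    } else {  # empty cell: separated univariate fit, ridge-stabilized
      co <- ridge_logistic(cbind(1, as.numeric(rm$X[, j])), y, ridge = 1e-8)
      beta[j] <- co[2]
      flags <- c(flags, sprintf("drug %d: separation, ridge fit", j))
    }
  }
  w <- ifelse(is.na(beta), Inf, 1 / pmax(abs(beta), 1 / w_max))
  out <- adaptive_weights(w, source = "univ")
  attr(out, "flags") <- flags
  attr(out, "beta_univ") <- beta
  out
}

#' Adaptive weights from a BIC-selected lasso
#'
#' First stage is [bic_select()] on a plain lasso path; weights are the
#' reciprocal absolute *unpenalized refit* coefficients of the selected
#' support, with infinite weight (exclusion) off the support.
#'
#' @inheritParams fit_lasso_path
#' @return An `adaptive_weights` object, first-stage `selection_result` in
#'   `attr(, "first_stage")`.
#' @export
weights_lb <- function(X, y, n_lambda = 100, ratio = 1e-2) {
  path <- fit_lasso_path(X, y, n_lambda = n_lambda, ratio = ratio)
  sel <- bic_select(path, X, y)
  w <- ifelse(sel$coef != 0, 1 / abs(sel$coef), Inf)
  out <- adaptive_weights(w, source = "lb")
  attr(out, "first_stage") <- sel
  out
}

#' Adaptive weights from CISL
#'
#' Maps the `B`-vector of non-zero selection proportions `tau_hat_p` to a
#' weight: `1/B` when the drug is selected somewhere along the path in every
#' subsample, `Inf` (exclusion) when it never is, and otherwise one minus the
#' fraction of subsamples in which it is.
#'
#' @param result a `cisl_result` from [cisl_statistics()].
#' @return An `adaptive_weights` object.
#' @export
weights_cisl <- function(result) {
  stopifnot(inherits(result, "cisl_result"))
  nb <- colSums(result$tau_hat > 0)
  B <- result$B
  w <- ifelse(nb == B, 1 / B, ifelse(nb == 0, Inf, 1 - nb / B))
  adaptive_weights(w, source = "cisl")
}

#' Adaptive-lasso stage
#'
#' Drops infinitely-weighted drugs, fits the weighted lasso path on the rest,
#' and selects either by BIC over the path's distinct supports (positivity
#' judged on the unpenalized refit coefficients) or by cross-validation
#' (positivity on the penalized coefficients at the selected penalty; with a
#' `weight_builder`, the penalty is chosen by [nested_cv_lambda()] with
#' per-fold weight re-derivation).
#'
#' @inheritParams cv_select
#' @param w an `adaptive_weights` object (or numeric weight vector).
#' @param selector `"bic"` or `"cv"`.
#' @param method method tag recorded in the signal set.
#' @param weight_builder for `selector = "cv"`, `"lcv"` or `"univ"` to
#'   re-derive weights inside each fold; NULL fixes the supplied weights.
#' @return A [signal_set()]; the underlying `selection_result` is attached as
#'   `attr(, "selection")`.
#' @export
adaptive_fit <- function(X, y, w, selector = c("bic", "cv"), seed = NULL,
                         method = paste0("adaptive-", selector[1]),
                         weight_builder = NULL, n_f = 5,
                         n_lambda = 100, ratio = 1e-2) {
  selector <- match.arg(selector)
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  if (inherits(w, "adaptive_weights") && !isTRUE(w$gamma == 1))
    stop("gamma != 1 is not implemented")
  wv <- if (inherits(w, "adaptive_weights")) w$w else as.numeric(w)
  if (!any(is.finite(wv)))
    return(signal_set(method, character(), numeric(), rm$drug_labels))
  if (selector == "bic") {
    path <- fit_lasso_path(rm, y, wv, n_lambda = n_lambda, ratio = ratio)
    sel <- bic_select(path, rm, y)
  } else if (is.null(weight_builder)) {
    sel <- cv_select(rm, y, wv, n_f = n_f, seed = seed,
                     n_lambda = n_lambda, ratio = ratio)
  } else {
    nl <- nested_cv_lambda(rm, y, weight_builder, n_f = n_f, seed = seed,
                           n_lambda = n_lambda, ratio = ratio)
    if (is.na(nl$lambda_star))
      return(signal_set(method, character(), numeric(), rm$drug_labels))
    wv <- nl$weights
    path <- fit_lasso_path(rm, y, wv, lambdas = nl$grid)
    j <- match(nl$lambda_star, nl$grid)
    coef <- as.numeric(path$beta[, j])
    sel <- selection_result(which(coef != 0), coef, path$a0[j],
                            nl$lambda_star,
                            data.frame(lambda = nl$grid, cv_deviance = nl$cvm),
                            rm$drug_labels)
  }
  out <- positive_signals(unname(sel$coef), rm$drug_labels, method)
  attr(out, "selection") <- sel
  out
}

#' Nested cross-validation for the adaptive penalty
#'
#' Chooses the adaptive-stage penalty the way the CV-based adaptive lasso
#' prescribes: for each outer fold, adaptive weights are re-derived on the
#' training portion only (directly from univariate coefficients, or via an
#' embedded cross-validated lasso), a weighted path is fitted on the training
#' data, and validation deviance is recorded on a common full-data penalty
#' grid (the path is evaluated at the grid's own points, no interpolation).
#' The deviance-minimizing penalty is then used on the full data with
#' full-data weights.
#'
#' @inheritParams cv_select
#' @param weight_builder `"lcv"` or `"univ"`.
#' @return list with `lambda_star` (NA when the full-data weights exclude
#'   everything), `grid`, `cvm` (mean validation deviance) and the full-data
#'   `weights`.
#' @export
nested_cv_lambda <- function(X, y, weight_builder = c("lcv", "univ"),
                             n_f = 5, seed = NULL,
                             n_lambda = 100, ratio = 1e-2) {
  weight_builder <- match.arg(weight_builder)
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  build <- function(Xs, ys, sd)
    switch(weight_builder,
           lcv = weights_lcv(Xs, ys, n_f = n_f, seed = sd,
                             n_lambda = n_lambda, ratio = ratio),
           univ = weights_univ(Xs, ys))
  wfull <- build(rm$X, y, derive_seed(seed, 0L))$w
  if (!any(is.finite(wfull)))
    return(list(lambda_star = NA_real_, grid = numeric(), cvm = numeric(),
                weights = wfull))
  grid <- lambda_grid(rm, y, wfull, n_lambda = n_lambda, ratio = ratio)
  folds <- stratified_folds(y, n_f, derive_seed(seed, 1L))
  dev <- matrix(NA_real_, n_f, length(grid))
  for (k in seq_len(n_f)) {
    tr <- folds != k
    wk <- build(rm$X[tr, , drop = FALSE], y[tr], derive_seed(seed, 1L + k))$w
    if (!any(is.finite(wk))) {  # fold excludes everything: null model
      p0 <- rep(mean(y[tr]), sum(!tr))
      dev[k, ] <- binomial_deviance(y[!tr], p0) / sum(!tr)
      next
    }
    pk <- fit_lasso_path(rm$X[tr, , drop = FALSE], y[tr], wk, lambdas = grid)
    eta <- sweep(as.matrix(rm$X[!tr, , drop = FALSE] %*% pk$beta), 2, pk$a0, "+")
    dev[k, ] <- apply(stats::plogis(eta), 2, function(p)
      binomial_deviance(y[!tr], p)) / sum(!tr)
  }
  cvm <- colMeans(dev)
  list(lambda_star = grid[which.min(cvm)], grid = grid, cvm = cvm,
       weights = wfull)
}
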