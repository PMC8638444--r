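## Weighted L1-penalized logistic path fitting and the three strategies for
## choosing the regularization parameter (cross-validation, BIC, permutation).
##
## Objective convention used throughout:
##   -(1/N) loglik(beta0, beta) + lambda * sum_p w_p |beta_p|,
## with an unpenalized intercept. Under this scaling the null-entry point is
##   lambda_max = max_p |x_p' (y - ybar)| / (N w_p).

check_weights <- function(w, P) {
  if (is.null(w)) w <- rep(1, P)
  if (inherits(w, "adaptive_weights")) w <- w$w
  w <- as.numeric(w)
  if (length(w) != P) stop("need one penalty weight per drug")
  if (any(is.na(w)) || any(w <= 0)) stop("penalty weights must be positive (Inf allowed)")
  if (!any(is.finite(w))) stop("all penalty weights are infinite")
  w
}

#' Null-model entry point of the weighted lasso path
#'
#' Smallest penalty at which no drug enters the model:
#' `max_p |x_p' (y - mean(y))| / (N * w_p)` over drugs with finite weight.
#'
#' @param X a [report_matrix()] or sparse binary matrix.
#' @param y binary outcome.
#' @param weights per-drug penalty multipliers (default all 1; `Inf` excludes
#'   a drug).
#' @return positive scalar.
#' @export
lambda_max <- function(X, y, weights = NULL) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  if (length(unique(y)) < 2) stop("outcome is constant; no selection problem defined")
  w <- check_weights(weights, rm$P)
  g <- abs(as.numeric(Matrix::crossprod(rm$X, y - mean(y)))) / rm$N
  max(g[is.finite(w)] / w[is.finite(w)])
}

#' Log-spaced penalty grid
#'
#' @inheritParams lambda_max
#' @param n_lambda grid length (default 100).
#' @param ratio ratio of the smallest to the largest penalty (default 1e-2).
#' @return strictly decreasing numeric vector from `lambda_max` down to
#'   `ratio * lambda_max`.
#' @export
lambda_grid <- function(X, y, weights = NULL, n_lambda = 100, ratio = 1e-2) {
  lmax <- lambda_max(X, y, weights)
  exp(seq(log(lmax), log(ratio * lmax), length.out = n_lambda))
}

#' Fit a weighted logistic lasso path
#'
#' Thin wrapper around [glmnet::glmnet()] that fixes the objective convention
#' above: drugs with infinite weight are excluded up front, the penalty is not
#' re-standardized, and the requested `lambdas` are honoured exactly (glmnet's
#' internal rescaling of penalty factors is undone). Coefficients are
#' warm-started along the decreasing grid.
#'
#' @inheritParams lambda_max
#' @param lambdas decreasing penalty grid; defaults to [lambda_grid()].
#' @param n_lambda,ratio passed to [lambda_grid()] when `lambdas` is NULL.
#' @param thresh glmnet convergence threshold.
#' @param dfmax optional cap on the active-set size: the path stops once the
#'   model exceeds `dfmax` drugs (remaining grid points carry the last
#'   solution forward and are flagged).
#' @return An object of class `lasso_path`: `lambda`, sparse `beta`
#'   (P x n_lambda), `a0` (intercepts), `df` (active-set sizes),
#'   `weights`, and `flagged` (lambdas glmnet did not reach; their columns
#'   carry the last converged solution).
#' @export
fit_lasso_path <- function(X, y, weights = NULL, lambdas = NULL,
                           n_lambda = 100, ratio = 1e-2, thresh = 1e-8,
                           dfmax = NULL) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  w <- check_weights(weights, rm$P)
  if (is.null(lambdas))
    lambdas <- lambda_grid(rm, y, w, n_lambda = n_lambda, ratio = ratio)
  if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  finite <- which(is.finite(w))
  Xf <- rm$X[, finite, drop = FALSE]
  pf <- w[finite]
  pad <- ncol(Xf) < 2
  if (pad) {  # glmnet needs >= 2 columns; a zero column can never activate
    Xf <- cbind(Xf, Matrix::sparseMatrix(i = integer(), j = integer(),
                                         x = numeric(), dims = c(rm$N, 1)))
    pf <- c(pf, 1)
  }
  ## glmnet rescales penalty.factor to sum to nvars and scales lambda to
  ## match; undo so `lambdas` are on the stated objective scale.
  scale <- sum(pf) / length(pf)
  fit <- suppressWarnings(
    glmnet::glmnet(Xf, y, family = "binomial", lambda = lambdas * scale,
                   penalty.factor = pf, standardize = FALSE,
                   thresh = thresh, maxit = 1e6,
                   dfmax = if (is.null(dfmax)) ncol(Xf) + 1L else dfmax))
  L <- length(lambdas)
  got <- length(fit$lambda)
  bsub <- fit$beta
  a0 <- as.numeric(fit$a0)
  flagged <- integer(0)
  if (got < L) {  # early exit (e.g. saturation): carry last solution forward
    flagged <- seq.int(got + 1L, L)
    bsub <- cbind(bsub, bsub[, rep(got, L - got), drop = FALSE])
    a0 <- c(a0, rep(a0[got], L - got))
  }
  if (pad) bsub <- bsub[-nrow(bsub), , drop = FALSE]
  df <- as.integer(Matrix::colSums(bsub != 0))
  if (!is.null(dfmax)) {
    ## glmnet does not honour dfmax with a user lambda sequence: truncate at
    ## the first grid point whose active set exceeds the cap
    j <- match(TRUE, df > dfmax)
    if (!is.na(j) && j > 1L) {
      flagged <- sort(unique(c(flagged, seq.int(j, L))))
      bsub[, seq.int(j, L)] <- bsub[, rep(j - 1L, L - j + 1L), drop = FALSE]
      a0[seq.int(j, L)] <- a0[j - 1L]
      df[seq.int(j, L)] <- df[j - 1L]
    }
  }
  beta <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(rm$P, L))
  beta[finite, ] <- bsub
  rownames(beta) <- rm$drug_labels
  structure(list(lambda = lambdas, beta = beta, a0 = a0,
                 df = df,
                 weights = w, flagged = flagged,
                 drug_labels = rm$drug_labels),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso_path: %d lambdas in [%.4g, %.4g], df %d..%d, %d drugs\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              min(x$df), max(x$df), nrow(x$beta)))
  invisible(x)
}

selection_result <- function(support, coef, intercept, lambda_star,
                             criterion, labels, flags = character()) {
  structure(list(support = support,
                 coef = stats::setNames(coef, labels),
                 intercept = intercept, lambda_star = lambda_star,
                 criterion = criterion, flags = flags,
                 drug_labels = labels),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: |support| = %d%s\n", length(x$support),
              if (!is.null(x$lambda_star) && !is.na(x$lambda_star))
                sprintf(", lambda* = %.4g", x$lambda_star) else ""))
  invisible(x)
}

#' Cross-validated penalty selection
#'
#' Picks the penalty minimizing the mean validation binomial deviance across
#' `n_f` folds stratified on the outcome, then refits the path on the full
#' data and reports the penalized coefficients at the selected penalty.
#'
#' @inheritParams fit_lasso_path
#' @param n_f number of folds (default 5; `n_f = N` gives leave-one-out).
#' @param seed fold-assignment seed.
#' @return A `selection_result` with penalized `coef` at `lambda_star` and the
#'   per-lambda mean validation deviance in `criterion`.
#' @export
cv_select <- function(X, y, weights = NULL, n_f = 5, seed = NULL,
                      lambdas = NULL, n_lambda = 100, ratio = 1e-2) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  w <- check_weights(weights, rm$P)
  if (is.null(lambdas))
    lambdas <- lambda_grid(rm, y, w, n_lambda = n_lambda, ratio = ratio)
  folds <- stratified_folds(y, n_f, seed)
  dev <- matrix(NA_real_, n_f, length(lambdas))
  for (k in seq_len(n_f)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) {  # can occur only unstratified / LOO-like
      p0 <- rep(mean(y[tr]), sum(!tr))
      dev[k, ] <- binomial_deviance(y[!tr], p0) / sum(!tr)
      next
    }
    pk <- fit_lasso_path(rm$X[tr, , drop = FALSE], y[tr], w, lambdas = lambdas)
    eta <- sweep(as.matrix(rm$X[!tr, , drop = FALSE] %*% pk$beta), 2, pk$a0, "+")
    dev[k, ] <- apply(stats::plogis(eta), 2, function(p)
      binomial_deviance(y[!tr], p)) / sum(!tr)
  }
  cvm <- colMeans(dev)
  j <- which.min(cvm)
  full <- fit_lasso_path(rm, y, w, lambdas = lambdas)
  coef <- as.numeric(full$beta[, j])
  selection_result(which(coef != 0), coef, full$a0[j], lambdas[j],
                   data.frame(lambda = lambdas, cv_deviance = cvm),
                   rm$drug_labels)
}

#' Unpenalized logistic refit on a support
#'
#' Maximum-likelihood logistic regression of the outcome on the intercept plus
#' the given support columns. Rank-deficient supports are repaired
#' deterministically (scanning in index order, a column that does not increase
#' the rank is dropped and flagged); separated fits are stabilized with a tiny
#' ridge (1e-8) and flagged.
#'
#' @inheritParams lambda_max
#' @param support integer indices (or labels) of the drugs in the model.
#' @return list with `intercept`, `coef` (full-length vector, zero off the
#'   support), `support` (kept indices), `loglik` and `flags`.
#' @param start optional warm-start coefficients: `c(intercept, beta)` with
#'   `beta` a full length-P vector (entries off the support are ignored).
#' @export
refit_mle <- function(X, y, support, start = NULL) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  if (is.character(support)) support <- match(support, rm$drug_labels)
  support <- sort(unique(as.integer(support)))
  flags <- character()
  coef <- numeric(rm$P)
  if (!length(support)) {
    pbar <- mean(y)
    ll <- if (pbar %in% c(0, 1)) 0 else
      rm$N * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
    return(list(intercept = stats::qlogis(pbar), coef = stats::setNames(coef, rm$drug_labels),
                support = integer(0), loglik = ll, flags = flags))
  }
  if (length(support) >= rm$N) stop("support size must be below N")
  Xs <- methods::as(rm$X[, support, drop = FALSE], "CsparseMatrix")
  ## rank repair on the intercept-augmented Gram matrix, scanning in index
  ## order so the lowest index is kept on collinearity
  cs <- Matrix::colSums(Xs)
  G <- rbind(c(rm$N, cs), cbind(cs, as.matrix(Matrix::crossprod(Xs))))
  keep <- rank_keep(G)
  if (!all(keep)) {
    flags <- c(flags, sprintf("dropped collinear column %d",
                              support[which(!keep) - 1L]))
    support <- support[keep[-1]]
    Xs <- Xs[, keep[-1], drop = FALSE]
  }
  b0 <- if (is.null(start)) NULL else c(start[1], start[-1][support])
  fit <- newton_logistic(Xs, y, start = b0)
  if (fit$separated) {
    fit <- newton_logistic(Xs, y, ridge = 1e-8, maxit = 200,
                           start = fit$coef)
    flags <- c(flags, "separation: ridge-stabilized fit")
  }
  coef[support] <- fit$coef[-1]
  list(intercept = fit$coef[1],
       coef = stats::setNames(coef, rm$drug_labels),
       support = support,
       loglik = fit$loglik,
       flags = flags)
}

## Greedy independent-column scan on a Gram matrix (first column always kept).
rank_keep <- function(G, tol = 1e-9) {
  k <- ncol(G)
  keep <- logical(k)
  keep[1] <- TRUE
  if (k > 1 && qr(G, tol = tol)$rank == k) return(rep(TRUE, k))
  for (j in seq.int(2L, length.out = k - 1L)) {
    idx <- c(which(keep), j)
    Gi <- G[idx, idx, drop = FALSE]
    keep[j] <- qr(Gi, tol = tol)$rank == length(idx)
  }
  keep
}

## Stable log-likelihood from the linear predictor.
loglik_eta <- function(y, eta) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

## Newton-Raphson logistic MLE with an explicit (unpenalized) intercept on a
## sparse design, with step-halving; optional ridge for separated fits. The
## weighted Gram matrix is assembled on the dgCMatrix slots directly to avoid
## S4 dispatch overhead in the inner loop.
newton_logistic <- function(Xs, y, ridge = 0, maxit = 50, tol = 1e-10,
                            start = NULL) {
  k <- ncol(Xs) + 1L
  b <- numeric(k)
  b[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  if (!is.null(start) && length(start) == k && all(is.finite(start)))
    b <- start
  rowidx <- Xs@i + 1L
  lin <- function(b) b[1] + as.numeric(Xs %*% b[-1])
  obj <- function(b, eta) -loglik_eta(y, eta) + ridge * sum(b[-1]^2)
  eta <- lin(b)
  dev <- obj(b, eta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    r <- y - mu
    g <- c(sum(r), as.numeric(Matrix::crossprod(Xs, r)))
    Xw <- Xs
    Xw@x <- Xs@x * wt[rowidx]
    H <- rbind(c(sum(wt), Matrix::colSums(Xw)),
               cbind(Matrix::colSums(Xw),
                     as.matrix(Matrix::crossprod(Xs, Xw))))
    if (ridge > 0) {
      g <- g - 2 * ridge * c(0, b[-1])
      H <- H + diag(c(0, rep(2 * ridge, k - 1)), k)
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    for (half in 0:20) {  # step-halving
      bn <- b + step / 2^half
      etan <- lin(bn)
      devn <- obj(bn, etan)
      if (devn <= dev + 1e-12) break
    }
    moved <- max(abs(bn - b))
    b <- bn; eta <- etan
    if (dev - devn < tol * (abs(dev) + 1) && moved < 1e-6) {
      dev <- devn; converged <- TRUE; break
    }
    dev <- devn
    if (ridge == 0 && max(abs(b)) > 15) break  # diverging: separated
  }
  separated <- ridge == 0 &&
    (!converged || max(abs(b)) > 15 ||
       { mu <- stats::plogis(eta); any(mu < 1e-10) || any(mu > 1 - 1e-10) })
  list(coef = b, loglik = loglik_eta(y, eta),
       separated = separated, converged = converged)
}

## Newton/IRLS with a fixed ridge on all coefficients; used when the MLE
## diverges under separation.
ridge_logistic <- function(Xd, y, ridge = 1e-8, maxit = 100, tol = 1e-10) {
  b <- numeric(ncol(Xd))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xd %*% b)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    g <- as.numeric(crossprod(Xd, y - mu)) - ridge * b
    H <- crossprod(Xd * wt, Xd) + diag(ridge, ncol(Xd))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

#' Bayesian Information Criterion
#'
#' `-2 * loglik + df * log(N)`, with `df` the number of drugs in the model
#' (the intercept is always present and not counted).
#'
#' @param loglik log-likelihood of the unpenalized refit.
#' @param df model size.
#' @param N number of reports.
#' @return scalar BIC.
#' @export
bic_score <- function(loglik, df, N) {
  if (df < 0) stop("df must be nonnegative")
  -2 * loglik + df * log(N)
}

#' BIC-based selection over a lasso path
#'
#' Enumerates the distinct supports visited along the path (different lambdas
#' with the same support give the same refit, hence the same BIC), refits each
#' by unpenalized maximum likelihood, and returns the support minimizing the
#' BIC. Ties break toward the smaller support.
#'
#' @param path a `lasso_path`.
#' @inheritParams lambda_max
#' @return A `selection_result` whose `coef` are the unpenalized refit
#'   coefficients of the winning support; `criterion` traces every candidate.
#' @export
bic_select <- function(path, X, y) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  supports <- apply(path$beta != 0, 2, which, simplify = FALSE)
  keys <- vapply(supports, paste, "", collapse = ",")
  uni <- which(!duplicated(keys))
  supports <- supports[uni]
  flags <- character()
  cand <- lapply(seq_along(supports), function(u) {
    j <- uni[u]  # warm-start from the penalized fit where the support arose
    fit <- refit_mle(rm, y, supports[[u]],
                     start = c(path$a0[j], as.numeric(path$beta[, j])))
    fit$bic <- bic_score(fit$loglik, length(fit$support), rm$N)
    fit
  })
  bics <- vapply(cand, `[[`, 0, "bic")
  sizes <- vapply(cand, function(f) length(f$support), 0L)
  best <- order(bics, sizes)[1]
  fit <- cand[[best]]
  selection_result(fit$support, unname(fit$coef), fit$intercept, NA_real_,
                   data.frame(support = keys[uni], df = sizes, bic = bics),
                   rm$drug_labels,
                   unlist(lapply(cand, `[[`, "flags")))
}

#' Permutation-based penalty selection
#'
#' For each of `K` uniform permutations of the outcome, computes the
#' null-entry penalty [lambda_max()] of the permuted problem; the selected
#' penalty is the median of the `K` values (midpoint of the two central order
#' statistics for even `K`). The final model is a lasso fit on the original
#' outcome at that penalty, and the penalized coefficients are reported.
#'
#' @inheritParams cv_select
#' @param K number of permutations (default 20).
#' @return A `selection_result`; `criterion` holds the per-permutation
#'   `lambda_max` values.
#' @export
perm_select <- function(X, y, K = 20, seed = NULL,
                        n_lambda = 100, ratio = 1e-2) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  if (K < 1) stop("K must be at least 1")
  lmaxes <- with_seed(seed, vapply(seq_len(K), function(l)
    lambda_max(rm, sample(y)), 0))
  lstar <- stats::median(lmaxes)
  lmax0 <- lambda_max(rm, y)
  if (lstar >= lmax0) {
    coef <- numeric(rm$P)
    return(selection_result(integer(0), coef, stats::qlogis(mean(y)), lstar,
                            data.frame(perm = seq_len(K), lambda_max = lmaxes),
                            rm$drug_labels))
  }
  grid <- exp(seq(log(lmax0), log(lstar), length.out = n_lambda))
  fit <- fit_lasso_path(rm, y, lambdas = grid)
  j <- length(grid)
  coef <- as.numeric(fit$beta[, j])
  selection_result(which(coef != 0), coef, fit$a0[j], lstar,
                   data.frame(perm = seq_len(K), lambda_max = lmaxes),
                   rm$drug_labels)
}
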