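## High-dimensional propensity-score detectors: per-drug exposure models with
## BIC-lasso confounder selection among all other drugs, followed by
## adjustment or weighting analyses with one-sided Wald tests and
## Benjamini-Yekutieli correction.

#' Estimate a drug's propensity score
#'
#' Treats the drug column as the exposure, selects confounders among all
#' other drugs with [bic_select()] on a lasso path, and refits the selected
#' exposure model by unpenalized maximum likelihood (intercept-only when the
#' selection is empty). The fitted probabilities are the propensity scores.
#'
#' @inheritParams lambda_max
#' @param drug column index (or label) of the exposure drug.
#' @param n_lambda,ratio selection-path grid.
#' @return An object of class `propensity_fit`: `drug`, `covariates`
#'   (selected confounder labels), `ps` (length-N fitted probabilities),
#'   `coef`, `intercept`.
#' @export
estimate_ps <- function(X, drug, n_lambda = 100, ratio = 1e-2) {
  rm <- as_report_matrix(X)
  if (is.character(drug)) drug <- match(drug, rm$drug_labels)
  Z <- as.integer(as.numeric(rm$X[, drug]))
  if (length(unique(Z)) < 2) stop("exposure column is constant")
  Xo <- rm$X[, -drug, drop = FALSE]
  path <- fit_lasso_path(Xo, Z, n_lambda = n_lambda, ratio = ratio)
  sel <- bic_select(path, Xo, Z)
  refit <- refit_mle(Xo, Z, sel$support)
  ps <- stats::plogis(refit$intercept +
                        as.numeric(Xo %*% refit$coef))
  structure(list(drug = drug, drug_label = rm$drug_labels[drug],
                 covariates = rm$drug_labels[-drug][refit$support],
                 ps = ps, coef = refit$coef, intercept = refit$intercept,
                 Z = Z),
            class = "propensity_fit")
}

#' Inverse-probability-of-treatment weights
#'
#' `1/ps` for exposed reports, `1/(1-ps)` for unexposed.
#'
#' @param ps propensity scores in (0, 1).
#' @param Z binary exposure vector.
#' @return numeric weights.
#' @export
iptw_weights <- function(ps, Z) {
  if (any(ps <= 0) || any(ps >= 1)) stop("propensity scores must lie in (0,1)")
  ifelse(Z == 1, 1 / ps, 1 / (1 - ps))
}

#' Percentile truncation of analysis weights
#'
#' Clamps weights to the `[r, 1-r]` empirical percentile interval of the
#' pooled weight distribution (linear-interpolation quantiles, both exposure
#' arms pooled). `r = 0` is the identity.
#'
#' @param weights numeric weights.
#' @param r truncation fraction (default 0.025).
#' @return truncated weights.
#' @export
truncate_weights <- function(weights, r = 0.025) {
  if (r < 0 || r >= 0.5) stop("r must be in [0, 0.5)")
  if (r == 0) return(weights)
  q <- stats::quantile(weights, c(r, 1 - r), names = FALSE, type = 7)
  pmin(pmax(weights, q[1]), q[2])
}

#' Matching weights
#'
#' `min(ps, 1-ps)` divided by the probability of the arm actually observed;
#' always in (0, 1], down-weighting reports far from exposure equipoise.
#'
#' @inheritParams iptw_weights
#' @return numeric weights.
#' @export
mw_weights <- function(ps, Z) {
  if (any(ps <= 0) || any(ps >= 1)) stop("propensity scores must lie in (0,1)")
  pmin(ps, 1 - ps) / ifelse(Z == 1, ps, 1 - ps)
}

#' One-sided test of a drug effect given its propensity score
#'
#' `mode = "adjust"` fits an unweighted logistic regression of the outcome on
#' the exposure and its propensity score (linear on the logit scale) and
#' returns the one-sided model-based Wald p-value for a harmful effect
#' (`beta_Z > 0`). The weighting modes fit a weighted logistic regression of
#' the outcome on the exposure alone, with IPTW, truncated-IPTW or matching
#' weights, and use a robust sandwich variance.
#'
#' @param y binary outcome.
#' @param Z binary exposure.
#' @param fit a `propensity_fit` for the drug (or a numeric ps vector).
#' @param mode `"adjust"`, `"iptw"`, `"iptwT"` or `"mw"`.
#' @param trunc_r truncation fraction for `"iptwT"`.
#' @return list with `p` (one-sided), `estimate`, `se` and `flags`.
#' @export
ps_drug_test <- function(y, Z, fit, mode = c("adjust", "iptw", "iptwT", "mw"),
                         trunc_r = 0.025) {
  mode <- match.arg(mode)
  y <- as_outcome(y)
  ps <- if (inherits(fit, "propensity_fit")) fit$ps else as.numeric(fit)
  flags <- character()
  res <- tryCatch({
    if (mode == "adjust") {
      m <- suppressWarnings(stats::glm(y ~ Z + ps, family = stats::binomial()))
      if (!m$converged) stop("no convergence")
      est <- stats::coef(m)["Z"]
      se <- sqrt(stats::vcov(m)["Z", "Z"])
    } else {
      w <- iptw_weights(ps, Z)
      if (mode == "iptwT") w <- truncate_weights(w, trunc_r)
      if (mode == "mw") w <- mw_weights(ps, Z)
      dat <- data.frame(y = y, Z = Z, w = w)
      m <- suppressWarnings(stats::glm(y ~ Z, family = stats::quasibinomial(),
                                       weights = w, data = dat))
      if (!m$converged) stop("no convergence")
      est <- stats::coef(m)["Z"]
      se <- sqrt(sandwich::vcovHC(m, type = "HC0")["Z", "Z"])
    }
    list(p = unname(stats::pnorm(est / se, lower.tail = FALSE)),
         estimate = unname(est), se = unname(se))
  }, error = function(e) {
    flags <<- c(flags, conditionMessage(e))
    list(p = 1, estimate = NA_real_, se = NA_real_)
  })
  c(res, list(flags = flags))
}

#' Benjamini-Yekutieli correction and declaration
#'
#' Adjusts p-values for multiple testing under arbitrary dependence and
#' declares drugs whose adjusted p-value is at most the FDR level `q`.
#'
#' @param pvalues named numeric vector of one-sided p-values (ineligible
#'   drugs should carry 1).
#' @param q FDR level (default 0.05).
#' @param eligible optional logical vector recorded in the table.
#' @return An object of class `test_table`: data.frame with `drug`, `p`,
#'   `p_adj`, `eligible`, `declared`, plus the level in `attr(, "q")`.
#' @export
by_adjust <- function(pvalues, q = 0.05, eligible = NULL) {
  p_adj <- stats::p.adjust(pvalues, method = "BY")
  tab <- data.frame(drug = if (is.null(names(pvalues)))
                      as.character(seq_along(pvalues)) else names(pvalues),
                    p = as.numeric(pvalues), p_adj = as.numeric(p_adj),
                    eligible = if (is.null(eligible)) TRUE else as.logical(eligible),
                    declared = as.numeric(p_adj) <= q)
  attr(tab, "q") <- q
  class(tab) <- c("test_table", "data.frame")
  tab
}

#' Propensity-score signal detection across all drugs
#'
#' Runs the co-report eligibility filter, estimates a propensity score and a
#' one-sided test for every eligible drug (ineligible drugs keep p = 1),
#' applies the Benjamini-Yekutieli correction at level `fdr` and declares the
#' surviving drugs.
#'
#' @inheritParams lambda_max
#' @inheritParams ps_drug_test
#' @param threshold co-report filter threshold (default 3).
#' @param fdr FDR level (default 0.05).
#' @param n_lambda,ratio confounder-selection path grid.
#' @return A [signal_set()] with the BY-adjusted p-values as scores; the full
#'   `test_table` is attached as `attr(, "table")`.
#' @export
ps_detect <- function(X, y, mode = c("adjust", "iptw", "iptwT", "mw"),
                      threshold = 3, fdr = 0.05, trunc_r = 0.025,
                      n_lambda = 100, ratio = 1e-2) {
  mode <- match.arg(mode)
  rm <- as_report_matrix(X)
  y <- as_outcome(y, rm$N)
  eligible <- coreport_filter(rm, y, threshold)
  p <- stats::setNames(rep(1, rm$P), rm$drug_labels)
  for (j in which(eligible)) {
    Z <- as.integer(as.numeric(rm$X[, j]))
    if (length(unique(Z)) < 2) next  # constant exposure: skipped, p stays 1
    fit <- estimate_ps(rm, j, n_lambda = n_lambda, ratio = ratio)
    p[j] <- ps_drug_test(y, Z, fit, mode = mode, trunc_r = trunc_r)$p
  }
  tab <- by_adjust(p, q = fdr, eligible = eligible)
  declared <- tab$drug[tab$declared]
  out <- signal_set(paste0("ps-", sub("iptwT", "iptwT", mode)),
                    declared, tab$p_adj[tab$declared],
                    rm$drug_labels, eligible)
  attr(out, "table") <- tab
  out
}
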