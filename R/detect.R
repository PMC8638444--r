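#' Run a signal detection method by name
#'
#' Unified dispatcher over the fourteen detectors compared in this package:
#' `rfet`; `lasso-cv`, `lasso-bic`, `lasso-perm`, `cisl`; the adaptive-lasso
#' family `adapt-cv`, `adapt-univ`, `adapt-univ-bic`, `adapt-bic`,
#' `adapt-cisl`; and the propensity-score family `ps-adjust`, `ps-iptw`,
#' `ps-iptwT`, `ps-mw`.
#'
#' @inheritParams lambda_max
#' @param method one of the tags above.
#' @param seed RNG seed for the method's internal randomness (folds,
#'   permutations, subsamples).
#' @param n_f CV folds; `K` permutations; `B`, `subsample_size`,
#'   `case_weight`, `quantile` CISL controls; `threshold`, `fdr`, `trunc_r`,
#'   `variant` test controls; `n_lambda`, `ratio` path grid.
#' @param K,B,subsample_size,case_weight,quantile,threshold,fdr,trunc_r,variant
#'   see above.
#' @return A [signal_set()].
#' @export
detect_signals <- function(X, y, method, seed = NULL,
                           n_f = 5, K = 20,
                           B = 100, subsample_size = NULL, case_weight = NULL,
                           quantile = 0.10,
                           threshold = 3, fdr = 0.05, trunc_r = 0.025,
                           variant = "standard",
                           n_lambda = 100, ratio = 1e-2) {
  rm <- as_report_matrix(X)
  y <- as_outcome(y, rm$N)
  labels <- rm$drug_labels
  cisl_res <- function(s) cisl_statistics(rm, y, B = B, size = subsample_size,
                                          case_weight = case_weight, seed = s,
                                          ratio = ratio)
  switch(method,
    "rfet" = rfet_detect(rm, y, variant = variant, threshold = threshold,
                         fdr = fdr),
    "lasso-cv" = {
      sel <- cv_select(rm, y, n_f = n_f, seed = seed,
                       n_lambda = n_lambda, ratio = ratio)
      positive_signals(unname(sel$coef), labels, "lasso-cv")
    },
    "lasso-bic" = {
      path <- fit_lasso_path(rm, y, n_lambda = n_lambda, ratio = ratio)
      sel <- bic_select(path, rm, y)
      out <- positive_signals(unname(sel$coef), labels, "lasso-bic")
      attr(out, "selection") <- sel
      out
    },
    "lasso-perm" = {
      sel <- perm_select(rm, y, K = K, seed = seed,
                         n_lambda = n_lambda, ratio = ratio)
      positive_signals(unname(sel$coef), labels, "lasso-perm")
    },
    "cisl" = cisl_select(cisl_res(seed), q = quantile),
    "adapt-cv" = adaptive_fit(rm, y, w = rep(1, rm$P), selector = "cv",
                              weight_builder = "lcv", seed = seed,
                              method = "adapt-cv", n_f = n_f,
                              n_lambda = n_lambda, ratio = ratio),
    "adapt-univ" = adaptive_fit(rm, y, w = rep(1, rm$P), selector = "cv",
                                weight_builder = "univ", seed = seed,
                                method = "adapt-univ", n_f = n_f,
                                n_lambda = n_lambda, ratio = ratio),
    "adapt-univ-bic" = adaptive_fit(rm, y, weights_univ(rm, y),
                                    selector = "bic", method = "adapt-univ-bic",
                                    n_lambda = n_lambda, ratio = ratio),
    "adapt-bic" = adaptive_fit(rm, y,
                               weights_lb(rm, y, n_lambda = n_lambda,
                                          ratio = ratio),
                               selector = "bic", method = "adapt-bic",
                               n_lambda = n_lambda, ratio = ratio),
    "adapt-cisl" = adaptive_fit(rm, y, weights_cisl(cisl_res(seed)),
                                selector = "bic", method = "adapt-cisl",
                                n_lambda = n_lambda, ratio = ratio),
    "ps-adjust" = ps_detect(rm, y, "adjust", threshold, fdr,
                            n_lambda = n_lambda, ratio = ratio),
    "ps-iptw" = ps_detect(rm, y, "iptw", threshold, fdr,
                          n_lambda = n_lambda, ratio = ratio),
    "ps-iptwT" = ps_detect(rm, y, "iptwT", threshold, fdr, trunc_r,
                           n_lambda = n_lambda, ratio = ratio),
    "ps-mw" = ps_detect(rm, y, "mw", threshold, fdr,
                        n_lambda = n_lambda, ratio = ratio),
    stop(sprintf("unknown method '%s'", method))
  )
}

#' Implemented detection methods
#' @return character vector of method tags accepted by [detect_signals()].
#' @export
detection_methods <- function() {
  c("rfet", "lasso-cv", "lasso-bic", "lasso-perm", "cisl",
    "adapt-cv", "adapt-univ", "adapt-univ-bic", "adapt-bic", "adapt-cisl",
    "ps-adjust", "ps-iptw", "ps-iptwT", "ps-mw")
}
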