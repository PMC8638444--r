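## Class-imbalanced subsampling lasso (CISL).
##
## Stability-selection-style detector tailored to rare outcomes: bootstrap
## subsamples are drawn with replacement with cases over-weighted, a lasso
## path is fitted to each, and for each drug the fraction of the first E
## model sizes in which its coefficient is positive (pi-hat) or non-zero
## (tau-hat) is recorded. Selection thresholds a low quantile of the pi-hat
## distribution across subsamples.

#' Draw class-rebalanced bootstrap subsamples
#'
#' Samples with replacement, with each case (`y = 1`) weighted `case_weight`
#' times a control, so rare outcomes are better represented. The default
#' weight `max(1, n0/n1)` makes the expected case fraction of a subsample
#' `min(0.5, observed fraction)`-balanced, i.e. rebalances toward 50% cases
#' without ever down-weighting cases.
#'
#' @param y binary outcome.
#' @param B number of subsamples (default 100).
#' @param size subsample size (default `floor(N/2)`).
#' @param case_weight sampling weight of a case relative to a control
#'   (must be >= 1).
#' @param seed RNG seed.
#' @return list of `B` integer index vectors (with replacement);
#'   `attr(, "case_weight")` records the weight used.
#' @export
draw_subsamples <- function(y, B = 100, size = NULL, case_weight = NULL,
                            seed = NULL) {
  y <- as_outcome(y)
  N <- length(y)
  n1 <- sum(y)
  if (n1 == 0) stop("no cases in the outcome")
  if (is.null(size)) size <- floor(N / 2)
  if (size > N) stop("subsample size exceeds N")
  if (is.null(case_weight)) case_weight <- max(1, (N - n1) / n1)
  if (case_weight < 1) stop("case_weight must be >= 1")
  prob <- ifelse(y == 1, case_weight, 1)
  out <- with_seed(seed, lapply(seq_len(B), function(b)
    sample.int(N, size, replace = TRUE, prob = prob)))
  attr(out, "case_weight") <- case_weight
  attr(out, "size") <- size
  out
}

#' Path coefficients at a target model size
#'
#' Returns the coefficient vector at the first (largest-penalty) path point
#' whose active-set size reaches `eta`; when the active-set sequence skips
#' `eta` the first point exceeding it is used, and when the path never
#' reaches `eta` the final path point is used.
#'
#' @param path a `lasso_path`.
#' @param eta target number of active drugs.
#' @return numeric coefficient vector.
#' @export
path_coef_by_size <- function(path, eta) {
  j <- match(TRUE, path$df >= eta)
  if (is.na(j)) j <- length(path$df)
  as.numeric(path$beta[, j])
}

## Index of the path point used for each eta in 1..E (first-crossing with
## carry-forward at skips, truncation at the path end).
path_index_by_size <- function(df, E) {
  L <- length(df)
  idx <- integer(E)
  for (eta in seq_len(E)) {
    j <- match(TRUE, df >= eta)
    idx[eta] <- if (is.na(j)) L else j
  }
  idx
}

#' Compute CISL subsampling statistics
#'
#' Fits one lasso path per subsample and records, for each drug `p` and
#' subsample `b`, the fraction of model sizes `eta = 1..E` at which the
#' drug's coefficient is strictly positive (`pi_hat`) or non-zero
#' (`tau_hat`), where `E` is the largest final active-set size over all
#' subsample paths. A subsample with a constant outcome is redrawn with an
#' incremented seed and logged.
#'
#' @inheritParams lambda_max
#' @inheritParams draw_subsamples
#' @param n_lambda,ratio subsample path grid (defaults 50, 1e-2).
#' @param dfmax cap on the subsample active-set size (default 50): the
#'   selection-frequency statistics are computed over the first `E` model
#'   sizes of each path, and capping keeps `E` well below `P` so that late,
#'   unstable path entries do not dilute them.
#' @return An object of class `cisl_result`: `pi_hat` and `tau_hat`
#'   (`B x P` matrices), `E`, `B`, and `subsample_log`.
#' @export
cisl_statistics <- function(X, y, B = 100, size = NULL, case_weight = NULL,
                            seed = NULL, n_lambda = 50, ratio = 1e-2,
                            dfmax = 50) {
  rm <- as_design(X)
  y <- as_outcome(y, rm$N)
  subs <- draw_subsamples(y, B = B, size = size, case_weight = case_weight,
                          seed = seed)
  log <- data.frame(b = seq_len(B), redrawn = FALSE)
  for (b in seq_len(B)) {  # redraw degenerate subsamples
    tries <- 0L
    while (length(unique(y[subs[[b]]])) < 2 && tries < 100L) {
      tries <- tries + 1L
      subs[[b]] <- with_seed(derive_seed(seed, b * 1000L + tries), {
        prob <- ifelse(y == 1, attr(subs, "case_weight"), 1)
        sample.int(rm$N, attr(subs, "size"), replace = TRUE, prob = prob)
      })
      log$redrawn[b] <- TRUE
    }
    if (length(unique(y[subs[[b]]])) < 2)
      stop("could not draw a subsample containing both outcome classes")
  }
  paths <- lapply(seq_len(B), function(b) {
    idx <- subs[[b]]
    fit_lasso_path(rm$X[idx, , drop = FALSE], y[idx],
                   n_lambda = n_lambda, ratio = ratio, dfmax = dfmax)
  })
  E <- max(vapply(paths, function(p) p$df[length(p$df)], 0L))
  pi_hat <- matrix(0, B, rm$P, dimnames = list(NULL, rm$drug_labels))
  tau_hat <- pi_hat
  for (b in seq_len(B)) {
    p <- paths[[b]]
    idx <- path_index_by_size(p$df, E)
    mult <- tabulate(idx, nbins = length(p$df))  # times each path point is used
    use <- which(mult > 0)
    bsub <- p$beta[, use, drop = FALSE]
    pi_hat[b, ] <- as.numeric((bsub > 0) %*% mult[use]) / E
    tau_hat[b, ] <- as.numeric((bsub != 0) %*% mult[use]) / E
  }
  structure(list(pi_hat = pi_hat, tau_hat = tau_hat, E = E, B = B,
                 subsample_log = log, drug_labels = rm$drug_labels),
            class = "cisl_result")
}

#' @export
print.cisl_result <- function(x, ...) {
  cat(sprintf("cisl_result: B = %d subsamples, %d drugs, E = %d\n",
              x$B, ncol(x$pi_hat), x$E))
  invisible(x)
}

#' CISL quantile selection rule
#'
#' Declares drug `p` when the lower (type-1) empirical `q`-quantile of its
#' `pi_hat` distribution across subsamples is strictly positive -- i.e. when
#' strictly fewer than `ceiling(q * B)` of the `B` values are zero.
#'
#' @param result a `cisl_result`.
#' @param q quantile level (default 0.10).
#' @return A [signal_set()] with the mean `pi_hat` as score.
#' @export
cisl_select <- function(result, q = 0.10) {
  stopifnot(inherits(result, "cisl_result"), q > 0, q < 1)
  zeros <- colSums(result$pi_hat == 0)
  declared <- which(zeros < ceiling(q * result$B))
  labels <- result$drug_labels
  signal_set("cisl", labels[declared],
             colMeans(result$pi_hat)[declared], labels)
}
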