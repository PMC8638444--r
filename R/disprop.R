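## Disproportionality baseline: reporting Fisher's exact test (RFET) on the
## 2x2 drug-by-event contingency table, with BY correction across drugs.

#' 2x2 drug-by-event contingency table
#'
#' @inheritParams lambda_max
#' @param drug column index (or label).
#' @return named integer vector `(a, b, c, d)`: reports with drug & event,
#'   drug without event, event without drug, neither. Margins sum to N.
#' @export
contingency <- function(X, y, drug) {
  rm <- as_report_matrix(X)
  y <- as_outcome(y, rm$N)
  if (is.character(drug)) drug <- match(drug, rm$drug_labels)
  x <- as.numeric(rm$X[, drug])
  a <- sum(x * y)
  c(a = as.integer(a), b = as.integer(sum(x) - a),
    c = as.integer(sum(y) - a), d = as.integer(rm$N - sum(x) - sum(y) + a))
}

#' Reporting Fisher's exact test
#'
#' One-sided exact p-value for over-reporting of the event with the drug:
#' the upper hypergeometric tail `P[A >= a]` with the table margins fixed.
#' The mid-p variant subtracts half the point mass at the observed count.
#' Degenerate margins (an empty row or column) give p = 1.
#'
#' @param table a contingency vector `(a, b, c, d)` from [contingency()].
#' @param variant `"standard"` or `"midp"`.
#' @return one-sided p-value.
#' @export
rfet <- function(table, variant = c("standard", "midp")) {
  variant <- match.arg(variant)
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  m <- a + b          # reports with the drug
  k <- a + c          # reports with the event
  N <- a + b + c + d
  if (m == 0 || k == 0 || m == N || k == N) return(1)
  p <- stats::phyper(a - 1, m, N - m, k, lower.tail = FALSE)
  if (variant == "midp") p <- p - 0.5 * stats::dhyper(a, m, N - m, k)
  unname(p)
}

#' RFET signal detection across all drugs
#'
#' Applies the co-report eligibility filter (ineligible drugs keep p = 1),
#' computes the one-sided RFET p-value per eligible drug, and declares drugs
#' surviving Benjamini-Yekutieli correction at level `fdr`.
#'
#' @inheritParams ps_detect
#' @param variant `"standard"` or `"midp"`.
#' @return A [signal_set()] with BY-adjusted p-values as scores; full
#'   `test_table` in `attr(, "table")`.
#' @export
rfet_detect <- function(X, y, variant = c("standard", "midp"),
                        threshold = 3, fdr = 0.05) {
  variant <- match.arg(variant)
  rm <- as_report_matrix(X)
  y <- as_outcome(y, rm$N)
  eligible <- coreport_filter(rm, y, threshold)
  p <- stats::setNames(rep(1, rm$P), rm$drug_labels)
  for (j in which(eligible))
    p[j] <- rfet(contingency(rm, y, j), variant = variant)
  tab <- by_adjust(p, q = fdr, eligible = eligible)
  out <- signal_set("rfet", tab$drug[tab$declared], tab$p_adj[tab$declared],
                    rm$drug_labels, eligible)
  attr(out, "table") <- tab
  out
}
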