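#' Construct a report matrix
#'
#' Bundles a sparse binary drug-exposure matrix (reports in rows, drugs in
#' columns) with its drug labels. This is the design matrix of the logistic
#' model underlying all detectors: one row per spontaneous report, one column
#' per drug, entry 1 when the drug appears on the report.
#'
#' @param X matrix-like object coercible to a sparse matrix; entries must be
#'   0/1. Stored entries are deduplicated (a drug reported twice on one report
#'   counts once).
#' @param drug_labels character vector of unique drug identifiers, one per
#'   column. Defaults to `colnames(X)` or `d1..dP`.
#' @return An object of class `report_matrix` with elements `X` (a
#'   `dgCMatrix`), `drug_labels`, `N` and `P`.
#' @export
report_matrix <- function(X, drug_labels = NULL) {
  X <- methods::as(methods::as(methods::as(X, "CsparseMatrix"),
                               "generalMatrix"), "dMatrix")
  if (length(X@x) && any(X@x != 0 & X@x != 1))
    stop("exposure matrix entries must be 0/1")
  X <- Matrix::drop0(X)
  if (nrow(X) < 1L || ncol(X) < 1L) stop("need at least one report and one drug")
  if (is.null(drug_labels)) drug_labels <- colnames(X)
  if (is.null(drug_labels)) drug_labels <- paste0("d", seq_len(ncol(X)))
  drug_labels <- as.character(drug_labels)
  if (length(drug_labels) != ncol(X))
    stop("drug_labels length must equal ncol(X)")
  if (anyDuplicated(drug_labels)) stop("duplicated drug label")
  colnames(X) <- drug_labels
  structure(list(X = X, drug_labels = drug_labels,
                 N = nrow(X), P = ncol(X)),
            class = "report_matrix")
}

#' @export
print.report_matrix <- function(x, ...) {
  cat(sprintf("report_matrix: %d reports x %d drugs, %d exposures (density %.4g)\n",
              x$N, x$P, length(x$X@x), length(x$X@x) / (x$N * x$P)))
  invisible(x)
}

#' @export
dim.report_matrix <- function(x) c(x$N, x$P)

## Coerce to report_matrix, accepting a bare (sparse) matrix.
as_report_matrix <- function(X) {
  if (inherits(X, "report_matrix")) X else report_matrix(X)
}

## Like as_report_matrix but without the 0/1 restriction: the penalized
## regression core is generic in the design, only report-level semantics
## (co-report counts, contingency tables) require binary entries.
as_design <- function(X) {
  if (is.list(X) && all(c("X", "drug_labels", "N", "P") %in% names(X)))
    return(X)
  X <- methods::as(methods::as(X, "CsparseMatrix"), "generalMatrix")
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("d", seq_len(ncol(X)))
  colnames(X) <- labels
  list(X = X, drug_labels = labels, N = nrow(X), P = ncol(X))
}

#' Validate a binary outcome vector
#'
#' @param y vector of 0/1 adverse-event indicators, one per report.
#' @param n expected length (number of reports), or NULL to skip the check.
#' @return integer vector of 0/1.
#' @export
as_outcome <- function(y, n = NULL) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome values must be 0 or 1")
  if (!is.null(n) && length(y) != n)
    stop("outcome length does not match the number of reports")
  as.integer(y)
}

#' Construct a signal set
#'
#' The common return type of all detectors: the drugs a method declares as
#' signals together with a per-drug score (a regression coefficient for
#' selection-based methods, a BY-adjusted p-value for tested methods).
#'
#' @param method method tag, e.g. `"lasso-bic"`.
#' @param declared character vector of declared drug labels.
#' @param score numeric vector aligned with `declared`.
#' @param drug_labels full label set the method operated on.
#' @param eligible optional named logical vector (co-report eligibility).
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(method, declared, score, drug_labels,
                       eligible = NULL) {
  declared <- as.character(declared)
  if (!all(declared %in% drug_labels))
    stop("declared drugs must be a subset of drug_labels")
  if (length(score) != length(declared))
    stop("score must align with declared")
  if (!is.null(eligible) && length(declared))
    stopifnot(all(eligible[declared]))
  structure(list(method = method, declared = declared,
                 score = stats::setNames(as.numeric(score), declared),
                 drug_labels = drug_labels, eligible = eligible),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("signal_set [%s]: %d signal(s) out of %d drugs\n",
              x$method, length(x$declared), length(x$drug_labels)))
  if (length(x$declared)) {
    df <- data.frame(drug = x$declared, score = unname(x$score))
    print(utils::head(df[order(-abs(df$score)), ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Co-report eligibility filter
#'
#' Flags drugs with strictly more than `threshold` reports in common with the
#' adverse event. Tested detectors (propensity-score methods, the reporting
#' Fisher exact test) are run only on eligible drugs; the remainder keep a
#' p-value of one before multiple-testing correction.
#'
#' @param X a `report_matrix` or sparse binary matrix.
#' @param y binary outcome vector.
#' @param threshold co-report count that must be exceeded (default 3, i.e. a
#'   drug needs at least 4 reports with the event).
#' @return named logical vector, TRUE for eligible drugs.
#' @export
coreport_filter <- function(X, y, threshold = 3) {
  rm <- as_report_matrix(X)
  y <- as_outcome(y, rm$N)
  co <- as.numeric(Matrix::crossprod(rm$X, y))
  stats::setNames(co > threshold, rm$drug_labels)
}

#' Declare signals from a coefficient vector
#'
#' The positive-coefficient signal rule shared by all regression-based
#' detectors: every drug with a strictly positive fitted coefficient is
#' declared. L1 solvers return exact zeros for inactive covariates, so no
#' epsilon is applied.
#'
#' @param coefficients numeric P-vector of fitted drug coefficients.
#' @param labels drug labels aligned with `coefficients`.
#' @param method method tag recorded in the result.
#' @return A [signal_set()].
#' @export
positive_signals <- function(coefficients, labels, method = "lasso") {
  if (length(coefficients) != length(labels))
    stop("coefficients and labels must align")
  keep <- which(coefficients > 0)
  signal_set(method, labels[keep], coefficients[keep], labels)
}
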