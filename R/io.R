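#' Read a report matrix and outcome from disk
#'
#' Two plain-text layouts are supported. `"mtx"`: a MatrixMarket file for the
#' exposure matrix plus sidecar files with one drug label per line and one 0/1
#' outcome per line. `"long"`: a tidy CSV with columns
#' `report_id,drug_id,outcome`, one row per drug mention; repeated mentions of
#' a drug on one report collapse to a single exposure, reports appear in
#' first-appearance order, and a report whose `drug_id` is empty contributes a
#' row of zeros.
#'
#' @param path for `format = "mtx"`, the `.mtx` file (labels/outcome default to
#'   `<path>.labels` / `<path>.outcome` unless given); for `"long"`, the CSV.
#' @param format `"mtx"` or `"long"`.
#' @param labels_path,outcome_path sidecar paths for the mtx layout.
#' @return list with elements `reports` (a [report_matrix()]) and `y`.
#' @export
load_reports <- function(path, format = c("long", "mtx"),
                         labels_path = NULL, outcome_path = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(labels_path)) labels_path <- paste0(path, ".labels")
    if (is.null(outcome_path)) outcome_path <- paste0(path, ".outcome")
    X <- Matrix::readMM(path)
    labels <- readLines(labels_path)
    if (length(labels) != ncol(X))
      stop("label file length does not match matrix columns")
    y <- scan(outcome_path, what = numeric(), quiet = TRUE)
    rm <- report_matrix(X, labels)
    return(list(reports = rm, y = as_outcome(y, rm$N)))
  }
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("report_id", "drug_id", "outcome")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns report_id, drug_id, outcome")
  rep_ids <- unique(df$report_id)
  out_by_rep <- tapply(df$outcome, df$report_id, function(v) unique(v))
  if (any(lengths(out_by_rep) != 1))
    stop("conflicting outcome values within a report")
  y <- as_outcome(suppressWarnings(as.numeric(unlist(out_by_rep[rep_ids]))))
  has_drug <- !is.na(df$drug_id) & nzchar(df$drug_id)
  drugs <- sort(unique(df$drug_id[has_drug]))
  if (!length(drugs)) stop("no drug exposures in file")
  i <- match(df$report_id[has_drug], rep_ids)
  j <- match(df$drug_id[has_drug], drugs)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(rep_ids), length(drugs)),
                            use.last.ij = TRUE)
  rm <- report_matrix(X, drugs)
  list(reports = rm, y = y)
}

#' Write a report matrix and outcome to disk
#'
#' Inverse of [load_reports()]; both layouts round-trip exactly.
#'
#' @param reports a [report_matrix()].
#' @param y binary outcome vector.
#' @param path destination (`.mtx` file or CSV, per `format`).
#' @param format `"mtx"` or `"long"`.
#' @param labels_path,outcome_path sidecar paths for the mtx layout.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, y, path, format = c("long", "mtx"),
                          labels_path = NULL, outcome_path = NULL) {
  format <- match.arg(format)
  reports <- as_report_matrix(reports)
  y <- as_outcome(y, reports$N)
  if (format == "mtx") {
    if (is.null(labels_path)) labels_path <- paste0(path, ".labels")
    if (is.null(outcome_path)) outcome_path <- paste0(path, ".outcome")
    Matrix::writeMM(reports$X, path)
    writeLines(reports$drug_labels, labels_path)
    writeLines(as.character(y), outcome_path)
    return(invisible(path))
  }
  Xt <- methods::as(reports$X, "TsparseMatrix")
  ord <- order(Xt@i, Xt@j)
  i <- Xt@i[ord] + 1L
  df <- data.frame(report_id = paste0("r", i),
                   drug_id = reports$drug_labels[Xt@j[ord] + 1L],
                   outcome = y[i])
  empty <- setdiff(seq_len(reports$N), i)
  if (length(empty))
    df <- rbind(df, data.frame(report_id = paste0("r", empty),
                               drug_id = "", outcome = y[empty]))
  df <- df[order(as.integer(sub("^r", "", df$report_id))), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference signal set
#'
#' @param path CSV with header `drug_id,status`; `status` must be one of
#'   `positive`, `negative`, `unknown`.
#' @return named character vector mapping drug label to status.
#' @export
load_reference_set <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("drug_id", "status") %in% names(df)))
    stop("reference CSV must have columns drug_id, status")
  if (!all(df$status %in% c("positive", "negative", "unknown")))
    stop("status must be positive, negative or unknown")
  stats::setNames(df$status, df$drug_id)
}
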