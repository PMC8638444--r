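## FDR/sensitivity scoring against a planted truth or a reference signal
## set, plus the replication harness that runs several detectors on
## identical simulated data.

#' Confusion counts for a signal set
#'
#' Simulation mode (`truth` a vector of true-predictor indices or labels):
#' every non-truth drug counts as negative. Reference mode (`truth` a named
#' status vector with values `positive`/`negative`/`unknown`): drugs of
#' unknown status are excluded from all counts except `n_signals`.
#'
#' @param signals a [signal_set()].
#' @param truth planted-predictor indices/labels, or a named status map.
#' @return list with `TP`, `FP`, `FN`, `TN`, `n_signals`,
#'   `n_signals_known` and `unknown_declared`.
#' @export
confusion_counts <- function(signals, truth) {
  stopifnot(inherits(signals, "signal_set"))
  labels <- signals$drug_labels
  declared <- signals$declared
  if (!is.null(names(truth)) && all(truth %in% c("positive", "negative", "unknown"))) {
    if (!all(names(truth) %in% labels)) stop("reference drugs not in drug labels")
    status <- stats::setNames(rep("unknown", length(labels)), labels)
    status[names(truth)] <- truth
  } else {
    if (is.numeric(truth)) truth <- labels[truth]
    if (!all(truth %in% labels)) stop("truth drugs not in drug labels")
    status <- stats::setNames(ifelse(labels %in% truth, "positive", "negative"),
                              labels)
  }
  dec <- labels %in% declared
  TP <- sum(dec & status == "positive")
  FP <- sum(dec & status == "negative")
  list(TP = TP, FP = FP,
       FN = sum(!dec & status == "positive"),
       TN = sum(!dec & status == "negative"),
       n_signals = length(declared),
       n_signals_known = TP + FP,
       unknown_declared = sum(dec & status == "unknown"))
}

#' FDR, sensitivity and specificity
#'
#' `FDR = FP / n_signals_known`, with the 0/0 case set to 0 so that
#' replications where a conservative method declares nothing average
#' cleanly. Sensitivity is `TP / n_TP` (NA when no true predictors exist);
#' specificity is `TN / (TN + FP)`.
#'
#' @param conf output of [confusion_counts()].
#' @param n_TP number of true positives in the truth (defaults to TP + FN).
#' @return list with `FDR`, `sensitivity`, `specificity`.
#' @export
signal_metrics <- function(conf, n_TP = NULL) {
  if (is.null(n_TP)) n_TP <- conf$TP + conf$FN
  list(FDR = if (conf$n_signals_known == 0) 0 else conf$FP / conf$n_signals_known,
       sensitivity = if (n_TP == 0) NA_real_ else conf$TP / n_TP,
       specificity = if (conf$TN + conf$FP == 0) NA_real_
                     else conf$TN / (conf$TN + conf$FP))
}

#' Replication harness across scenarios and methods
#'
#' For each scenario and replication, simulates one data set and runs every
#' requested method on the *same* data, then scores each declared set
#' against the planted truth. Per-task seeds are pre-drawn from the master
#' seed, so results are deterministic and independent of execution order.
#' When both `adapt-bic` and `lasso-bic` are run, the harness also checks
#' that every adapt-bic signal lies inside the lasso-bic selected support
#' (a structural property of the two-stage construction) and records the
#' outcome in `subset_ok`.
#'
#' @param scenarios scenario numbers (rows of [scenario_grid()]).
#' @param methods character vector of [detection_methods()] tags.
#' @param reps replications per scenario.
#' @param seed master seed.
#' @param N,P,model simulation size and exposure model.
#' @param ... further arguments passed to [detect_signals()].
#' @return list with `per_rep` (one row per scenario x rep x method) and
#'   `aggregate` (mean and sample SD of each metric per scenario x method).
#' @export
run_replications <- function(scenarios, methods, reps, seed = 1,
                             N = 1e5, P = 500, model = exposure_model(),
                             ...) {
  grid <- scenario_grid()
  tasks <- expand.grid(scenario = scenarios, rep = seq_len(reps))
  task_seeds <- with_seed(seed,
                          sample.int(.Machine$integer.max - 1, nrow(tasks)))
  rows <- list()
  for (t in seq_len(nrow(tasks))) {
    sc <- tasks$scenario[t]
    sim <- simulate_scenario(grid[sc, ], N = N, P = P, model = model,
                             seed = task_seeds[t])
    results <- list()
    for (m in methods) {
      results[[m]] <- tryCatch(
        detect_signals(sim$reports, sim$y, m,
                       seed = derive_seed(task_seeds[t], match(m, methods)),
                       ...),
        error = function(e) e)
    }
    subset_ok <- NA
    if (all(c("adapt-bic", "lasso-bic") %in% methods) &&
        inherits(results[["adapt-bic"]], "signal_set") &&
        inherits(results[["lasso-bic"]], "signal_set")) {
      lb_support <- attr(results[["lasso-bic"]], "selection")$support
      subset_ok <- all(match(results[["adapt-bic"]]$declared,
                             sim$reports$drug_labels) %in% lb_support)
    }
    for (m in methods) {
      r <- results[[m]]
      if (!inherits(r, "signal_set")) {
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sc, rep = tasks$rep[t], method = m, n_signals = NA,
          TP = NA, FP = NA, FDR = NA, sensitivity = NA, subset_ok = subset_ok,
          error = conditionMessage(r))
        next
      }
      conf <- confusion_counts(r, sim$truth)
      met <- signal_metrics(conf, n_TP = length(sim$truth))
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc, rep = tasks$rep[t], method = m,
        n_signals = conf$n_signals, TP = conf$TP, FP = conf$FP,
        FDR = met$FDR, sensitivity = met$sensitivity,
        subset_ok = subset_ok, error = NA_character_)
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep,
                                     list(per_rep$scenario, per_rep$method),
                                     drop = TRUE), function(d)
    data.frame(scenario = d$scenario[1], method = d$method[1],
               reps = nrow(d),
               mean_n_signals = mean(d$n_signals, na.rm = TRUE),
               mean_FDR = mean(d$FDR, na.rm = TRUE),
               sd_FDR = stats::sd(d$FDR, na.rm = TRUE),
               mean_sensitivity = mean(d$sensitivity, na.rm = TRUE),
               sd_sensitivity = stats::sd(d$sensitivity, na.rm = TRUE))))
  rownames(agg) <- NULL
  list(per_rep = per_rep, aggregate = agg)
}
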