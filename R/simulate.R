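## Synthetic spontaneous-report data: a sparse binary exposure matrix with
## heavy-tailed drug reporting frequencies, frequency-class assignment of
## planted true predictors, and logistic outcome generation over a 27-cell
## scenario grid (3 intercepts x {no predictors} + {5,20} predictors x
## {1,2} effect x {frequent, rare} class).

#' Exposure-model specification
#'
#' Generative model for the exposure matrix. Each report draws
#' `k ~ 1 + Poisson(mean_extra_drugs)` drug mentions with replacement from a
#' heavy-tailed drug weight law (log-uniform over `weight_range`), and
#' duplicate mentions collapse (the matrix is binary). The implied marginal
#' inclusion probability of drug j is then exactly
#' `1 - (1 - q_j) * exp(-mean_extra_drugs * q_j)` with `q_j = w_j / sum(w)`
#' (see [implied_marginals()]). An optional cluster structure tilts each
#' report's weights toward one drug cluster to induce co-reporting
#' correlation; `cluster_odds = 1` is independence.
#'
#' @param weight_range range of the log-uniform drug weight law. The default
#'   `c(2e-4, 0.05)` keeps every drug's implied marginal above 11 per 100 000
#'   at P = 500 while populating both the frequent (>= 100/100 000) and rare
#'   (20-100/100 000) reporting classes.
#' @param mean_extra_drugs Poisson mean of drug mentions beyond the first
#'   (default 1.5, i.e. 2.5 mentions per report on average).
#' @param n_clusters number of drug clusters (0 disables clustering).
#' @param cluster_odds within-cluster weight multiplier (1 = independence).
#' @return An object of class `exposure_model`.
#' @export
exposure_model <- function(weight_range = c(2e-4, 0.05),
                           mean_extra_drugs = 1.5,
                           n_clusters = 0, cluster_odds = 1) {
  stopifnot(length(weight_range) == 2, all(weight_range > 0),
            weight_range[1] < weight_range[2],
            mean_extra_drugs > 0, cluster_odds >= 1, n_clusters >= 0)
  structure(list(weight_range = weight_range,
                 mean_extra_drugs = mean_extra_drugs,
                 n_clusters = n_clusters, cluster_odds = cluster_odds),
            class = "exposure_model")
}

#' Implied marginal exposure probabilities
#'
#' Exact per-report inclusion probability of each drug under the
#' with-replacement, deduplicated mention model of [exposure_model()].
#'
#' @param weights drug sampling weights.
#' @param mean_extra_drugs Poisson mean of extra mentions.
#' @return numeric vector of inclusion probabilities.
#' @export
implied_marginals <- function(weights, mean_extra_drugs = 1.5) {
  q <- weights / sum(weights)
  1 - (1 - q) * exp(-mean_extra_drugs * q)
}

#' Sample a synthetic exposure matrix
#'
#' Draws drug weights from the model's law, then per-report mentions as
#' described in [exposure_model()]. The drawn weights and implied marginals
#' are attached as attributes.
#'
#' @param model an [exposure_model()].
#' @param N number of reports.
#' @param P number of drugs.
#' @param seed RNG seed.
#' @return A [report_matrix()] with attributes `weights` and `marginals`.
#' @export
sample_exposure <- function(model = exposure_model(), N, P, seed = NULL) {
  stopifnot(inherits(model, "exposure_model"))
  with_seed(seed, {
    w <- exp(stats::runif(P, log(model$weight_range[1]),
                          log(model$weight_range[2])))
    k <- 1L + stats::rpois(N, model$mean_extra_drugs)
    k <- pmin(k, P)
    rows <- rep.int(seq_len(N), k)
    cl <- NULL
    if (model$n_clusters > 0)
      cl <- rep_len(seq_len(model$n_clusters), P)[sample.int(P)]
    if (model$n_clusters > 0 && model$cluster_odds > 1) {
      wsum <- tapply(w, cl, sum)
      rep_cl <- sample.int(model$n_clusters, N, replace = TRUE,
                           prob = as.numeric(wsum))
      cols <- integer(sum(k))
      for (cc in seq_len(model$n_clusters)) {
        wc <- w * ifelse(cl == cc, model$cluster_odds, 1)
        sel <- rep_cl[rows] == cc
        cols[sel] <- sample.int(P, sum(sel), replace = TRUE, prob = wc)
      }
    } else {
      cols <- sample.int(P, sum(k), replace = TRUE, prob = w)
    }
    X <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(N, P),
                              use.last.ij = TRUE)
    rm <- report_matrix(X, sprintf("d%03d", seq_len(P)))
    attr(rm, "weights") <- w
    attr(rm, "marginals") <- implied_marginals(w, model$mean_extra_drugs)
    attr(rm, "clusters") <- cl
    rm
  })
}

## Reporting-frequency class of each drug from realized column counts.
## Thresholds are rates per report (100/100 000 and 20/100 000) scaled by N;
## a count exactly at the frequent boundary goes to "frequent".
frequency_class <- function(counts, N) {
  hi <- 100 / 1e5 * N
  lo <- 20 / 1e5 * N
  ifelse(counts >= hi, "frequent", ifelse(counts >= lo, "rare", "neither"))
}

#' Plant true predictors in a frequency class
#'
#' Draws `n_TP` drugs uniformly without replacement among those whose
#' realized report count falls in the requested class (frequent: at least
#' 100 per 100 000 reports; rare: 20 to 100 per 100 000, the boundary
#' count going to frequent), and builds the coefficient vector.
#'
#' @param X a [report_matrix()].
#' @param n_TP number of true predictors (0 allowed with `tp_class="none"`).
#' @param tp_class `"frequent"`, `"rare"` or `"none"`.
#' @param beta_TP common log-odds-ratio of the true predictors.
#' @param seed RNG seed.
#' @return list with `idx` (chosen column indices) and `beta` (length-P).
#' @export
choose_true_predictors <- function(X, n_TP, tp_class = c("none", "frequent", "rare"),
                                   beta_TP = 1, seed = NULL) {
  tp_class <- match.arg(tp_class)
  rm <- as_report_matrix(X)
  beta <- numeric(rm$P)
  if (n_TP == 0 || tp_class == "none") {
    if (n_TP != 0 || tp_class != "none")
      stop("n_TP = 0 requires tp_class = 'none' and vice versa")
    return(list(idx = integer(0), beta = beta))
  }
  cls <- frequency_class(Matrix::colSums(rm$X), rm$N)
  pool <- which(cls == tp_class)
  if (length(pool) < n_TP)
    stop(sprintf("only %d drugs in class '%s', need %d",
                 length(pool), tp_class, n_TP))
  idx <- with_seed(seed, sort(pool[sample.int(length(pool), n_TP)]))
  beta[idx] <- beta_TP
  list(idx = idx, beta = beta)
}

#' Simulate the adverse-event outcome
#'
#' Independent Bernoulli draws from the logistic model
#' `P(y=1|x) = plogis(beta0 + x' beta)`.
#'
#' @param X a [report_matrix()].
#' @param beta0 intercept (controls outcome scarcity).
#' @param beta length-P coefficient vector (default all zero).
#' @param seed RNG seed.
#' @return integer 0/1 vector of length N.
#' @export
simulate_outcome <- function(X, beta0, beta = NULL, seed = NULL) {
  rm <- as_report_matrix(X)
  eta <- rep(beta0, rm$N)
  if (!is.null(beta) && any(beta != 0))
    eta <- eta + as.numeric(rm$X %*% beta)
  with_seed(seed, as.integer(stats::rbinom(rm$N, 1, stats::plogis(eta))))
}

#' The 27-scenario simulation grid
#'
#' Scenarios 1-3: no true predictors, intercepts -2, -4, -6. Scenarios 4-15:
#' frequently reported true predictors, looping (n_TP, beta_TP) in
#' (5,1), (5,2), (20,1), (20,2) within each intercept. Scenarios 16-27: the
#' same with rarely reported true predictors.
#'
#' @return data.frame with columns `scenario`, `beta0`, `n_TP`, `beta_TP`,
#'   `tp_class`.
#' @export
scenario_grid <- function() {
  g0 <- data.frame(beta0 = c(-2, -4, -6), n_TP = 0, beta_TP = NA_real_,
                   tp_class = "none")
  block <- function(cls) {
    cells <- expand.grid(beta_TP = c(1, 2), n_TP = c(5, 20))
    cells <- cells[order(cells$n_TP, cells$beta_TP), ]
    out <- do.call(rbind, lapply(c(-2, -4, -6), function(b0)
      data.frame(beta0 = b0, n_TP = cells$n_TP, beta_TP = cells$beta_TP,
                 tp_class = cls)))
    out
  }
  g <- rbind(g0, block("frequent"), block("rare"))
  g <- cbind(scenario = seq_len(nrow(g)), g)
  rownames(g) <- NULL
  g
}

#' Simulate one replication of a scenario
#'
#' Draws a fresh exposure matrix, plants the scenario's true predictors by
#' realized reporting frequency, and simulates the outcome. Matrix, predictor
#' set and outcome are all regenerated per replication.
#'
#' @param scenario a scenario number (row of [scenario_grid()]) or a
#'   one-row data.frame with the same columns.
#' @param N,P problem size (defaults 1e5 and 500).
#' @param model an [exposure_model()].
#' @param seed RNG seed for the replication.
#' @return list with `reports`, `y`, `truth` (true-predictor indices),
#'   `beta`, and the scenario row.
#' @export
simulate_scenario <- function(scenario, N = 1e5, P = 500,
                              model = exposure_model(), seed = NULL) {
  if (is.numeric(scenario)) scenario <- scenario_grid()[scenario, ]
  rm <- sample_exposure(model, N, P, seed = derive_seed(seed, 1L))
  tp <- choose_true_predictors(rm, scenario$n_TP,
                               as.character(scenario$tp_class),
                               beta_TP = if (is.na(scenario$beta_TP)) 1
                                         else scenario$beta_TP,
                               seed = derive_seed(seed, 2L))
  y <- simulate_outcome(rm, scenario$beta0, tp$beta,
                        seed = derive_seed(seed, 3L))
  list(reports = rm, y = y, truth = tp$idx, beta = tp$beta,
       scenario = scenario)
}
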