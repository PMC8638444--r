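## Independent oracles used to check the package's fitting and testing code.
## They deliberately share no code with the implementation under test.

## Proximal-gradient (FISTA) solver for the weighted logistic lasso,
##   min over (b0, b) of (1/N) sum log(1 + exp(eta)) - y * eta
##                      + lambda * sum_p w_p |b_p|,
## run to tight tolerance on small dense problems.
prox_lasso_oracle <- function(X, y, lambda, w = rep(1, ncol(X)),
                              maxit = 200000, tol = 1e-12) {
  X <- as.matrix(X)
  N <- nrow(X)
  P <- ncol(X)
  keep <- is.finite(w)
  b0 <- 0
  b <- numeric(P)
  L <- 0.25 * (norm(cbind(1, X), "2")^2) / N  # Lipschitz bound of the gradient
  z0 <- b0; z <- b; tk <- 1
  obj <- function(b0, b) {
    eta <- b0 + X %*% b
    mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      lambda * sum(w[keep] * abs(b[keep]))
  }
  last <- obj(b0, b)
  for (it in seq_len(maxit)) {
    eta <- z0 + X %*% z
    mu <- 1 / (1 + exp(-eta))
    g <- crossprod(X, mu - y) / N
    g0 <- mean(mu - y)
    b0_new <- z0 - g0 / L
    u <- z - g / L
    thr <- lambda * w / L
    b_new <- sign(u) * pmax(abs(u) - thr, 0)
    b_new[!keep] <- 0
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z0 <- b0_new + (tk - 1) / tk_new * (b0_new - b0)
    z <- b_new + (tk - 1) / tk_new * (b_new - b)
    b0 <- b0_new; b <- b_new; tk <- tk_new
    if (it %% 200 == 0) {
      cur <- obj(b0, b)
      if (abs(last - cur) < tol * (abs(last) + 1)) break
      last <- cur
    }
  }
  ## polish: with the active set and signs fixed, the objective is smooth;
  ## solve the stationarity system by Newton to machine precision
  act <- which(b != 0)
  s <- sign(b[act])
  for (it in 1:40) {
    eta <- b0 + X[, act, drop = FALSE] %*% b[act]
    mu <- 1 / (1 + exp(-eta))
    wt <- as.numeric(mu * (1 - mu))
    Xa <- cbind(1, X[, act, drop = FALSE])
    g <- as.numeric(crossprod(Xa, mu - y)) / N + lambda * c(0, w[act] * s)
    H <- crossprod(Xa * wt, Xa) / N
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    b0 <- b0 - step[1]
    b[act] <- b[act] - step[-1]
    if (max(abs(step)) < 1e-14) break
  }
  list(intercept = b0, coef = as.numeric(b))
}

## Unpenalized logistic MLE via a generic quasi-Newton optimizer.
newton_mle_oracle <- function(X, y) {
  X <- as.matrix(X)
  Xd <- cbind(1, X)
  nll <- function(b) {
    eta <- Xd %*% b
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
  }
  gr <- function(b) as.numeric(crossprod(Xd, 1 / (1 + exp(-Xd %*% b)) - y))
  fit <- stats::optim(numeric(ncol(Xd)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  list(intercept = fit$par[1], coef = fit$par[-1],
       loglik = -fit$value)
}

## Benjamini-Yekutieli step-up applied from its threshold definition.
by_stepup_oracle <- function(p, q) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / (m * cm))
  declared <- logical(m)
  if (length(ok)) declared[ord[seq_len(max(ok))]] <- TRUE
  declared
}

## One-sided Fisher p-value by explicit hypergeometric summation.
fisher_tail_oracle <- function(a, b, c, d) {
  m <- a + b; k <- a + c; N <- a + b + c + d
  hi <- min(m, k)
  if (m == 0 || k == 0 || m == N || k == N) return(1)
  sum(vapply(a:hi, function(x)
    choose(m, x) * choose(N - m, k - x), 0)) / choose(N, k)
}

## Sparse binary toy design with independent Bernoulli exposures.
toy_reports <- function(N, P, freq = 0.2, seed = 1) {
  withr::with_seed(seed, {
    X <- Matrix::Matrix(matrix(rbinom(N * P, 1, freq), N, P), sparse = TRUE)
    report_matrix(X, sprintf("t%02d", seq_len(P)))
  })
}

## Logistic outcome for a toy design.
toy_outcome <- function(rm, beta0, beta = NULL, seed = 1) {
  eta <- rep(beta0, rm$N)
  if (!is.null(beta)) eta <- eta + as.numeric(rm$X %*% beta)
  withr::with_seed(seed + 1000, rbinom(rm$N, 1, plogis(eta)))
}
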