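test_that("lambda_max matches its closed form and scales with weights", {
  X <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(4, 1))
  y <- c(1, 1, 0, 0)
  expect_equal(lambda_max(X, y), abs(1 - 0.5) / 4)  # = 0.125

  rm <- toy_reports(60, 6, seed = 11)
  yy <- toy_outcome(rm, -0.5, seed = 11)
  w <- rep(1, 6)
  l1 <- lambda_max(rm, yy, w)
  w[3] <- 2  # doubling one weight halves that drug's contribution
  g <- abs(as.numeric(Matrix::crossprod(rm$X, yy - mean(yy)))) / rm$N
  expect_equal(lambda_max(rm, yy, w), max(g / w))
  expect_lte(lambda_max(rm, yy, w), l1)

  expect_error(lambda_max(rm, rep(1, 60)), "constant")
  expect_error(lambda_max(rm, yy, rep(Inf, 6)), "infinite")
})

test_that("the path is empty above lambda_max and non-empty just below", {
  withr::with_seed(21, {
    X <- Matrix::Matrix(matrix(rbinom(500, 1, 0.3), 50, 10), sparse = TRUE)
    y <- rbinom(50, 1, plogis(-1 + X[, 2]))
  })
  lm <- lambda_max(X, y)
  p <- fit_lasso_path(X, y, lambdas = c(1.01, 0.99, 0.5) * lm)
  expect_equal(p$df[1], 0L)
  expect_gte(p$df[2], 1L)

  g <- lambda_grid(X, y, n_lambda = 40, ratio = 1e-2)
  expect_equal(g[1], lm)
  expect_equal(g[40], 0.01 * lm)
  expect_true(all(diff(log(g)) < 0))
  expect_equal(diff(range(diff(log(g)))), 0, tolerance = 1e-10)
})

test_that("path coefficients agree with a proximal-gradient oracle", {
  # 5x2 dense toy, one lambda
  X5 <- Matrix::Matrix(matrix(c(1, 0, 1, 0, 1,
                                0, 1, 1, 0, 0), 5, 2), sparse = TRUE)
  y5 <- c(1, 0, 1, 0, 1)
  lam <- 0.05
  p <- fit_lasso_path(X5, y5, lambdas = c(0.2, lam), thresh = 1e-12)
  o <- prox_lasso_oracle(as.matrix(X5), y5, lam)
  expect_equal(as.numeric(p$beta[, 2]), o$coef, tolerance = 1e-6)
  expect_equal(p$a0[2], o$intercept, tolerance = 1e-6)

  # weighted 50x10 instance at several lambdas
  withr::with_seed(31, {
    X <- Matrix::Matrix(matrix(rbinom(500, 1, 0.4), 50, 10), sparse = TRUE)
    y <- rbinom(50, 1, plogis(-0.5 + 1.5 * X[, 1] - X[, 4]))
  })
  w <- c(0.5, 1, 2, 1, 1, 3, 1, 1, 0.7, 1)
  lm <- lambda_max(X, y, w)
  lams <- lm * c(1, 0.5, 0.2, 0.08)
  p <- fit_lasso_path(X, y, w, lambdas = lams, thresh = 1e-12)
  for (j in 2:4) {
    o <- prox_lasso_oracle(as.matrix(X), y, lams[j], w)
    expect_equal(as.numeric(p$beta[, j]), o$coef, tolerance = 1e-6)
  }
})

test_that("weighted fit equals column-rescaled unweighted fit", {
  withr::with_seed(32, {
    X <- Matrix::Matrix(matrix(rbinom(500, 1, 0.3), 50, 10), sparse = TRUE)
    y <- rbinom(50, 1, plogis(-0.5 + 2 * X[, 2]))
  })
  w <- c(2, 1, 0.5, 1, 1.5, 1, 1, 3, 1, 1)
  lam <- 0.3 * lambda_max(X, y, w)
  lams <- c(3 * lam, lam)
  pw <- fit_lasso_path(X, y, w, lambdas = lams)
  pu <- fit_lasso_path(X %*% Matrix::Diagonal(x = 1 / w), y, lambdas = lams)
  expect_equal(as.numeric(pw$beta[, 2]), as.numeric(pu$beta[, 2]) / w,
               tolerance = 1e-8)
})

test_that("KKT conditions hold along the path; excluded drugs never enter", {
  withr::with_seed(33, {
    X <- Matrix::Matrix(matrix(rbinom(1200, 1, 0.25), 80, 15), sparse = TRUE)
    y <- rbinom(80, 1, plogis(-1 + 2 * X[, 3] - X[, 7]))
  })
  w <- rep(1, 15); w[5] <- Inf; w[9] <- 2
  p <- fit_lasso_path(X, y, w, n_lambda = 25, ratio = 0.05)
  expect_true(all(p$beta[5, ] == 0))
  N <- nrow(X)
  for (j in seq_along(p$lambda)) {
    b <- as.numeric(p$beta[, j])
    mu <- plogis(p$a0[j] + as.numeric(X %*% b))
    grad <- as.numeric(Matrix::crossprod(X, y - mu)) / N
    act <- which(b != 0)
    inact <- setdiff(which(is.finite(w)), act)
    if (length(act))
      expect_lt(max(abs(grad[act] - p$lambda[j] * w[act] * sign(b[act]))), 1e-4)
    if (length(inact))
      expect_lt(max(abs(grad[inact]) - p$lambda[j] * w[inact]), 1e-4)
  }
  # at very large lambda the fit is the null model
  pnull <- fit_lasso_path(X, y, lambdas = c(10, 5) * lambda_max(X, y))
  expect_equal(pnull$df, c(0L, 0L))
  expect_equal(pnull$a0[1], qlogis(mean(y)), tolerance = 1e-6)
})

test_that("cross-validation recovers a dominant predictor and handles LOO", {
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      X <- Matrix::Matrix(matrix(rbinom(2000 * 5, 1, 0.3), 2000, 5),
                          sparse = TRUE)
      y <- rbinom(2000, 1, plogis(-2 + 3 * X[, 2]))
    })
    sel <- cv_select(X, y, seed = s)
    if (2 %in% sel$support) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of seeds

  # leave-one-out on a 20x2 instance runs and returns a valid lambda
  withr::with_seed(41, {
    X <- Matrix::Matrix(matrix(rbinom(40, 1, 0.5), 20, 2), sparse = TRUE)
    y <- rbinom(20, 1, 0.5)
  })
  sel <- cv_select(X, y, n_f = 20, seed = 1)
  expect_true(sel$lambda_star > 0 && is.finite(sel$lambda_star))
})

test_that("cross-validation on pure noise stays modest (pinned regression)", {
  dfs <- integer(10)
  for (s in 1:10) {
    withr::with_seed(200 + s, {
      X <- Matrix::Matrix(matrix(rbinom(500 * 10, 1, 0.3), 500, 10),
                          sparse = TRUE)
      y <- rbinom(500, 1, 0.2)  # independent of X
    })
    dfs[s] <- length(cv_select(X, y, seed = s)$support)
  }
  # value computed once from this exact configuration and frozen
  expect_equal(median(dfs), 1.5)
  expect_lte(max(dfs), 10)
})

test_that("refit_mle matches closed forms and a generic optimizer", {
  rm <- toy_reports(250, 4, freq = 0.35, seed = 52)
  y <- toy_outcome(rm, -0.5, c(1, 0, -0.8, 0), seed = 52)
  # empty support: intercept-only closed form
  f0 <- refit_mle(rm, y, integer(0))
  pbar <- mean(y)
  expect_equal(f0$intercept, qlogis(pbar))
  expect_equal(f0$loglik, 250 * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar)))

  # 2-column toy against a BFGS oracle
  f <- refit_mle(rm, y, c(1, 3))
  o <- newton_mle_oracle(as.matrix(rm$X[, c(1, 3)]), y)
  expect_equal(unname(f$coef[c(1, 3)]), o$coef, tolerance = 1e-6)
  expect_equal(unname(f$intercept), o$intercept, tolerance = 1e-6)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)

  # zero column is dropped deterministically and flagged
  X <- cbind(rm$X, Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(), dims = c(250, 1)))
  fz <- refit_mle(X, y, c(2, 5))
  expect_equal(fz$support, 2L)
  expect_match(fz$flags, "collinear", all = FALSE)

  # duplicated column: lowest index kept
  Xd <- cbind(rm$X, rm$X[, 1])
  fd <- refit_mle(Xd, y, c(1, 5))
  expect_equal(fd$support, 1L)

  # separation: finite result with a flag
  Xs <- Matrix::sparseMatrix(i = 1:5, j = rep(1, 5), x = 1, dims = c(10, 1))
  ys <- c(rep(1, 5), rep(0, 5))
  fs <- refit_mle(Xs, ys, 1)
  expect_true(all(is.finite(fs$coef)))
  expect_match(fs$flags, "separation", all = FALSE)
})

test_that("BIC arithmetic is -2 loglik + df log N", {
  expect_equal(bic_score(-50, 2, 100), 100 + 2 * log(100))  # 109.2103...
  expect_equal(bic_score(-50, 0, 100), 100)
  expect_equal(bic_score(-50, 3, 100) - bic_score(-50, 2, 100), log(100))
  expect_error(bic_score(-50, -1, 100), "nonnegative")
})

test_that("bic_select agrees with exhaustive support enumeration", {
  withr::with_seed(61, {
    X <- Matrix::Matrix(matrix(rbinom(300 * 4, 1, 0.4), 300, 4), sparse = TRUE)
    y <- rbinom(300, 1, plogis(-1 + 1.5 * X[, 1]))
  })
  path <- fit_lasso_path(X, y, n_lambda = 30)
  sel <- bic_select(path, X, y)
  # oracle: BIC of every possible support, via glm
  all_supports <- unlist(lapply(0:4, function(k)
    combn(4, k, simplify = FALSE)), recursive = FALSE)
  bics <- vapply(all_supports, function(s) {
    if (length(s) == 0) {
      ll <- sum(dbinom(y, 1, mean(y), log = TRUE))
    } else {
      g <- glm(y ~ as.matrix(X[, s, drop = FALSE]), family = binomial())
      ll <- as.numeric(logLik(g))
    }
    -2 * ll + length(s) * log(300)
  }, 0)
  # restrict the oracle to supports actually visited by the path
  keys <- vapply(all_supports, paste, "", collapse = ",")
  path_keys <- unique(apply(as.matrix(path$beta != 0), 2,
                            function(z) paste(which(z), collapse = ",")))
  cand <- which(keys %in% path_keys)
  best <- cand[which.min(bics[cand])]
  expect_equal(sel$support, all_supports[[best]])
  expect_equal(min(sel$criterion$bic), bics[best], tolerance = 1e-6)
})

test_that("bic_select depends only on the set of distinct supports", {
  withr::with_seed(62, {
    X <- Matrix::Matrix(matrix(rbinom(400 * 6, 1, 0.3), 400, 6), sparse = TRUE)
    y <- rbinom(400, 1, plogis(-1 + 2 * X[, 5]))
  })
  p1 <- fit_lasso_path(X, y, n_lambda = 25)
  p2 <- fit_lasso_path(X, y, n_lambda = 100)  # denser parameterization
  s1 <- bic_select(p1, X, y)
  s2 <- bic_select(p2, X, y)
  k1 <- unique(apply(as.matrix(p1$beta != 0), 2, paste, collapse = ""))
  k2 <- unique(apply(as.matrix(p2$beta != 0), 2, paste, collapse = ""))
  if (setequal(k1, k2)) expect_equal(s1$support, s2$support)
  # and the winner is always among the visited supports
  expect_true(paste(s1$support, collapse = ",") %in%
                s1$criterion$support)
})

test_that("bic_select recovers a true predictor and stays empty under noise", {
  hits <- 0L; empties <- 0L
  for (s in 1:25) {
    withr::with_seed(300 + s, {
      X <- Matrix::Matrix(matrix(rbinom(2000 * 8, 1, 0.2), 2000, 8),
                          sparse = TRUE)
      y <- rbinom(2000, 1, plogis(-2 + 2 * X[, 4]))
      y0 <- rbinom(2000, 1, 0.15)
    })
    p <- fit_lasso_path(X, y)
    if (identical(bic_select(p, X, y)$support, 4L)) hits <- hits + 1L
    p0 <- fit_lasso_path(X, y0)
    if (length(bic_select(p0, X, y0)$support) == 0) empties <- empties + 1L
  }
  expect_gte(hits, 23L)     # >= 90% exact recovery
  expect_gt(empties, 12L)   # noise: empty support in the majority of runs
})

test_that("permutation selection follows the median-lambda_max rule", {
  # X with all-identical rows: lambda_max is permutation-invariant
  X <- Matrix::Matrix(matrix(rep(c(1, 0, 1), each = 12), 12, 3), sparse = TRUE)
  y <- rep(c(0, 1), 6)
  sel <- perm_select(X, y, K = 7, seed = 3)
  expect_equal(sel$lambda_star, lambda_max(X, y))
  expect_true(all(sel$criterion$lambda_max == sel$criterion$lambda_max[1]))

  # K = 1: lambda* is the single permuted lambda_max
  rm <- toy_reports(100, 6, seed = 71)
  yy <- toy_outcome(rm, -1, seed = 71)
  s1 <- perm_select(rm, yy, K = 1, seed = 9)
  expect_equal(s1$lambda_star, s1$criterion$lambda_max[1])

  # direct oracle on a fixed 200x20 instance: recompute each permuted
  # lambda_max independently and take the median
  rm2 <- toy_reports(200, 20, freq = 0.15, seed = 72)
  y2 <- toy_outcome(rm2, -0.8, seed = 72)
  K <- 20
  sel2 <- perm_select(rm2, y2, K = K, seed = 13)
  lmaxes <- withr::with_seed(13, vapply(seq_len(K), function(l) {
    yp <- sample(y2)
    max(abs(as.numeric(Matrix::crossprod(rm2$X, yp - mean(yp)))) / rm2$N)
  }, 0))
  expect_equal(sort(sel2$criterion$lambda_max), sort(lmaxes))
  expect_equal(sel2$lambda_star, median(lmaxes))  # even K: midpoint rule
  # coefficients at lambda* are the penalized fit on the original outcome
  if (sel2$lambda_star < lambda_max(rm2, y2)) {
    o <- prox_lasso_oracle(as.matrix(rm2$X), y2, sel2$lambda_star)
    expect_equal(unname(sel2$coef), o$coef, tolerance = 1e-5)
  }
})
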