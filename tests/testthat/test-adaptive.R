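test_that("adaptive weight constructors apply their reciprocal formulas", {
  rm <- toy_reports(1500, 6, freq = 0.25, seed = 91)
  y <- toy_outcome(rm, -1.5, c(2, 0, 0, -2, 0, 0), seed = 91)

  wl <- weights_lcv(rm, y, seed = 3)
  sel <- attr(wl, "first_stage")
  nz <- sel$coef != 0
  expect_equal(wl$w[nz], 1 / abs(unname(sel$coef[nz])))
  expect_true(all(is.infinite(wl$w[!nz])))
  # negative first-stage coefficients still give finite weights
  expect_true(any(sel$coef < 0) && all(is.finite(wl$w[sel$coef < 0])))
  # same seed, same weights
  expect_identical(wl$w, weights_lcv(rm, y, seed = 3)$w)

  wb <- weights_lb(rm, y)
  selb <- attr(wb, "first_stage")
  expect_true(all(is.finite(wb$w[selb$support])))
  expect_true(all(is.infinite(wb$w[-selb$support])))
  expect_equal(wb$w[selb$support],
               1 / abs(unname(selb$coef[selb$support])))
})

test_that("univariate weights equal the reciprocal log odds-ratio", {
  # 2x2 cells (a,b,c,d) = (20,80,100,800): log OR = log 2
  x <- c(rep(1, 100), rep(0, 900))
  y <- c(rep(1, 20), rep(0, 80), rep(1, 100), rep(0, 800))
  X <- Matrix::Matrix(cbind(x, x2 = c(rep(1, 500), rep(0, 500))), sparse = TRUE)
  w <- weights_univ(X, y)
  expect_equal(w$w[1], 1 / log(2), tolerance = 1e-10)

  # independent drug (OR = 1): zero coefficient mapped to the finite cap
  xo <- rep(c(1, 1, 0, 0), 25)
  yo <- rep(c(1, 0, 1, 0), 25)
  Xo <- Matrix::Matrix(cbind(xo, b = rep(0:1, 50)), sparse = TRUE)
  wo <- weights_univ(Xo, yo)
  expect_equal(wo$w[1], 1e10)

  # never-reported drug: infinite weight, flagged
  Xz <- cbind(X, z = Matrix::sparseMatrix(i = integer(), j = integer(),
                                          x = numeric(), dims = c(1000, 1)))
  wz <- weights_univ(Xz, y)
  expect_true(is.infinite(wz$w[3]))
  expect_match(attr(wz, "flags"), "never reported", all = FALSE)

  # agreement with a generic-optimizer univariate MLE on random columns
  rm <- toy_reports(800, 10, freq = 0.3, seed = 92)
  yy <- toy_outcome(rm, -1, c(1.5, rep(0, 9)), seed = 92)
  wu <- weights_univ(rm, yy)
  for (j in c(1, 4, 8)) {
    o <- newton_mle_oracle(as.matrix(rm$X[, j, drop = FALSE]), yy)
    expect_equal(unname(attr(wu, "beta_univ")[j]), o$coef, tolerance = 1e-6)
  }
})

test_that("CISL weights follow the three-branch rule", {
  tau <- rbind(c(0.1, 0, 0.1),
               c(0.2, 0, 0),
               c(0.3, 0, 0.2),
               c(0.4, 0, 0),
               c(0.5, 0, 0))
  colnames(tau) <- c("all_pos", "all_zero", "mixed")
  res <- structure(list(pi_hat = tau, tau_hat = tau, E = 10, B = 5,
                        subsample_log = NULL, drug_labels = colnames(tau)),
                   class = "cisl_result")
  w <- weights_cisl(res)
  expect_equal(unname(w$w), c(1 / 5, Inf, 1 - 2 / 5))
  # finite weights live in [1/B, 1]; mixed branch is at least 1/B
  expect_true(all(w$w[is.finite(w$w)] >= 1 / 5 - 1e-12))
  expect_true(all(w$w[is.finite(w$w)] <= 1))
})

test_that("gamma other than 1 is rejected", {
  expect_error(adaptive_weights(c(1, 2), gamma = 2), "not implemented")
})

test_that("the adaptive stage is invariant to a common weight rescaling", {
  rm <- toy_reports(1200, 8, freq = 0.25, seed = 93)
  y <- toy_outcome(rm, -1.5, c(2, 0, 0, 0, -1.5, 0, 0, 0), seed = 93)
  w1 <- rep(1, 8)
  s1 <- adaptive_fit(rm, y, w1, selector = "bic")
  s2 <- adaptive_fit(rm, y, 5 * w1, selector = "bic")
  expect_identical(s1$declared, s2$declared)
  # equal weights reproduce the plain lasso-bic support
  path <- fit_lasso_path(rm, y)
  expect_identical(sort(attr(s1, "selection")$support),
                   sort(bic_select(path, rm, y)$support))
})

test_that("weighted adaptive fit matches the column-rescaling oracle", {
  withr::with_seed(94, {
    X <- Matrix::Matrix(matrix(rbinom(50 * 10, 1, 0.35), 50, 10), sparse = TRUE)
    y <- rbinom(50, 1, plogis(-0.5 + 2 * X[, 6]))
  })
  w <- c(1, 2, 0.5, 1, 1.5, 0.8, 1, 2.5, 1, 1)
  lam <- 0.25 * lambda_max(X, y, w)
  pw <- fit_lasso_path(X, y, w, lambdas = c(4 * lam, lam), thresh = 1e-12)
  pu <- fit_lasso_path(X %*% Matrix::Diagonal(x = 1 / w), y,
                       lambdas = c(4 * lam, lam), thresh = 1e-12)
  expect_equal(as.numeric(pw$beta[, 2]),
               as.numeric(pu$beta[, 2]) / w, tolerance = 1e-8)
})

test_that("all-infinite weights give an empty signal set, not an error", {
  rm <- toy_reports(300, 5, seed = 95)
  y <- toy_outcome(rm, -1, seed = 95)
  s <- adaptive_fit(rm, y, adaptive_weights(rep(Inf, 4) |> c(1) |> rev(),
                                            source = "lb"),
                    selector = "bic")
  expect_s3_class(s, "signal_set")
  w_all_inf <- structure(list(w = rep(Inf, 5), gamma = 1, source = "lb"),
                         class = "adaptive_weights")
  s0 <- adaptive_fit(rm, y, w_all_inf, selector = "bic")
  expect_length(s0$declared, 0)
})

test_that("adapt-bic signals are contained in the lasso-bic support", {
  m <- exposure_model()
  for (s in 1:4) {
    rm <- sample_exposure(m, 6000, 60, seed = 500 + s)
    tp <- choose_true_predictors(rm, 3, "frequent", beta_TP = 2,
                                 seed = 500 + s)
    y <- simulate_outcome(rm, -2, tp$beta, seed = 500 + s)
    lb <- detect_signals(rm, y, "lasso-bic")
    ab <- detect_signals(rm, y, "adapt-bic")
    expect_true(all(match(ab$declared, rm$drug_labels) %in%
                      attr(lb, "selection")$support))
  }
})

test_that("adapt-bic recovers a single strong predictor cleanly", {
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(600 + s, {
      X <- Matrix::Matrix(matrix(rbinom(2000 * 8, 1, 0.2), 2000, 8),
                          sparse = TRUE)
      y <- rbinom(2000, 1, plogis(-2 + 2 * X[, 3]))
    })
    s2 <- adaptive_fit(X, y, weights_lb(X, y), selector = "bic")
    if (identical(s2$declared, "d3")) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # exact support, no false positives, >= 90%
})

test_that("nested cross-validation is deterministic and finds the signal", {
  rm <- toy_reports(1500, 6, freq = 0.3, seed = 96)
  y <- toy_outcome(rm, -1.5, c(2.5, 0, 0, 0, 0, 0), seed = 96)
  n1 <- nested_cv_lambda(rm, y, "univ", seed = 11)
  n2 <- nested_cv_lambda(rm, y, "univ", seed = 11)
  expect_identical(n1$lambda_star, n2$lambda_star)
  expect_true(is.finite(n1$lambda_star))
  s <- adaptive_fit(rm, y, rep(1, 6), selector = "cv",
                    weight_builder = "univ", seed = 11, method = "adapt-univ")
  expect_true("t01" %in% s$declared)
  # the validation grid is built from the full data and used as-is
  expect_equal(n1$grid[1], lambda_max(rm, y, n1$weights))
  expect_length(n1$cvm, length(n1$grid))
})
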