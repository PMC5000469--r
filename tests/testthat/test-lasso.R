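make_lasso_fixture <- function(n = 20, q = 3, seed = 1) {
  with_seed(seed, {
    R <- matrix(rbinom(n * q, 1, 0.5), n, q,
                dimnames = list(NULL, paste0("r", 1:q)))
    eta <- -1 + 1.5 * R[, 1] - 1 * R[, 2]
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    list(R = R, y = y)
  })
}

penalized_objective <- function(beta0, beta, R, y, lambda) {
  eta <- beta0 + as.numeric(R %*% beta)
  mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
    lambda * sum(abs(beta))
}

test_that("full shrinkage returns the intercept-only null model", {
  fx <- make_lasso_fixture()
  fit <- fit_sparse_logistic(fx$R, fx$y, lambda = 1e6)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(fx$y)), tolerance = 1e-6)
  expect_equal(fit$selected, character(0))
})

test_that("input validation rejects malformed problems", {
  fx <- make_lasso_fixture()
  expect_error(fit_sparse_logistic(fx$R, rep(1, 20), 0.1),
               class = "cohortrules_value_error")
  expect_error(fit_sparse_logistic(fx$R * 2, fx$y, 0.1),
               class = "cohortrules_value_error")
  expect_error(fit_sparse_logistic(fx$R, fx$y, -1),
               class = "cohortrules_value_error")
})

test_that("the coordinate-descent objective matches a generic minimizer", {
  fx <- make_lasso_fixture()
  for (lam in c(0.02, 0.08, 0.2)) {
    fit <- fit_sparse_logistic(fx$R, fx$y, lam)
    oracle <- optim(rep(0, 4),
                    function(p) penalized_objective(p[1], p[2:4], fx$R, fx$y, lam),
                    method = "Nelder-Mead",
                    control = list(maxit = 50000, reltol = 1e-14))
    expect_lt(abs(fit$objective - oracle$value), 1e-4)
    expect_lte(fit$objective, oracle$value + 1e-8)  # never worse than the oracle
  }
})

test_that("an unpenalized one-predictor fit equals the crude log odds ratio", {
  # 2x2 layout: exposed 40 (12 withdrawn), unexposed 60 (9 withdrawn)
  R <- matrix(rep(c(1L, 0L), c(40, 60)), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(rep(1L, 12), rep(0L, 28), rep(1L, 9), rep(0L, 51))
  fit <- fit_sparse_logistic(R, y, lambda = 0)
  closed <- log((12 * 51) / (28 * 9))
  expect_equal(unname(fit$beta), closed, tolerance = 1e-6)
  expect_equal(fit$intercept, qlogis(9 / 60), tolerance = 1e-6)
  or <- crude_odds_ratio(contingency_cell("e", 28, 12),
                         contingency_cell("u", 51, 9))
  expect_equal(unname(fit$beta), or$log_or, tolerance = 1e-6)
})

test_that("KKT conditions hold along a twenty-point penalty path", {
  fx <- make_lasso_fixture(n = 200, q = 8, seed = 3)
  grid <- cohortrules:::default_lambda_grid(fx$R, fx$y, 20, 0.01)
  for (lam in grid) {
    fit <- fit_sparse_logistic(fx$R, fx$y, lam, tol = 1e-7)
    kk <- kkt_conditions(fit, fx$R, fx$y, tol = 1e-6)
    expect_true(all(kk$ok))
  }
})

test_that("lambda_max is the exact edge of the empty model", {
  fx <- make_lasso_fixture(n = 300, q = 5, seed = 4)
  lmax <- lambda_max(fx$R, fx$y)
  at <- fit_sparse_logistic(fx$R, fx$y, lmax)
  expect_true(all(at$beta == 0))
  below <- fit_sparse_logistic(fx$R, fx$y, 0.9 * lmax)
  expect_gt(sum(below$beta != 0), 0)
})

test_that("warm-started path solutions match cold restarts", {
  fx <- make_lasso_fixture(n = 150, q = 6, seed = 5)
  grid <- cohortrules:::default_lambda_grid(fx$R, fx$y, 10, 0.05)
  path <- fit_sparse_logistic(fx$R, fx$y, grid, tol = 1e-7)
  for (i in c(3, 6, 10)) {
    cold <- fit_sparse_logistic(fx$R, fx$y, grid[i], tol = 1e-7)
    expect_lt(abs(path$objective[i] - cold$objective), 1e-6)
  }
})

test_that("permuting rule columns permutes the coefficients identically", {
  fx <- make_lasso_fixture(n = 120, q = 5, seed = 6)
  colnames(fx$R) <- paste0("r", 1:5)
  perm <- c(4, 2, 5, 1, 3)
  f1 <- fit_sparse_logistic(fx$R, fx$y, 0.03, tol = 1e-7)
  f2 <- fit_sparse_logistic(fx$R[, perm], fx$y, 0.03, tol = 1e-7)
  expect_equal(f2$beta[names(f1$beta)], f1$beta, tolerance = 1e-6)
})

test_that("the solver agrees with an established penalized-regression package", {
  skip_if_not_installed("glmnet")
  fx <- make_lasso_fixture(n = 400, q = 10, seed = 7)
  lam <- 0.03
  fit <- fit_sparse_logistic(fx$R, fx$y, lam, tol = 1e-7)
  g <- glmnet::glmnet(fx$R, fx$y, family = "binomial", lambda = lam,
                      standardize = FALSE, thresh = 1e-12)
  gb <- as.numeric(g$beta)
  obj_g <- penalized_objective(g$a0, gb, fx$R, fx$y, lam)
  expect_lt(abs(fit$objective - obj_g), 1e-5)
  expect_equal(unname(fit$beta), gb, tolerance = 1e-3)
})

test_that("cross-validation runs at boundary fold counts and validates folds", {
  fx <- make_lasso_fixture(n = 10, q = 2, seed = 8)
  fx$y <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  cv <- select_lambda_cv(fx$R, fx$y, k = 10, nlambda = 8)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$table), 8)
  expect_true(cv$lambda_star %in% cv$table$lambda)
  expect_true(all(diff(cv$table$lambda) < 0))

  expect_error(select_lambda_cv(fx$R, fx$y, k = 1), class = "cohortrules_value_error")
  expect_error(select_lambda_cv(fx$R, fx$y, k = 11), class = "cohortrules_value_error")
  expect_error(select_lambda_cv(fx$R, c(1L, rep(0L, 9)), k = 5),
               class = "cohortrules_value_error")
})

test_that("cross-validation finds a strongly planted rule", {
  with_seed(99, {
    n <- 5000
    R <- matrix(rbinom(n * 5, 1, 0.3), n, 5,
                dimnames = list(NULL, paste0("r", 1:5)))
    y <- rbinom(n, 1, plogis(qlogis(0.2) + 1.0 * R[, 3]))
  })
  cv <- select_lambda_cv(R, y, k = 5, seed = 2)
  fit <- fit_sparse_logistic(R, y, cv$lambda_star, tol = 1e-7)
  expect_true("r3" %in% fit$selected)
})
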