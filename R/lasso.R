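#' Sparse (L1-penalized) logistic regression over rule indicators
#'
#' Minimizes `(1/n) * sum_i [log(1 + exp(eta_i)) - y_i * eta_i] +
#' lambda * ||beta||_1` with an unpenalized intercept, by iteratively
#' reweighted least squares with cyclic coordinate descent (active-set
#' updates verified by full sweeps). This is the rule-pruning model: the
#' predictors are the 0/1 rule-endorsement indicators and the outcome is
#' withdrawal status.
#'
#' @param R n-by-q binary (0/1) rule-indicator matrix.
#' @param y 0/1 outcome vector with both classes present.
#' @param lambda Penalty parameter(s) >= 0; a decreasing vector is solved as
#'   a warm-started path.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_sweeps Cap on total coordinate sweeps per penalty value.
#' @return For a single `lambda`: a `penalized_fit` with elements `beta`
#'   (named), `intercept`, `lambda`, `objective`, `selected` (names of
#'   nonzero coefficients). For a vector: a `penalized_path` with matrix
#'   `beta` (q x L).
#' @export
fit_sparse_logistic <- function(R, y, lambda, tol = 1e-7, max_sweeps = 1e5) {
  R <- as.matrix(R)
  if (length(y) != nrow(R)) {
    abort("length(y) must equal nrow(R)", class = "cohortrules_value_error")
  }
  if (!all(y %in% c(0, 1))) {
    abort("y must be binary 0/1", class = "cohortrules_value_error")
  }
  if (length(unique(y)) < 2) {
    abort("degenerate fit: outcome has a single class", class = "cohortrules_value_error")
  }
  if (!all(R %in% c(0, 1))) {
    abort("rule-indicator matrix must be binary 0/1", class = "cohortrules_value_error")
  }
  if (any(lambda < 0)) {
    abort("lambda must be >= 0", class = "cohortrules_value_error")
  }
  storage.mode(R) <- "integer"
  terms <- colnames(R) %||% paste0("rule_", seq_len(ncol(R)))
  res <- .lasso_logistic_path_cpp(R, as.numeric(y), as.numeric(lambda),
                                  tol, as.integer(max_sweeps))
  if (length(lambda) == 1) {
    beta <- setNames(res$beta[, 1], terms)
    structure(list(beta = beta, intercept = res$intercept[1],
                   lambda = lambda, objective = res$objective[1],
                   selected = terms[beta != 0], sweeps = res$sweeps[1],
                   n = nrow(R)),
              class = "penalized_fit")
  } else {
    rownames(res$beta) <- terms
    structure(list(beta = res$beta, intercept = res$intercept,
                   lambda = as.numeric(lambda), objective = res$objective,
                   sweeps = res$sweeps, n = nrow(R)),
              class = "penalized_path")
  }
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("<penalized_fit> lambda = ", format(x$lambda), ", ",
      length(x$selected), "/", length(x$beta), " rules selected, objective = ",
      sprintf("%.6f", x$objective), "\n", sep = "")
  invisible(x)
}

#' @method tidy penalized_fit
#' @export
tidy.penalized_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$intercept, unname(x$beta)),
    selected = c(TRUE, x$beta != 0)
  )
}

#' @method glance penalized_fit
#' @export
glance.penalized_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, objective = x$objective,
                 n_selected = length(x$selected), n = x$n,
                 sweeps = x$sweeps)
}

#' Smallest penalty yielding the empty model
#'
#' `lambda_max = max_j |(1/n) * sum_i R_ij (y_i - mean(y))|`: at this
#' penalty (and above) every rule coefficient is zero and the intercept is
#' `logit(mean(y))`.
#'
#' @inheritParams fit_sparse_logistic
#' @return A positive number.
#' @export
lambda_max <- function(R, y) {
  R <- as.matrix(R)
  # a hair above the exact edge so the empty model is optimal there even
  # under floating-point ties in the soft-threshold comparison
  (1 + 1e-9) * max(abs(crossprod(R, y - mean(y)))) / length(y)
}

#' Karush-Kuhn-Tucker residuals of a penalized fit
#'
#' At the optimum, the unpenalized-loss gradient `g_j = (1/n) sum_i R_ij
#' (p_i - y_i)` must satisfy `|g_j| <= lambda` for zero coefficients and
#' `g_j = -lambda * sign(beta_j)` for active ones.
#'
#' @param fit A `penalized_fit`.
#' @inheritParams fit_sparse_logistic
#' @param tol Violation tolerance.
#' @return A tibble: `term`, `estimate`, `gradient`, `violation`, `ok`.
#' @export
kkt_conditions <- function(fit, R, y, tol = 1e-6) {
  R <- as.matrix(R)
  eta <- fit$intercept + as.numeric(R %*% fit$beta)
  p <- plogis(eta)
  g <- as.numeric(crossprod(R, p - y)) / length(y)
  viol <- ifelse(fit$beta == 0,
                 pmax(abs(g) - fit$lambda, 0),
                 abs(g + fit$lambda * sign(fit$beta)))
  tibble::tibble(term = names(fit$beta), estimate = unname(fit$beta),
                 gradient = g, violation = viol, ok = viol <= tol)
}

default_lambda_grid <- function(R, y, nlambda = 30, lambda_min_ratio = 0.01) {
  lmax <- lambda_max(R, y)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

stratified_folds <- function(y, k) {
  n <- length(y)
  if (k < 2) abort("k must be >= 2", class = "cohortrules_value_error")
  if (k > n) abort("k must be <= n", class = "cohortrules_value_error")
  if (min(table(y)) < 2) {
    abort(paste0("cannot stratify: a class has < 2 members; ",
                 "collect more data or reduce k"),
          class = "cohortrules_value_error")
  }
  fold <- integer(n)
  start <- 0L
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    # cycle through folds with a running offset so every fold is used even
    # when a class has fewer members than k (e.g. leave-one-out)
    fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  fold
}

binomial_deviance <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Choose the penalty by stratified k-fold cross-validation
#'
#' Solves a warm-started path on a log-spaced grid descending from
#' `lambda_max` within each training fold, scores each penalty by held-out
#' mean binomial deviance, and picks either the deviance-minimizing penalty
#' (`rule = "min"`) or the largest penalty within one standard error of the
#' minimum (`rule = "1se"`, the sparser conventional choice).
#'
#' @inheritParams fit_sparse_logistic
#' @param k Number of folds (stratified on the outcome).
#' @param rule `"1se"` (default) or `"min"`.
#' @param nlambda,lambda_min_ratio Grid: `nlambda` log-spaced values from
#'   `lambda_max` down to `lambda_max * lambda_min_ratio`.
#' @param seed Seed for the fold assignment.
#' @return A `cv_result`: tibble of `lambda`, `mean_deviance`, `se`,
#'   `n_selected`, plus `lambda_min`, `lambda_1se`, `lambda_star`, `rule`.
#' @export
select_lambda_cv <- function(R, y, k = 10, rule = c("1se", "min"),
                             nlambda = 20, lambda_min_ratio = 0.05,
                             seed = 1L, tol = 1e-4) {
  rule <- match.arg(rule)
  R <- as.matrix(R)
  grid <- default_lambda_grid(R, y, nlambda, lambda_min_ratio)
  fold <- with_seed(derive_seed(seed, "cv_folds"), stratified_folds(y, k))

  dev <- matrix(NA_real_, nrow = k, ncol = length(grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (sum(!tr) == 0) next
    if (length(unique(y[tr])) < 2) {
      abort("a training fold lost an outcome class; reduce k",
            class = "cohortrules_value_error")
    }
    path <- fit_sparse_logistic(R[tr, , drop = FALSE], y[tr], grid, tol = tol)
    eta <- matrix(path$intercept, nrow = sum(!tr), ncol = length(grid),
                  byrow = TRUE) + R[!tr, , drop = FALSE] %*% path$beta
    dev[f, ] <- apply(plogis(eta), 2, function(p) binomial_deviance(y[!tr], p))
  }

  full_path <- fit_sparse_logistic(R, y, grid, tol = tol)
  k_eff <- sum(!is.na(dev[, 1]))
  mean_dev <- colMeans(dev, na.rm = TRUE)
  se_dev <- apply(dev, 2, sd, na.rm = TRUE) / sqrt(k_eff)
  i_min <- which.min(mean_dev)
  i_1se <- min(which(mean_dev <= mean_dev[i_min] + se_dev[i_min]))
  tbl <- tibble::tibble(
    lambda = grid, mean_deviance = mean_dev, se = se_dev,
    n_selected = apply(full_path$beta, 2, function(b) sum(b != 0))
  )
  structure(list(table = tbl, lambda_min = grid[i_min],
                 lambda_1se = grid[i_1se],
                 lambda_star = if (rule == "min") grid[i_min] else grid[i_1se],
                 rule = rule, k = k, path = full_path),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$k, "-fold, rule = ", x$rule,
      ", lambda* = ", format(x$lambda_star),
      " (min = ", format(x$lambda_min), ", 1se = ", format(x$lambda_1se), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$table

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(x = log(.data$lambda), y = .data$mean_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_deviance - .data$se,
                                      ymax = .data$mean_deviance + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_star), linetype = 2) +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "held-out binomial deviance",
                  title = "Cross-validated penalty path")
}
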