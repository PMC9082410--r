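## Penalized-regression stage: coordinate-descent Lasso over a decreasing
## penalty path, 10-fold cross-validated lambda selection, and
## post-double-selection OLS for the exposure coefficient.
##
## Objective: (1/2n) * RSS + lambda * sum |beta| on standardized columns, so
## lambda does not scale with n. Lambda values under other scalings (e.g.
## un-normalized RSS) are not comparable.

std_record <- function(x) {
  xm <- colMeans(x)
  xs <- sqrt(colMeans(sweep(x, 2, xm)^2))  # population sd, matches 1/n objective
  list(mean = xm, sd = xs)
}

standardize_cols <- function(x, rec) {
  sweep(sweep(x, 2, rec$mean), 2, ifelse(rec$sd > 0, rec$sd, 1), "/")
}

#' Largest penalty with an all-zero solution
#'
#' For standardized columns and centered outcome,
#' `lambda_max = max_j |x_j' y| / (n * pf_j)` over penalized columns; at or
#' above it every penalized coefficient is exactly zero.
#'
#' @param x Numeric predictor matrix.
#' @param y Numeric outcome.
#' @param penalty_factor Per-column penalty loadings (0 = unpenalized).
#' @return Scalar `lambda_max`.
#' @export
lambda_max <- function(x, y, penalty_factor = rep(1, ncol(x))) {
  x <- as.matrix(x)
  rec <- std_record(x)
  xs <- standardize_cols(x, rec)
  yc <- y - mean(y)
  g <- abs(drop(crossprod(xs, yc))) / length(y)
  pen <- penalty_factor > 0
  if (!any(pen)) stop("no penalized columns", call. = FALSE)
  max(g[pen] / penalty_factor[pen])
}

#' Lasso solution at fixed penalty (cyclic coordinate descent)
#'
#' Minimizes `(1/2n) * sum((y - yhat)^2) + lambda * sum(pf_j * |beta_j|)` by
#' cyclic coordinate descent with soft-thresholding on internally standardized
#' columns; the intercept is unpenalized (handled by centering). Convergence:
#' maximum standardized-coefficient change below `tol` (default 1e-8) or
#' `max_sweeps` sweeps.
#'
#' @param x Numeric predictor matrix (columns named).
#' @param y Numeric outcome vector.
#' @param lambda Non-negative penalty (may be a decreasing vector; warm starts
#'   are used along the path).
#' @param penalty_factor Per-column penalty loadings (0 = unpenalized).
#' @param tol Convergence tolerance on the standardized scale.
#' @param max_sweeps Sweep cap (default 1e5).
#' @return List with `coefficients` (original scale, intercept first; matrix
#'   with one column per lambda), `std_path` (standardized-scale
#'   coefficients), `lambda`, `sweeps`, `std` (standardization record).
#' @export
lasso_fit <- function(x, y, lambda, penalty_factor = rep(1, ncol(x)),
                      tol = 1e-8, max_sweeps = 1e5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in the design", call. = FALSE)
  }
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  rec <- std_record(x)
  xs <- standardize_cols(x, rec)
  ym <- mean(y)
  yc <- y - ym
  res <- lasso_cd(xs, yc, as.numeric(lambda), as.numeric(penalty_factor),
                  numeric(ncol(x)), tol, as.integer(max_sweeps))
  if (!all(res$converged)) {
    i <- which(!res$converged)[1]
    stop(sprintf(
      "coordinate descent did not converge at lambda = %g (last max change %g)",
      lambda[i], res$last_change[i]), call. = FALSE)
  }
  std_path <- res$path
  rownames(std_path) <- colnames(x)
  # back-transform: beta_orig = beta_std / sd; intercept = ym - sum(b * mean)
  beta <- std_path / ifelse(rec$sd > 0, rec$sd, 1)
  intercept <- ym - drop(crossprod(beta, rec$mean))
  coefs <- rbind(`(Intercept)` = intercept, beta)
  colnames(coefs) <- colnames(std_path) <- paste0("s", seq_along(lambda))
  list(coefficients = coefs, std_path = std_path, lambda = lambda,
       sweeps = res$sweeps, std = rec)
}

#' Cross-validated penalty selection for the Lasso path
#'
#' Fits the Lasso over a log-spaced grid from `lambda_max` down to
#' `lambda_max * 1e-4`, selects lambda by K-fold cross-validation on a seeded
#' random partition (mean out-of-fold squared error; `"min"` rule by default,
#' `"1se"` available), and refits the full-data path. Ties in the CV error
#' are broken toward the larger (sparser) lambda.
#'
#' @inheritParams lasso_fit
#' @param n_folds Number of CV folds (default 10).
#' @param grid_size Number of lambdas on the path (default 50).
#' @param fold_seed Seed for the fold partition.
#' @param rule `"min"` or `"1se"`.
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @return Object of class `lasso_fit`: `lambda_grid`, `coef_path` (original
#'   scale), `std_path`, `cv_mean_error`, `cv_se`, `selected_lambda`,
#'   `selected_index`, `coefficients` (at the selection), `active_set`,
#'   `n_folds`, `fold_seed`.
#' @export
cv_select_lambda <- function(x, y, n_folds = 10, grid_size = 50,
                             fold_seed = 1, rule = c("min", "1se"),
                             penalty_factor = rep(1, ncol(x)),
                             lambda_min_ratio = 1e-4, tol = 1e-8) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(y)
  if (n < n_folds) stop("fewer rows than folds", call. = FALSE)
  lmax <- lambda_max(x, y, penalty_factor)
  grid <- lmax * 10^(seq(0, log10(lambda_min_ratio), length.out = grid_size))
  folds <- with_seed(fold_seed, sample(rep_len(seq_len(n_folds), n)))
  if (min(table(folds)) < 2) stop("a CV fold has fewer than 2 rows", call. = FALSE)

  err <- matrix(NA_real_, n_folds, grid_size)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit_k <- lasso_fit(x[tr, , drop = FALSE], y[tr], grid,
                       penalty_factor = penalty_factor, tol = tol)
    pred <- cbind(1, x[!tr, , drop = FALSE]) %*% fit_k$coefficients
    err[k, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(err)
  cvse <- apply(err, 2, sd) / sqrt(n_folds)
  idx <- which.min(cvm)  # first minimum = largest lambda on the decreasing grid
  if (rule == "1se") {
    idx <- which(cvm <= cvm[idx] + cvse[idx])[1]
  }
  full <- lasso_fit(x, y, grid, penalty_factor = penalty_factor, tol = tol)
  beta_sel <- full$std_path[, idx]
  structure(list(
    lambda_grid = grid,
    coef_path = full$coefficients,
    std_path = full$std_path,
    cv_mean_error = cvm,
    cv_se = cvse,
    selected_lambda = grid[idx],
    selected_index = idx,
    coefficients = full$coefficients[, idx],
    active_set = colnames(x)[beta_sel != 0],
    n_folds = n_folds,
    fold_seed = fold_seed,
    rule = rule,
    std = full$std
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("Lasso path: %d lambdas, %d-fold CV (seed %d, %s rule)\n",
              length(x$lambda_grid), x$n_folds, x$fold_seed, x$rule))
  cat(sprintf("  selected lambda = %.6g\n", x$selected_lambda))
  cat(sprintf("  active set (%d): %s\n", length(x$active_set),
              paste(x$active_set, collapse = ", ")))
  invisible(x)
}
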