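#' OLS with heteroskedasticity-robust standard errors
#'
#' Least squares of `y` on the given columns (intercept added), with sandwich
#' HC1 standard errors and adjusted R-squared. Rank-deficient designs raise an
#' error naming the dependent columns rather than silently dropping them.
#'
#' @param x Numeric matrix/data frame of predictors (no intercept column).
#' @param y Numeric outcome.
#' @param weights Optional strictly positive weights.
#' @return Object of class `ols_fit`: `coefficients`, `se` (robust),
#'   `t`, `p_value`, `adj_r2`, `r2`, `vcov` (robust), `fitted`, `residuals`,
#'   `n`, `lm` (the underlying fit).
#' @export
ols_fit <- function(x, y, weights = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(y)
  if (nrow(x) != n) stop("x and y have different lengths", call. = FALSE)
  if (n <= ncol(x) + 1) stop("need n > p + 1 observations", call. = FALSE)
  w <- check_weights(weights, n)
  dat <- data.frame(y = y, x, check.names = FALSE)
  fit <- lm(y ~ ., data = dat, weights = w)
  if (anyNA(coef(fit))) {
    stop(sprintf("collinear columns: %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = "HC1")
  se <- sqrt(diag(vc))
  b <- coef(fit)
  tt <- b / se
  p <- 2 * pnorm(-abs(tt))
  s <- summary(fit)
  structure(list(
    coefficients = b, se = se, t = tt, p_value = p,
    r2 = s$r.squared, adj_r2 = s$adj.r.squared,
    vcov = vc, fitted = fitted(fit), residuals = residuals(fit),
    n = n, lm = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, adj R^2 = %.4f (robust HC1 SEs)\n", x$n, x$adj_r2))
  stars <- cut(x$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$se, 4), sig = as.character(stars))
  print(tab)
  invisible(x)
}

#' Analysis design: outcome, exposure and controls
#'
#' Packs the regression ingredients used by the selection stage: the outcome,
#' the designated exposure (the consumption composite), and the named control
#' columns, together with the standardization record used on the controls.
#'
#' @param data Data frame of respondent records (no missing values in the
#'   used columns).
#' @param outcome Name of the outcome column.
#' @param exposure Name of the exposure column.
#' @param controls Character vector of control column names (may be empty;
#'   must exclude the exposure).
#' @param weights Optional name of a weight column.
#' @return Object of class `design_matrix`: `y`, `exposure` (vector),
#'   `controls` (matrix), `weights`, `std` (per-column mean/sd of controls),
#'   and the column names.
#' @export
design_matrix <- function(data, outcome, exposure, controls = character(),
                          weights = NULL) {
  cols <- c(outcome, exposure, controls, weights)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (exposure %in% controls) stop("controls must exclude the exposure", call. = FALSE)
  sub <- data[cols]
  if (!all(complete.cases(sub))) stop("missing values in the design", call. = FALSE)
  ctrl <- as.matrix(data[controls])
  if (length(controls) > 0) {
    sds <- apply(ctrl, 2, sd)
    if (any(sds <= 0)) {
      stop(sprintf("constant control column: %s",
                   paste(controls[sds <= 0], collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(
    y = data[[outcome]],
    exposure = data[[exposure]],
    controls = ctrl,
    weights = if (is.null(weights)) NULL else data[[weights]],
    std = if (length(controls) > 0) std_record(ctrl) else NULL,
    outcome_name = outcome, exposure_name = exposure,
    control_names = controls
  ), class = "design_matrix")
}

#' Post-double-selection estimate of the exposure effect
#'
#' Two Lasso selection steps - outcome on controls, exposure on controls -
#' followed by OLS of the outcome on the exposure plus the union of the two
#' active sets, with a robust (HC1) standard error on the exposure
#' coefficient. This guards the exposure estimate against moderate mistakes
#' in either selection. With no controls it reduces to the simple OLS slope.
#'
#' @param design A [design_matrix()] object.
#' @param n_folds,grid_size,fold_seed,rule Passed to [cv_select_lambda()];
#'   the exposure-equation selection uses `fold_seed + 1`.
#' @return Object of class `post_double_result`: `exposure_coefficient`,
#'   `standard_error`, `p_value`, `selected_controls`, `ols_coefficients`,
#'   `n_used`, and the two selection fits (`step_outcome`, `step_exposure`),
#'   plus `final` (the `ols_fit`).
#' @export
post_double_selection <- function(design, n_folds = 10, grid_size = 50,
                                  fold_seed = 1, rule = "min") {
  stopifnot(inherits(design, "design_matrix"))
  y <- design$y
  xcol <- matrix(design$exposure, ncol = 1,
                 dimnames = list(NULL, design$exposure_name))
  if (length(design$control_names) == 0) {
    final <- ols_fit(xcol, y)
    return(structure(list(
      exposure_coefficient = final$coefficients[design$exposure_name],
      standard_error = final$se[design$exposure_name],
      p_value = final$p_value[design$exposure_name],
      selected_controls = character(),
      ols_coefficients = final$coefficients,
      n_used = final$n,
      step_outcome = NULL, step_exposure = NULL, final = final
    ), class = "post_double_result"))
  }
  Z <- design$controls
  s1 <- cv_select_lambda(Z, y, n_folds = n_folds, grid_size = grid_size,
                         fold_seed = fold_seed, rule = rule)
  s2 <- cv_select_lambda(Z, design$exposure, n_folds = n_folds,
                         grid_size = grid_size, fold_seed = fold_seed + 1,
                         rule = rule)
  sel <- union(s1$active_set, s2$active_set)
  final <- ols_fit(cbind(xcol, Z[, sel, drop = FALSE]), y,
                   weights = design$weights)
  structure(list(
    exposure_coefficient = final$coefficients[design$exposure_name],
    standard_error = final$se[design$exposure_name],
    p_value = final$p_value[design$exposure_name],
    selected_controls = sel,
    ols_coefficients = final$coefficients,
    n_used = final$n,
    step_outcome = s1, step_exposure = s2, final = final
  ), class = "post_double_result")
}

#' @export
print.post_double_result <- function(x, ...) {
  cat("Post-double-selection estimate\n")
  cat(sprintf("  exposure coefficient = %.4f (robust SE %.4f)\n",
              x$exposure_coefficient, x$standard_error))
  cat(sprintf("  selected controls (%d): %s\n", length(x$selected_controls),
              paste(x$selected_controls, collapse = ", ")))
  invisible(x)
}
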