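#' Wagstaff decomposition of the concentration index
#'
#' For a linear model `y = a + sum_k b_k x_k + e`, the concentration index
#' decomposes as `CI = sum_k eta_k C_k + GC_e / mu`, where
#' `eta_k = b_k * xbar_k / mu` is the elasticity of the mean outcome with
#' respect to factor k, `C_k` is the concentration index of factor k against
#' the *same* fractional ranks, and the residual term is the generalized
#' concentration index of the regression residuals over `mu`. Coefficients
#' come from weighted OLS of the outcome on all factors; the adding-up
#' identity `sum(contributions) + residual = CI` holds to machine precision
#' by construction.
#'
#' @param outcome Numeric outcome with positive weighted mean.
#' @param ranking Numeric ranking variable.
#' @param factors Data frame (or matrix) of named numeric factor columns.
#' @param weights Optional strictly positive sampling weights.
#' @return Object of class `wagstaff_decomposition` with elements `ci`
#'   (a `concentration_result`), `mu`, `coefficients`, `residual`,
#'   `residual_pct`, and `table`: one row per factor with `coefficient`,
#'   `mean`, `elasticity`, `factor_ci`, `contribution`, `pct_contribution`,
#'   sorted by absolute percentage contribution.
#' @export
wagstaff_decomposition <- function(outcome, ranking, factors, weights = NULL) {
  y <- as.numeric(outcome)
  n <- length(y)
  X <- as.data.frame(factors)
  if (nrow(X) != n) stop("factors must have the same rows as the outcome", call. = FALSE)
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("all factor columns must be numeric", call. = FALSE)
  }
  w <- check_weights(weights, n)
  cres <- concentration_index(y, ranking, w, se = "none",
                              ranking_name = "ranking")
  mu <- cres$mu
  R <- cres$R

  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop(sprintf("collinear factors: %s", paste(dropped, collapse = ", ")),
         call. = FALSE)
  }
  fit <- lm(y ~ ., data = X, weights = w)
  beta <- coef(fit)[-1]

  xbar <- vapply(X, wmean, numeric(1), w = w)
  cov_xR <- vapply(X, wcov, numeric(1), y = R, w = w)
  contribution <- 2 * beta * cov_xR / mu           # eta_k * C_k, safe at xbar=0
  factor_ci <- ifelse(abs(xbar) > 1e-12, 2 * cov_xR / xbar, NA_real_)
  elasticity <- beta * xbar / mu
  residual <- cres$ci - sum(contribution)

  tab <- data.frame(
    factor = names(beta),
    coefficient = unname(beta),
    mean = unname(xbar),
    elasticity = unname(elasticity),
    factor_ci = unname(factor_ci),
    contribution = unname(contribution),
    pct_contribution = unname(contribution / cres$ci * 100),
    row.names = NULL
  )
  tab <- tab[order(-abs(tab$pct_contribution)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    ci = cres,
    mu = mu,
    coefficients = coef(fit),
    table = tab,
    residual = residual,
    residual_pct = residual / cres$ci * 100
  ), class = "wagstaff_decomposition")
}

#' @export
print.wagstaff_decomposition <- function(x, ...) {
  cat(sprintf("Wagstaff decomposition: CI = %.4f, residual = %.4g (%.2f%%)\n",
              x$ci$ci, x$residual, x$residual_pct))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Horizontal inequity via need-factor standardization
#'
#' Inequity is the inequality left after removing the part attributable to
#' legitimate need: `HI = CI - sum over need factors of eta_k * C_k`. Need
#' factors default downstream to demographic/health-need variables (gender,
#' education years, health status, age); the remaining (non-need) contributions
#' and the residual stay in HI. HI > 0 indicates pro-rich inequity.
#'
#' @param decomp A [wagstaff_decomposition()] result.
#' @param need_factors Character vector of factor names treated as need;
#'   may be empty (then `HI = CI`).
#' @return Object of class `horizontal_inequity`: `hi`, `need_factors`,
#'   `nonneed_factors`, `need_contribution_total`, `ci` (the underlying
#'   `concentration_result`).
#' @export
horizontal_inequity <- function(decomp, need_factors = character()) {
  stopifnot(inherits(decomp, "wagstaff_decomposition"))
  unknown <- setdiff(need_factors, decomp$table$factor)
  if (length(unknown) > 0) {
    stop(sprintf("unknown need factor(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  need_total <- sum(decomp$table$contribution[decomp$table$factor %in% need_factors])
  structure(list(
    hi = decomp$ci$ci - need_total,
    need_factors = need_factors,
    nonneed_factors = setdiff(decomp$table$factor, need_factors),
    need_contribution_total = need_total,
    ci = decomp$ci
  ), class = "horizontal_inequity")
}

#' @export
print.horizontal_inequity <- function(x, ...) {
  cat(sprintf("Horizontal inequity: HI = %.4f (CI = %.4f, need contributions = %.4f)\n",
              x$hi, x$ci$ci, x$need_contribution_total))
  cat("  need factors:", if (length(x$need_factors)) paste(x$need_factors, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Seeded nonparametric bootstrap for CI and HI
#'
#' Resamples rows with replacement and recomputes the concentration index and
#' horizontal inequity, giving bootstrap standard errors and percentile
#' intervals for quantities (HI, contribution shares) whose analytic standard
#' errors are awkward.
#'
#' @inheritParams wagstaff_decomposition
#' @param need_factors Character vector of need-factor names.
#' @param B Number of bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @return List with `ci_se`, `hi_se`, `ci_ci95`, `hi_ci95`, and the draws.
#' @export
bootstrap_inequality <- function(outcome, ranking, factors,
                                 need_factors = character(),
                                 weights = NULL, B = 1000, seed = 1) {
  n <- length(outcome)
  w <- check_weights(weights, n)
  X <- as.data.frame(factors)
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- wagstaff_decomposition(outcome[idx], ranking[idx],
                                  X[idx, , drop = FALSE], w[idx])
      h <- horizontal_inequity(d, need_factors)
      c(ci = d$ci$ci, hi = h$hi)
    }, numeric(2))
  })
  list(
    ci_se = sd(draws["ci", ]),
    hi_se = sd(draws["hi", ]),
    ci_ci95 = unname(quantile(draws["ci", ], c(0.025, 0.975))),
    hi_ci95 = unname(quantile(draws["hi", ], c(0.025, 0.975))),
    draws = t(draws)
  )
}

#' Stratified concentration and inequity analysis
#'
#' Recomputes the concentration index and horizontal inequity independently
#' within each stratum (ranks are re-derived within stratum), plus the mean
#' and SD of the outcome by quartile of the ranking variable - the usual
#' "inequality by income group" table. Strata below the size floor are skipped
#' with a warning.
#'
#' @param data Data frame of respondent records.
#' @param stratify_by Name of the stratifying column.
#' @param outcome Name of the outcome column.
#' @param ranking Name of the ranking column.
#' @param factors Character vector of factor columns for the within-stratum
#'   decomposition (used for HI).
#' @param need_factors Character vector of need-factor names.
#' @param weights Optional name of the weight column.
#' @param min_n Minimum stratum size (default 30).
#' @return Object of class `subgroup_inequality`: `summary` data frame
#'   (stratum, n, ci, ci_se, hi), `quartile_table` (stratum x ranking-quartile
#'   mean +/- SD of the outcome), and per-stratum detail.
#' @export
subgroup_inequality <- function(data, stratify_by, outcome, ranking,
                                factors, need_factors = character(),
                                weights = NULL, min_n = 30) {
  for (col in c(stratify_by, outcome, ranking, factors, weights)) {
    if (!col %in% names(data)) stop(sprintf("column '%s' not found", col), call. = FALSE)
  }
  strata <- split(seq_len(nrow(data)), data[[stratify_by]])
  rows <- list()
  qrows <- list()
  detail <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (length(idx) < min_n) {
      warning(sprintf("stratum '%s' has %d rows (< %d): skipped",
                      s, length(idx), min_n))
      next
    }
    d <- data[idx, , drop = FALSE]
    w <- if (is.null(weights)) NULL else d[[weights]]
    # factors can collapse within a stratum (e.g. an income group inside an
    # income stratum); constant columns are dropped from the local model
    live <- factors[vapply(d[factors], function(v) sd(v) > 0, logical(1))]
    dec <- wagstaff_decomposition(d[[outcome]], d[[ranking]],
                                  d[live], w)
    cres <- concentration_index(d[[outcome]], d[[ranking]], w,
                                ranking_name = ranking)
    hi <- horizontal_inequity(dec, need_factors)
    rows[[s]] <- data.frame(stratum = s, n = length(idx),
                            ci = cres$ci, ci_se = cres$se, hi = hi$hi)
    qg <- quantile_group(d[[ranking]], 4)
    for (q in sort(unique(qg))) {
      yq <- d[[outcome]][qg == q]
      qrows[[paste(s, q)]] <- data.frame(
        stratum = s, quartile = q, n = length(yq),
        mean = mean(yq), sd = sd(yq))
    }
    detail[[s]] <- list(ci = cres, decomposition = dec, hi = hi)
  }
  if (length(rows) == 0) stop("no stratum met the size floor", call. = FALSE)
  structure(list(
    summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    quartile_table = do.call(rbind, c(qrows, list(make.row.names = FALSE))),
    detail = detail
  ), class = "subgroup_inequality")
}

#' @export
print.subgroup_inequality <- function(x, ...) {
  cat("Within-stratum concentration and inequity indices\n")
  s <- x$summary
  s[c("ci", "ci_se", "hi")] <- lapply(s[c("ci", "ci_se", "hi")], round, 4)
  print(s, row.names = FALSE)
  invisible(x)
}
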