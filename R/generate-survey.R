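## Seeded survey simulator. Rank dependence between covariates and the
## consumption construct is induced by a Gaussian copula on latent normals;
## marginals are applied by inverse CDF, so the rank structure (which is all
## the concentration index sees) is controlled separately from the marginal
## shapes. Latent correlations are calibrated so the *post-discretization*
## Spearman correlation with the latent consumption factor hits the target.

## population Spearman correlation between a discretized margin (midranks)
## and the continuous factor, as a function of the latent correlation rho
spearman_discrete <- function(rho, probs, grid_m = 512) {
  F <- cumsum(probs)
  m <- c(0, F[-length(F)]) + probs / 2      # midranks in [0, 1]
  varm <- sum(probs * m^2) - 0.25
  if (varm <= 0) return(0)
  u <- (seq_len(grid_m) - 0.5) / grid_m
  f <- qnorm(u)
  s <- sqrt(max(1 - rho^2, 1e-12))
  thr <- qnorm(pmin(F, 1 - 1e-15))
  thr[length(thr)] <- Inf
  lo <- c(-Inf, thr[-length(thr)])
  Em <- numeric(grid_m)
  for (c_i in seq_along(probs)) {
    Em <- Em + m[c_i] * (pnorm((thr[c_i] - rho * f) / s) -
                           pnorm((lo[c_i] - rho * f) / s))
  }
  (mean(Em * u) - 0.25) / sqrt(varm / 12)
}

## latent correlation achieving a target Spearman for a given marginal spec
calibrate_rho <- function(target, spec, name) {
  if (target == 0) return(0)
  if (spec$type == "truncnorm") {
    # continuous margin: closed form for the Gaussian copula
    return(2 * sin(pi * target / 6))
  }
  probs <- if (spec$type == "bernoulli") c(1 - spec$p, spec$p) else spec$probs
  fmax <- spearman_discrete(0.9999, probs)
  if (abs(target) > fmax) {
    stop(sprintf(
      "configuration error for covariate '%s': target rank correlation %.3f exceeds the attainable maximum %.3f under its marginal",
      name, target, fmax), call. = FALSE)
  }
  uniroot(function(r) spearman_discrete(r, probs) - abs(target),
          c(0, 0.9999), tol = 1e-9)$root * sign(target)
}

apply_marginal <- function(u, spec) {
  switch(spec$type,
    bernoulli = as.integer(u > qnorm(1 - spec$p)),
    categorical = {
      thr <- qnorm(pmin(cumsum(spec$probs), 1 - 1e-15))
      spec$levels[findInterval(u, thr[-length(thr)]) + 1L]
    },
    truncnorm = {
      pa <- pnorm(spec$min, spec$mean, spec$sd)
      pb <- pnorm(spec$max, spec$mean, spec$sd)
      q <- pa + pnorm(u) * (pb - pa)
      x <- qnorm(q, spec$mean, spec$sd)
      pmin(pmax(round(x), spec$min), spec$max)
    }
  )
}

## split integer totals 0..32 into 4 exchangeable items 0..8 summing exactly
## to the total (sequential hypergeometric draws = multivariate hypergeometric)
split_items <- function(total, balanced = FALSE) {
  n <- length(total)
  if (balanced) {
    base <- total %/% 4L
    rem <- total %% 4L
    items <- sapply(1:4, function(j) base + as.integer(j <= rem))
  } else {
    k1 <- rhyper(n, 8, 24, total)
    k2 <- rhyper(n, 8, 16, total - k1)
    k3 <- rhyper(n, 8, 8, total - k1 - k2)
    items <- cbind(k1, k2, k3, total - k1 - k2 - k3)
  }
  items <- matrix(as.integer(items), nrow = n)
  colnames(items) <- paste0("item", 1:4)
  items
}

#' Generate a synthetic household survey
#'
#' Draws a respondent-level table with the configured marginals, a Gaussian
#' copula linking every covariate to the latent household-consumption factor,
#' five Likert-derived consumption items (compressed into a PCA composite),
#' and a health-education score generated from the known linear model in the
#' config, discretized onto 0..32 and split into four 0-8 items. The table
#' carries the ground truth (`latent_consumption` column; `truth` attribute
#' with the true coefficients) so downstream estimators can be validated.
#'
#' @param config A [survey_config()].
#' @return A `survey_table` (data frame) with columns: `id`, `item1..item4`,
#'   `he_total`, `he_log`, `cons_1..cons_5`, `consumption` (composite in
#'   `[0,1]`), `age`, `age_sq`, `gender`, `married`, `education_years`,
#'   `residence`, `insurance`, `health_status`, `monthly_income`,
#'   `annual_income`, `city`, `community`, `weight`, plus two ground-truth
#'   columns: `latent_consumption` (the copula factor) and `latent_outcome`
#'   (the linear-model outcome before rounding/censoring onto 0..32; on it
#'   the configured coefficients hold exactly, whereas coefficients on the
#'   discretized score are slightly attenuated by the 0/32 bounds).
#'   Attributes: `config`, `truth` (alpha, beta, sigma_eps, composite
#'   loadings/reliability).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  n <- config$n_respondents
  with_seed(config$seed, {
    f <- rnorm(n)  # latent consumption factor

    # five consumption dimensions: one-factor model, then Likert cut-points,
    # reverse-coded so higher = more consumption, on {0, .25, .5, .75, 1}
    lam <- config$loading
    thr <- qnorm(pmin(cumsum(config$likert_probs), 1 - 1e-15))
    cons <- sapply(1:5, function(d) {
      z <- lam * f + sqrt(1 - lam^2) * rnorm(n)
      (findInterval(z, thr[-length(thr)])) / 4
    })
    colnames(cons) <- paste0("cons_", 1:5)
    comp <- pca_composite(cons)
    consumption <- comp$standardized_scores

    # covariates via the copula
    covs <- list()
    for (nm in names(config$marginals)) {
      spec <- config$marginals[[nm]]
      target <- if (nm %in% names(config$rank_corr)) config$rank_corr[[nm]] else 0
      rho <- calibrate_rho(target, spec, nm)
      u <- rho * f + sqrt(1 - rho^2) * rnorm(n)
      covs[[nm]] <- apply_marginal(u, spec)
    }
    if (!is.null(covs$age)) covs$age_sq <- covs$age^2

    # latent outcome: linear model on the configured scale
    beta <- config$beta
    X <- cbind(consumption = consumption,
               do.call(cbind, covs[setdiff(names(beta), "consumption")]))
    missing_beta <- setdiff(names(beta), colnames(X))
    if (length(missing_beta) > 0) {
      stop(sprintf("beta names without a generated covariate: %s",
                   paste(missing_beta, collapse = ", ")), call. = FALSE)
    }
    eps <- rnorm(n, 0, config$sigma_eps)
    ell <- config$alpha + drop(X[, names(beta), drop = FALSE] %*% beta) + eps
    t_star <- if (config$latent_scale == "log") expm1(ell) else ell

    if (config$discretize) {
      total <- as.integer(pmin(32, pmax(0, round(t_star))))
      items <- split_items(total, balanced = config$item_noise_sd == 0)
      he_total <- total
      he_log <- log1p(total)
    } else {
      items <- NULL
      he_total <- t_star
      he_log <- log1p(t_star)
    }

    # community / city labels and sampling weights
    if (config$weight_scheme == "stratified") {
      pr <- 0.5 + seq_len(config$n_communities) / config$n_communities
      pr <- pr / sum(pr)
      community <- sample.int(config$n_communities, n, replace = TRUE, prob = pr)
      weight <- (1 / pr[community])
      weight <- weight / mean(weight)
    } else {
      community <- sample.int(config$n_communities, n, replace = TRUE)
      weight <- rep(1, n)
    }
    city <- ((community - 1L) %% config$n_cities) + 1L

    out <- data.frame(id = seq_len(n))
    if (!is.null(items)) out <- cbind(out, items)
    out <- cbind(out, data.frame(
      he_total = he_total, he_log = he_log, cons,
      consumption = consumption,
      age = covs$age, age_sq = covs$age_sq, gender = covs$gender,
      married = covs$married, education_years = covs$education_years,
      residence = covs$residence, insurance = covs$insurance,
      health_status = covs$health_status,
      monthly_income = covs$monthly_income,
      annual_income = covs$annual_income,
      city = city, community = community, weight = weight,
      latent_consumption = f,
      latent_outcome = ell   # pre-discretization linear-model outcome
    ))
    attr(out, "config") <- config
    attr(out, "truth") <- list(
      alpha = config$alpha, beta = beta, sigma_eps = config$sigma_eps,
      loadings = comp$loadings,
      cronbach_alpha = comp$cronbach_alpha,
      explained_variance_ratio = comp$explained_variance_ratio
    )
    class(out) <- c("survey_table", "data.frame")
    out
  })
}

#' Expected concentration index implied by a generator config
#'
#' Monte-Carlo estimate of the population concentration index of the
#' health-education outcome against the consumption ranking under the
#' config's data-generating process: one large draw (default 1e6 rows) is
#' generated and its CI computed. No closed form exists once the score is
#' rounded and censored at 0/32, so this is an approximation whose error
#' shrinks as `1/sqrt(n_mc)`. The linear decomposition value
#' `sum_k eta_k C_k` evaluated with the *true* coefficients is attached as
#' attribute `linear_approx` (it is exactly 0 when all beta are 0).
#'
#' @param config A [survey_config()].
#' @param n_mc Rows in the Monte-Carlo draw (default 1e6).
#' @param seed Seed for the draw (default derived from the config seed).
#' @return Scalar expected CI with attributes `linear_approx` and `n_mc`.
#' @export
expected_ci <- function(config, n_mc = 1e6, seed = NULL) {
  stopifnot(inherits(config, "survey_config"))
  cfg <- config
  cfg$n_respondents <- as.integer(n_mc)
  cfg$seed <- seed %||% substream_seed(config$seed, 77)
  tab <- generate_survey(cfg)
  y <- if (config$latent_scale == "log") tab$he_log else tab$he_total
  w <- tab$weight
  R <- fractional_rank(tab$consumption, w)
  mu <- wmean(y, w)
  ci <- 2 * wcov(y, R, w) / mu
  beta <- config$beta
  lin <- 0
  for (nm in names(beta)) {
    if (beta[nm] == 0) next
    lin <- lin + 2 * beta[nm] * wcov(tab[[nm]], R, w) / mu
  }
  structure(ci, linear_approx = unname(lin), n_mc = n_mc)
}

#' Write / read a survey table as CSV with a JSON sidecar
#'
#' The CSV is RFC-4180 UTF-8 with a header row; the sidecar
#' (`<path>.json`) stores the generator config and true parameters when the
#' table came from [generate_survey()].
#'
#' @param table A `survey_table` or plain data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  df <- as.data.frame(table)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  truth <- attr(table, "truth")
  config <- attr(table, "config")
  if (!is.null(config)) {
    cfg <- unclass(config)
    # named vectors keep their names in JSON only as objects
    for (nm in c("beta", "rank_corr")) cfg[[nm]] <- as.list(cfg[[nm]])
    if (!is.null(truth)) {
      truth$beta <- as.list(truth$beta)
      truth$loadings <- as.list(truth$loadings)
    }
    side <- list(config = cfg, truth = truth)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
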