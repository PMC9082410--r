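## Generator configuration: marginal distributions matched to the published
## sample description of the 2020 cross-sectional consumption/health-education
## survey (n = 7,715 respondents, 85 cities, 301 communities), a Gaussian
## copula carrying the rank dependence between covariates and the latent
## household-consumption factor, and a known linear data-generating process
## for the health-education outcome.

default_marginals <- function() {
  list(
    age = list(type = "truncnorm", mean = 35, sd = 12, min = 18, max = 80),
    gender = list(type = "bernoulli", p = 0.51),
    married = list(type = "bernoulli", p = 0.59),
    education_years = list(type = "categorical",
                           levels = c(0, 6, 9, 12, 16, 20),
                           probs = c(0.13, 0.18, 0.25, 0.20, 0.16, 0.08)),
    residence = list(type = "bernoulli", p = 0.44),
    insurance = list(type = "bernoulli", p = 0.37),
    health_status = list(type = "categorical", levels = 1:5,
                         probs = c(0.05, 0.15, 0.35, 0.30, 0.15)),
    monthly_income = list(type = "categorical", levels = 1:4,
                          probs = c(0.25, 0.25, 0.25, 0.25)),
    annual_income = list(type = "categorical", levels = 1:6,
                         probs = c(0.18, 0.20, 0.21, 0.17, 0.14, 0.10))
  )
}

default_rank_corr <- function() {
  c(age = -0.10, gender = 0.02, married = 0.05, education_years = 0.35,
    residence = -0.25, insurance = 0.20, health_status = 0.15,
    monthly_income = 0.40, annual_income = 0.45)
}

## True linear coefficients on the log health-education outcome ln(1+score).
## The exposure effect (0.30 per unit of the [0,1] consumption composite) and
## the covariate effects are sized so the population concentration index of
## the outcome against consumption rank is about 0.032, with consumption and
## annual income the leading contributors.
default_beta <- function() {
  c(consumption = 0.30, age_sq = -3e-05, gender = 0, married = 0,
    education_years = 0.011, residence = -0.12, insurance = 0.04,
    health_status = 0.045, monthly_income = 0, annual_income = 0.045)
}

#' Synthetic-survey generator configuration
#'
#' Assembles and validates the configuration for [generate_survey()]:
#' marginal distributions of the covariates, target Spearman rank
#' correlations between each covariate and the latent consumption factor
#' (induced by a Gaussian copula), the true linear coefficients of the
#' outcome model, and nuisance settings. Defaults reproduce the marginal
#' structure of the published survey (gender share 0.51, mean education
#' 9.86 years, health-education score mean 12.17 / SD 7.72, consumption
#' composite mean about 0.33, five consumption items with internal
#' reliability alpha about 0.85).
#'
#' The outcome model is linear on the log scale by default:
#' `ln(1 + score) = alpha + sum_k beta_k x_k + eps`, `eps ~ N(0, sigma_eps)`,
#' with the score discretized onto 0..32 and split into four 0-8 items that
#' sum exactly to the total.
#'
#' @param n_respondents Number of rows (>= 2).
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @param beta Named numeric vector of true coefficients (see
#'   `healthineq:::default_beta`); `consumption` refers to the PCA composite.
#' @param rank_corr Named numeric vector in `[-1, 1]`: target Spearman
#'   correlation of each covariate with the latent consumption factor.
#' @param marginals Named list of per-covariate marginal specs
#'   (`bernoulli`, `categorical`, `truncnorm`).
#' @param alpha Intercept of the latent outcome model.
#' @param sigma_eps Residual SD of the latent outcome model.
#' @param likert_probs Marginal probabilities of the five reverse-coded
#'   consumption item levels (scores 0, .25, .5, .75, 1).
#' @param loading Common factor loading of the five consumption items
#'   (0.77 gives realized item reliability alpha about 0.85 after
#'   discretization onto the five Likert levels).
#' @param item_noise_sd Non-negative; 0 gives a deterministic balanced split
#'   of the total into the four outcome items, any positive value the
#'   exchangeable multivariate-hypergeometric split (default).
#' @param latent_scale `"log"` (default; model linear in `ln(1+score)`) or
#'   `"total"` (linear in the 0-32 score).
#' @param discretize If `TRUE` (default) the score is rounded onto 0..32 and
#'   split into items; if `FALSE` the continuous latent outcome is stored and
#'   item columns are omitted (useful for exact ground-truth checks).
#' @param weight_scheme `"uniform"` (all weights 1) or `"stratified"`
#'   (weights inversely proportional to the community sampling fraction).
#' @param n_cities,n_communities Numbers of city/community labels.
#' @return Object of class `survey_config`.
#' @export
survey_config <- function(n_respondents = 7715L, seed = 1L,
                          beta = default_beta(),
                          rank_corr = default_rank_corr(),
                          marginals = default_marginals(),
                          alpha = 2.031, sigma_eps = 0.517,
                          likert_probs = c(0.22, 0.36, 0.28, 0.10, 0.04),
                          loading = 0.77,
                          item_noise_sd = 1,
                          latent_scale = c("log", "total"),
                          discretize = TRUE,
                          weight_scheme = c("uniform", "stratified"),
                          n_cities = 85L, n_communities = 301L) {
  latent_scale <- match.arg(latent_scale)
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(n_respondents) || n_respondents < 2) {
    stop("n_respondents must be at least 2", call. = FALSE)
  }
  if (item_noise_sd < 0) stop("item_noise_sd must be non-negative", call. = FALSE)
  if (sigma_eps < 0) stop("sigma_eps must be non-negative", call. = FALSE)
  if (any(rank_corr < -1 | rank_corr > 1)) {
    stop("rank_corr values must lie in [-1, 1]", call. = FALSE)
  }
  if (abs(sum(likert_probs) - 1) > 1e-12 || any(likert_probs < 0)) {
    stop("likert_probs must be a probability vector summing to 1", call. = FALSE)
  }
  required <- names(default_marginals())
  absent <- setdiff(required, names(marginals))
  if (length(absent) > 0) {
    stop(sprintf("marginals must cover the survey covariates; missing: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(marginals)) {
    validate_marginal(marginals[[nm]], nm)
  }
  unknown <- setdiff(names(rank_corr), names(marginals))
  if (length(unknown) > 0) {
    stop(sprintf("rank_corr names without marginal spec: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    n_respondents = as.integer(n_respondents), seed = as.integer(seed),
    beta = beta, rank_corr = rank_corr, marginals = marginals,
    alpha = alpha, sigma_eps = sigma_eps, likert_probs = likert_probs,
    loading = loading, item_noise_sd = item_noise_sd,
    latent_scale = latent_scale, discretize = discretize,
    weight_scheme = weight_scheme,
    n_cities = as.integer(n_cities), n_communities = as.integer(n_communities)
  ), class = "survey_config")
}

validate_marginal <- function(spec, name) {
  err <- function(msg) {
    stop(sprintf("invalid distribution spec for covariate '%s': %s", name, msg),
         call. = FALSE)
  }
  if (is.null(spec$type)) err("missing type")
  switch(spec$type,
    bernoulli = {
      if (is.null(spec$p) || spec$p <= 0 || spec$p >= 1) err("p must be in (0, 1)")
    },
    categorical = {
      if (is.null(spec$levels) || is.null(spec$probs)) err("needs levels and probs")
      if (length(spec$levels) != length(spec$probs)) err("levels/probs length mismatch")
      if (any(spec$probs < 0)) err("negative probability")
      if (abs(sum(spec$probs) - 1) > 1e-12) err("probabilities must sum to 1")
    },
    truncnorm = {
      if (is.null(spec$mean) || is.null(spec$sd) || is.null(spec$min) ||
          is.null(spec$max)) err("needs mean, sd, min, max")
      if (spec$sd <= 0 || spec$max <= spec$min) err("sd > 0 and max > min required")
    },
    err(sprintf("unknown type '%s'", spec$type))
  )
  invisible(TRUE)
}

#' @export
print.survey_config <- function(x, ...) {
  cat(sprintf("Survey generator config: n = %d, seed = %d\n",
              x$n_respondents, x$seed))
  cat(sprintf("  latent scale: %s, discretize: %s, weights: %s\n",
              x$latent_scale, x$discretize, x$weight_scheme))
  cat(sprintf("  true beta: %s\n",
              paste(sprintf("%s=%g", names(x$beta), x$beta), collapse = ", ")))
  invisible(x)
}

#' Read / write a generator config as YAML
#'
#' @param path File path.
#' @param config A `survey_config`.
#' @param seed Optional seed override applied after reading.
#' @return `read_survey_config` returns a `survey_config`.
#' @export
read_survey_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  for (nm in c("beta", "rank_corr", "likert_probs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(survey_config, raw)
}

#' @rdname read_survey_config
#' @export
write_survey_config <- function(config, path) {
  stopifnot(inherits(config, "survey_config"))
  out <- unclass(config)
  out$beta <- as.list(out$beta)
  out$rank_corr <- as.list(out$rank_corr)
  yaml::write_yaml(out, path)
  invisible(path)
}
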