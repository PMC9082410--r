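test_that("identical config and seed give identical tables", {
  a <- generate_survey(survey_config(n_respondents = 500, seed = 123))
  b <- generate_survey(survey_config(n_respondents = 500, seed = 123))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_survey(survey_config(n_respondents = 500, seed = 124))
  expect_false(identical(a$he_total, c2$he_total))
})

test_that("generated tables satisfy the row-level invariants", {
  sv <- small_survey(2000, seed = 50)
  items <- as.matrix(sv[paste0("item", 1:4)])
  expect_true(all(items >= 0 & items <= 8 & items == round(items)))
  expect_identical(as.integer(rowSums(items)), sv$he_total)
  expect_true(all(sv$he_total >= 0 & sv$he_total <= 32))
  expect_equal(sv$he_log, log1p(sv$he_total))
  expect_true(all(sv$weight > 0))
  expect_true(all(sv$gender %in% 0:1) && all(sv$married %in% 0:1))
  expect_true(all(sv$health_status %in% 1:5))
  expect_true(all(sv$age >= 18 & sv$age <= 80))
  expect_identical(sv$age_sq, sv$age^2)
  expect_true(all(sv$consumption >= 0 & sv$consumption <= 1))
  expect_true(all(sv$city %in% 1:85) && all(sv$community %in% 1:301))

  # balanced item split when item_noise_sd = 0
  sv0 <- small_survey(200, seed = 51, item_noise_sd = 0)
  it0 <- as.matrix(sv0[paste0("item", 1:4)])
  expect_true(all(apply(it0, 1, function(r) max(r) - min(r) <= 1)))
  expect_identical(as.integer(rowSums(it0)), sv0$he_total)
})

test_that("categorical marginals match their spec within binomial tolerance", {
  n <- 7715
  sv <- generate_survey(survey_config(n_respondents = n, seed = 52))
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(sv$gender) - 0.51), 0.02)            # published share
  expect_lt(abs(mean(sv$education_years) - 9.86), 0.3)    # published mean
  expect_lt(abs(mean(sv$married) - 0.59), tol(0.59))
  expect_lt(abs(mean(sv$residence) - 0.44), tol(0.44))
  expect_lt(abs(mean(sv$insurance) - 0.37), tol(0.37))
  for (lv in 1:5) {
    p <- c(0.05, 0.15, 0.35, 0.30, 0.15)[lv]
    expect_lt(abs(mean(sv$health_status == lv) - p), tol(p))
  }
  # outcome scale mirrors the published score distribution
  expect_lt(abs(mean(sv$he_total) - 12.17), 0.5)
  expect_gt(sd(sv$he_total), 6.5)
})

test_that("copula calibration hits the target rank correlations", {
  n <- 6000
  sv <- generate_survey(survey_config(n_respondents = n, seed = 53))
  targets <- c(age = -0.10, education_years = 0.35, residence = -0.25,
               insurance = 0.20, health_status = 0.15,
               monthly_income = 0.40, annual_income = 0.45)
  for (nm in names(targets)) {
    achieved <- cor(sv[[nm]], sv$latent_consumption, method = "spearman")
    expect_lt(abs(achieved - targets[[nm]]), 0.05)
  }
})

test_that("config validation rejects malformed inputs", {
  expect_error(survey_config(n_respondents = 1), "at least 2")
  expect_error(survey_config(rank_corr = c(age = 1.2)), "\\[-1, 1\\]")
  bad <- healthineq:::default_marginals()
  bad$gender$p <- 1.5
  expect_error(survey_config(marginals = bad), "gender")
  bad2 <- healthineq:::default_marginals()
  bad2$annual_income$probs <- c(0.5, 0.5, 0.1, 0, 0, 0)
  expect_error(survey_config(marginals = bad2), "annual_income")
  # unattainable rank correlation for a binary margin
  expect_error(
    generate_survey(survey_config(n_respondents = 100,
                                  rank_corr = c(gender = 0.99))),
    "gender")
})

test_that("all-zero coefficients give a null concentration index", {
  beta0 <- healthineq:::default_beta(); beta0[] <- 0
  cis <- vapply(1:30, function(i) {
    sv <- generate_survey(survey_config(n_respondents = 800, seed = 700 + i,
                                        beta = beta0, item_noise_sd = 0))
    concentration_index(sv$he_log, sv$consumption, se = "none")$ci
  }, numeric(1))
  expect_lt(abs(mean(cis)), 3 * sd(cis) / sqrt(length(cis)))
  # and the closed-form side of expected_ci is exactly zero
  e <- expected_ci(survey_config(beta = beta0), n_mc = 20000, seed = 1)
  expect_identical(attr(e, "linear_approx"), 0)
  expect_lt(abs(as.numeric(e)), 0.02)
})

test_that("expected_ci equals the factor CI when the exposure is the ranking", {
  # exposure effect only, no noise: outcome = a + 1 * consumption exactly,
  # so the outcome CI equals eta * C(consumption) with eta = C of itself
  beta1 <- healthineq:::default_beta(); beta1[] <- 0; beta1["consumption"] <- 1
  cfg <- survey_config(n_respondents = 20000, seed = 54, beta = beta1,
                       sigma_eps = 0, discretize = FALSE)
  sv <- generate_survey(cfg)
  ci_y <- concentration_index(sv$he_log, sv$consumption, se = "none")$ci
  R <- fractional_rank(sv$consumption)
  mu <- mean(sv$he_log)
  lin <- 2 * 1 * bf_wcov(sv$consumption, R, rep(1, nrow(sv))) / mu
  expect_equal(ci_y, lin, tolerance = 1e-10)
})

test_that("continuous (non-discretized) outcome reproduces the linear model exactly", {
  cfg <- survey_config(n_respondents = 1000, seed = 55, sigma_eps = 0,
                       discretize = FALSE)
  sv <- generate_survey(cfg)
  truth <- attr(sv, "truth")
  X <- as.matrix(sv[names(truth$beta)])
  pred <- truth$alpha + drop(X %*% truth$beta)
  expect_equal(sv$he_log, pred, tolerance = 1e-10)
  expect_false("item1" %in% names(sv))
})

test_that("stratified weights are positive and vary by community", {
  sv <- generate_survey(survey_config(n_respondents = 3000, seed = 56,
                                      weight_scheme = "stratified"))
  expect_true(all(sv$weight > 0))
  expect_gt(sd(sv$weight), 0)
  expect_equal(mean(sv$weight), 1, tolerance = 1e-9)
})

test_that("survey round-trips through CSV with a config sidecar", {
  sv <- small_survey(120, seed = 57)
  path <- file.path(tempdir(), "roundtrip.csv")
  write_survey(sv, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read.csv(path)
  expect_equal(back$he_total, sv$he_total)
  expect_equal(back$consumption, sv$consumption, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$truth$beta$consumption, 0.30)
  unlink(c(path, paste0(path, ".json")))
})

test_that("generator config round-trips through YAML", {
  cfg <- survey_config(n_respondents = 250, seed = 77, sigma_eps = 0.3)
  path <- file.path(tempdir(), "cfg.yaml")
  write_survey_config(cfg, path)
  cfg2 <- read_survey_config(path)
  expect_equal(cfg2$beta, cfg$beta)
  expect_equal(cfg2$sigma_eps, 0.3)
  expect_identical(generate_survey(cfg2)$he_total, generate_survey(cfg)$he_total)
  cfg3 <- read_survey_config(path, seed = 78)
  expect_identical(cfg3$seed, 78L)
  unlink(path)
})
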