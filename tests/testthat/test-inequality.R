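test_that("fractional ranks: midpoints, ties, weighted mean one half", {
  expect_equal(fractional_rank(c(10, 20, 30, 40)), c(1, 3, 5, 7) / 8)
  expect_equal(fractional_rank(c(1, 1, 2)), c(1 / 3, 1 / 3, 5 / 6))
  expect_equal(fractional_rank(rep(7, 5)), rep(0.5, 5))
  set.seed(10)
  for (i in 1:20) {
    x <- sample(1:6, 30, replace = TRUE)
    w <- runif(30, 0.1, 2)
    R <- fractional_rank(x, w)
    expect_true(all(R > 0 & R < 1))
    expect_equal(sum(w * R) / sum(w), 0.5, tolerance = 1e-12)
    expect_true(all(diff(R[order(x)]) >= 0))
  }
  expect_error(fractional_rank(1:5, c(1, 1, 0, 1, 1)), "positive")
})

test_that("concentration index matches brute-force covariance and flips sign", {
  res <- concentration_index(1:4, 1:4)
  expect_equal(res$ci, 0.25, tolerance = 1e-12)
  # constant outcome: zero covariance
  expect_equal(concentration_index(rep(2, 6), 1:6)$ci, 0)
  # antisymmetry in the ranking direction
  set.seed(11)
  y <- rexp(40) + 0.5; r <- rnorm(40)
  expect_equal(concentration_index(y, r, se = "none")$ci,
               -concentration_index(y, -r, se = "none")$ci, tolerance = 1e-12)
  expect_error(concentration_index(c(-2, 0, -1), 1:3), "positive")
})

test_that("CI invariances: scale, translation, replication = weights", {
  set.seed(12)
  y <- rexp(50) + 0.2; r <- runif(50); w <- sample(1:4, 50, replace = TRUE)
  ci <- concentration_index(y, r, w, se = "none")$ci
  # scale invariance
  expect_equal(concentration_index(5 * y, r, w, se = "none")$ci, ci,
               tolerance = 1e-12)
  # translation: ci(y + c) = ci(y) * mu / (mu + c)
  mu <- sum(w * y) / sum(w); cc <- 3
  expect_equal(concentration_index(y + cc, r, w, se = "none")$ci,
               ci * mu / (mu + cc), tolerance = 1e-12)
  # integer weights equal row replication
  idx <- rep(seq_along(y), w)
  expect_equal(concentration_index(y[idx], r[idx], se = "none")$ci, ci,
               tolerance = 1e-12)
})

test_that("bounded-outcome corrections: mirror property and binary identity", {
  set.seed(15)
  y <- sample(0:32, 60, replace = TRUE)
  r <- rnorm(60)
  e1 <- concentration_index(y, r, se = "none", correction = "erreygers",
                            bounds = c(0, 32))$ci_corrected
  # mirrored outcome (offset keeps the plain-CI mean positive)
  e2 <- concentration_index(32 - y + 1e-9, r, se = "none",
                            correction = "erreygers",
                            bounds = c(0, 32 + 1e-9))$ci_corrected
  expect_equal(e1, -e2, tolerance = 1e-6)

  # binary outcome: Wagstaff normalization equals CI / (1 - mu)
  yb <- rbinom(200, 1, 0.4); yb[1] <- 1  # ensure positive mean
  rb <- rnorm(200)
  res <- concentration_index(yb, rb, se = "none", correction = "wagstaff",
                             bounds = c(0, 1))
  expect_equal(res$ci_corrected, res$ci / (1 - res$mu), tolerance = 1e-12)
  expect_error(concentration_index(yb, rb, correction = "erreygers"),
               "bounds")
})

test_that("maximal concentration reaches 1 - 1/n with equal weights", {
  ci <- concentration_index(c(0, 0, 0, 1), 1:4, se = "none")$ci
  expect_equal(ci, 0.75, tolerance = 1e-12)
})

test_that("concentration curve endpoints, diagonal case, extreme case", {
  cur <- concentration_curve(rep(3, 5), 1:5)
  expect_equal(cur$p[1], 0); expect_equal(cur$L[1], 0)
  expect_equal(cur$p[nrow(cur)], 1); expect_equal(cur$L[nrow(cur)], 1)
  expect_equal(cur$L, cur$p, tolerance = 1e-12)  # equality line
  cur2 <- concentration_curve(c(0, 0, 0, 1), 1:4)
  expect_equal(cur2$L[cur2$p == 0.75], 0)
  expect_true(all(diff(cur2$L) >= 0))
})

test_that("curve area and convenient regression agree with the covariance CI", {
  set.seed(13)
  for (i in 1:25) {
    tb <- random_ranked_table(n = sample(5:60, 1), with_ties = i %% 2 == 0)
    res <- concentration_index(tb$y, tb$x, tb$w)
    # independent oracle: brute-force covariance
    R <- fractional_rank(tb$x, tb$w)
    ci_bf <- 2 * bf_wcov(tb$y, R, tb$w) / (sum(tb$w * tb$y) / sum(tb$w))
    expect_equal(res$ci, ci_bf, tolerance = 1e-12)
    # twice the signed area between diagonal and curve
    expect_equal(ci_from_curve(res$curve), res$ci, tolerance = 1e-10)
    # convenient-regression slope
    lhs <- 2 * bf_wcov(R, R, tb$w) * tb$y / (sum(tb$w * tb$y) / sum(tb$w))
    slope <- coef(lm(lhs ~ R, weights = tb$w))["R"]
    expect_equal(unname(slope), res$ci, tolerance = 1e-10)
    expect_gt(res$se, 0)
  }
})

test_that("wagstaff decomposition satisfies adding-up and matches a brute-force oracle", {
  # n = 6 hand-made table
  y <- c(2, 5, 3, 8, 6, 9)
  rank_var <- c(1, 3, 2, 6, 4, 5)
  fac <- data.frame(a = c(0, 1, 0, 1, 1, 1), b = c(1.2, 0.5, 2.0, 1.8, 0.9, 2.5))
  w <- c(1, 2, 1, 1, 2, 1)
  dec <- wagstaff_decomposition(y, rank_var, fac, w)

  # oracle: separate weighted OLS and covariance calls
  fit <- lm(y ~ a + b, data = fac, weights = w)
  R <- fractional_rank(rank_var, w)
  mu <- sum(w * y) / sum(w)
  ci <- 2 * bf_wcov(y, R, w) / mu
  for (nm in c("a", "b")) {
    contrib <- 2 * coef(fit)[nm] * bf_wcov(fac[[nm]], R, w) / mu
    expect_equal(dec$table$contribution[dec$table$factor == nm],
                 unname(contrib), tolerance = 1e-10)
  }
  expect_equal(sum(dec$table$contribution) + dec$residual, dec$ci$ci,
               tolerance = 1e-12)
  expect_equal(sum(dec$table$pct_contribution) + dec$residual_pct, 100,
               tolerance = 1e-8)

  # residual equals the generalized concentration index of the residuals / mu
  expect_equal(dec$residual, 2 * bf_wcov(residuals(fit), R, w) / mu,
               tolerance = 1e-10)
})

test_that("decomposition edge cases: perfect model, null factor, collinearity", {
  y <- c(1, 4, 2, 7, 5, 3)
  dec <- wagstaff_decomposition(y, y, data.frame(x = y))
  expect_equal(dec$table$elasticity, 1, tolerance = 1e-12)
  expect_equal(dec$table$contribution, dec$ci$ci, tolerance = 1e-12)
  expect_equal(dec$residual, 0, tolerance = 1e-12)

  # adding a pure-noise factor with (near) zero coefficient leaves rows stable
  set.seed(14)
  n <- 300
  x1 <- rnorm(n); yy <- 3 + 2 * x1 + rnorm(n, 0, 1e-8) + 10
  z <- rnorm(n)  # independent, coefficient ~ 0
  d1 <- wagstaff_decomposition(yy, x1, data.frame(x1 = x1))
  d2 <- wagstaff_decomposition(yy, x1, data.frame(x1 = x1, z = z))
  expect_equal(d2$table$contribution[d2$table$factor == "x1"],
               d1$table$contribution[d1$table$factor == "x1"], tolerance = 1e-6)
  expect_lt(abs(d2$table$contribution[d2$table$factor == "z"]), 1e-8)

  expect_error(
    wagstaff_decomposition(y, y, data.frame(a = 1:6, b = 2 * (1:6))),
    "collinear")
})

test_that("horizontal inequity reduces to CI for empty or rank-neutral need sets", {
  sv <- small_survey(600, seed = 21)
  fac <- c("consumption", "education_years", "annual_income", "gender")
  dec <- wagstaff_decomposition(sv$he_log, sv$consumption, sv[fac], sv$weight)
  expect_equal(horizontal_inequity(dec, character())$hi, dec$ci$ci)
  hi <- horizontal_inequity(dec, c("gender", "education_years"))
  expect_equal(hi$hi, dec$ci$ci - hi$need_contribution_total, tolerance = 1e-12)
  expect_error(horizontal_inequity(dec, "nope"), "unknown")
})

test_that("subgroup analysis: identical strata agree, constant stratum equals pooled", {
  sv <- small_survey(300, seed = 22)
  sv2 <- rbind(sv, sv)
  sv2$grp <- rep(c("A", "B"), each = nrow(sv))
  fac <- c("consumption", "education_years", "annual_income")
  res <- subgroup_inequality(sv2, "grp", "he_log", "consumption", fac,
                             need_factors = "education_years")
  expect_equal(res$summary$ci[1], res$summary$ci[2], tolerance = 1e-12)
  expect_equal(res$summary$hi[1], res$summary$hi[2], tolerance = 1e-12)

  sv$const <- "all"
  pooled <- concentration_index(sv$he_log, sv$consumption, sv$weight, se = "none")
  res2 <- subgroup_inequality(sv, "const", "he_log", "consumption", fac)
  expect_equal(res2$summary$ci, pooled$ci, tolerance = 1e-12)

  # small strata are skipped with a warning
  sv$tiny <- c("big", rep("rest", nrow(sv) - 1))
  expect_warning(
    subgroup_inequality(sv, "tiny", "he_log", "consumption", fac, min_n = 30),
    "skipped")
})

test_that("bootstrap returns positive spreads and honest intervals", {
  sv <- small_survey(200, seed = 23)
  fac <- c("consumption", "education_years")
  b <- bootstrap_inequality(sv$he_log, sv$consumption, sv[fac],
                            need_factors = "education_years",
                            weights = sv$weight, B = 60, seed = 9)
  expect_gt(b$ci_se, 0)
  expect_gt(b$hi_se, 0)
  expect_lt(b$ci_ci95[1], b$ci_ci95[2])
  b2 <- bootstrap_inequality(sv$he_log, sv$consumption, sv[fac],
                             need_factors = "education_years",
                             weights = sv$weight, B = 60, seed = 9)
  expect_identical(b$draws, b2$draws)
})
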