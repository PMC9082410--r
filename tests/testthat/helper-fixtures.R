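# Shared fixtures: all synthetic, built in code at test time.

# small survey with the default data-generating process
small_survey <- function(n = 400, seed = 42, ...) {
  generate_survey(survey_config(n_respondents = n, seed = seed, ...))
}

# analysis covariates used by the selection stage (age enters squared)
analysis_controls <- function() {
  c("age_sq", "gender", "married", "education_years", "residence",
    "insurance", "health_status", "monthly_income", "annual_income")
}

# random small ranked table for concentration-index oracle checks; at least
# two distinct ranking values so the rank variance is positive
random_ranked_table <- function(n, with_ties = FALSE) {
  repeat {
    x <- if (with_ties) sample(1:max(2, n %/% 2), n, replace = TRUE) else runif(n)
    if (length(unique(x)) >= 2) break
  }
  list(
    y = rexp(n) + 0.1,          # positive outcome
    x = x,
    w = runif(n, 0.2, 3)        # arbitrary positive weights
  )
}

# brute-force weighted population covariance (independent of package helpers)
bf_wcov <- function(a, b, w) {
  W <- sum(w)
  ma <- sum(w * a) / W
  mb <- sum(w * b) / W
  sum(w * (a - ma) * (b - mb)) / W
}

# design with an orthonormal column block: t(X) %*% X / n = I
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  raw <- matrix(rnorm(n * p), n, p)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))               # orthonormal columns, t(Q) Q = I
  X <- q * sqrt(n)                 # now crossprod(X)/n = I, columns centered
  colnames(X) <- paste0("x", seq_len(p))
  X
}
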