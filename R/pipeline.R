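#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: input (CSV path or generator
#' config), outcome and ranking choices, need factors for the inequity
#' standardization, Lasso settings, bootstrap draws, and output directory.
#' All randomness derives from one root seed split into per-stage substreams.
#'
#' @param input Path to a survey CSV, or `NULL` to simulate.
#' @param generator A [survey_config()] used when `input` is `NULL`.
#' @param outcome `"log_total"` (default) or `"total"`.
#' @param ranking `"consumption"` (default) or `"annual_income"`.
#' @param need_factors Need factors for the horizontal-inequity
#'   standardization; default gender, education years, health status, age
#'   (entering as age squared).
#' @param fixed_effects `"none"` (default), `"city"` or `"community"`:
#'   one-hot blocks appended to the controls, unpenalized in OLS and given
#'   zero penalty loadings in the Lasso steps.
#' @param n_folds,grid_size,rule Lasso CV settings.
#' @param bootstrap Bootstrap draws for CI/HI uncertainty (0 = off).
#' @param subgroup_by Column defining strata for the subgroup table
#'   (default `"annual_income_3"`, annual income collapsed to
#'   low/middle/higher).
#' @param outdir Output directory (created if needed).
#' @param seed Root seed.
#' @param figures Write PNG figures (default `TRUE`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = survey_config(),
                            outcome = c("log_total", "total"),
                            ranking = c("consumption", "annual_income"),
                            need_factors = c("gender", "education_years",
                                             "health_status", "age_sq"),
                            fixed_effects = c("none", "city", "community"),
                            n_folds = 10, grid_size = 50, rule = "min",
                            bootstrap = 0,
                            subgroup_by = "annual_income_3",
                            outdir = tempfile("healthineq_run_"),
                            seed = 1L, figures = TRUE) {
  structure(list(
    input = input, generator = generator,
    outcome = match.arg(outcome), ranking = match.arg(ranking),
    need_factors = need_factors,
    fixed_effects = match.arg(fixed_effects),
    n_folds = n_folds, grid_size = grid_size, rule = rule,
    bootstrap = bootstrap, subgroup_by = subgroup_by,
    outdir = outdir, seed = as.integer(seed), figures = figures
  ), class = "pipeline_config")
}

survey_schema <- function() {
  list(
    items = paste0("item", 1:4),
    cons = paste0("cons_", 1:5),
    covariates = c("age", "age_sq", "gender", "married", "education_years",
                   "residence", "insurance", "health_status",
                   "monthly_income", "annual_income"),
    domains = list(
      gender = 0:1, married = 0:1, residence = 0:1, insurance = 0:1,
      health_status = 1:5
    )
  )
}

#' Validate a survey table
#'
#' Enforces the row-level invariants (items integer in 0..8 summing to the
#' stored total, strictly positive weights, categorical codes within their
#' domains); violating rows are dropped and counted per reason. More than
#' half the rows dropping is treated as a schema mismatch and raises an
#' error.
#'
#' @param x Data frame or path to a CSV file.
#' @return List with `data` (clean rows), `drop_report` (data frame of
#'   reason/count), `n_read`, `n_kept`.
#' @export
validate_survey <- function(x) {
  df <- if (is.character(x)) read.csv(x, check.names = TRUE) else as.data.frame(x)
  sc <- survey_schema()
  needed <- c("he_total", "he_log", sc$cons, sc$covariates)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema mismatch, missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n_read <- nrow(df)
  if (!"weight" %in% names(df)) df$weight <- 1
  bad <- list()
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    bad[[reason]] <<- cond
  }
  if (all(sc$items %in% names(df))) {
    it <- as.matrix(df[sc$items])
    flag(apply(it < 0 | it > 8 | it != round(it), 1, any), "item out of range")
    flag(abs(rowSums(it) - df$he_total) > 1e-8, "item sum != total")
  }
  flag(df$weight <= 0, "non-positive weight")
  for (nm in names(sc$domains)) {
    flag(!(df[[nm]] %in% sc$domains[[nm]]), sprintf("%s outside domain", nm))
  }
  any_bad <- Reduce(`|`, bad, rep(FALSE, n_read))
  drop_report <- data.frame(
    reason = names(bad),
    n = vapply(bad, sum, integer(1)),
    row.names = NULL
  )
  drop_report <- drop_report[drop_report$n > 0, , drop = FALSE]
  kept <- df[!any_bad, , drop = FALSE]
  if (nrow(kept) < n_read / 2) {
    stop(sprintf("more than 50%% of rows invalid (%d of %d): probable schema mismatch",
                 n_read - nrow(kept), n_read), call. = FALSE)
  }
  list(data = kept, drop_report = drop_report,
       n_read = n_read, n_kept = nrow(kept))
}

fe_dummies <- function(values, prefix) {
  lv <- sort(unique(values))
  m <- sapply(lv[-1], function(v) as.numeric(values == v))  # first level = reference
  colnames(m) <- paste0(prefix, "_", lv[-1])
  m
}

#' Run the full analysis pipeline
#'
#' Simulate (or load and validate) the survey, rebuild the consumption
#' composite and health-education scores, run OLS and post-double-selection
#' Lasso for the consumption effect, estimate the concentration index,
#' horizontal inequity and Wagstaff decomposition (decomposition covariates =
#' exposure plus the Lasso-selected controls), the subgroup table, and write
#' all reports into the output directory: `survey.csv` (if simulated),
#' `results.json`, `regression_table.csv`, `decomposition_table.csv`,
#' `subgroup_table.csv`, `reliability.json`, `manifest.json`, and figures.
#' `results.json` contains no timestamps, so identical (config, seed) runs
#' produce byte-identical result bundles.
#'
#' @param config A [pipeline_config()].
#' @return The results list, invisibly (also serialized to
#'   `results.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("healthineq")),
                   seed = config$seed, stages = list(), failed_stage = NULL)
  finalize_manifest <- function() {
    manifest$started <- format(t0, "%Y-%m-%dT%H:%M:%S%z")
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  stage <- "input"
  on.exit({
    manifest$failed_stage <- if (identical(stage, "done")) NULL else stage
    finalize_manifest()
  })

  ## stage: input -------------------------------------------------------
  if (is.null(config$input)) {
    gen <- config$generator
    gen$seed <- substream_seed(config$seed, 1)
    data <- generate_survey(gen)
    write_survey(data, file.path(config$outdir, "survey.csv"))
    drop_report <- data.frame(reason = character(), n = integer())
    n_read <- nrow(data)
  } else {
    val <- validate_survey(config$input)
    data <- val$data
    drop_report <- val$drop_report
    n_read <- val$n_read
  }
  manifest$stages$input <- list(rows_read = n_read, rows_dropped = n_read - nrow(data),
                                rows_analyzed = nrow(data))

  ## stage: scores ------------------------------------------------------
  stage <- "scores"
  comp <- pca_composite(data[survey_schema()$cons])
  data$consumption <- comp$standardized_scores
  reliability <- list(
    cronbach_alpha = comp$cronbach_alpha,
    loadings = as.list(comp$loadings),
    explained_variance_ratio = comp$explained_variance_ratio
  )
  jsonlite::write_json(reliability, file.path(config$outdir, "reliability.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outcome_col <- if (config$outcome == "log_total") "he_log" else "he_total"
  ranking_col <- if (config$ranking == "consumption") "consumption" else "annual_income"

  ## stage: selection ---------------------------------------------------
  stage <- "selection"
  controls <- setdiff(survey_schema()$covariates, "age")  # age enters squared
  pf <- rep(1, length(controls))
  ctrl_mat <- as.matrix(data[controls])
  if (config$fixed_effects != "none") {
    fe <- fe_dummies(data[[config$fixed_effects]], config$fixed_effects)
    ctrl_mat <- cbind(ctrl_mat, fe)
    pf <- c(pf, rep(0, ncol(fe)))  # fixed-effect blocks are never penalized
  }
  ols <- ols_fit(cbind(consumption = data$consumption, ctrl_mat),
                 data[[outcome_col]])
  des <- structure(list(
    y = data[[outcome_col]], exposure = data$consumption,
    controls = ctrl_mat, weights = NULL, std = std_record(ctrl_mat),
    outcome_name = outcome_col, exposure_name = "consumption",
    control_names = colnames(ctrl_mat)
  ), class = "design_matrix")
  pds <- post_double_selection(des, n_folds = config$n_folds,
                               grid_size = config$grid_size,
                               fold_seed = substream_seed(config$seed, 2),
                               rule = config$rule)
  reg_tab <- regression_table(ols, pds)
  write.csv(reg_tab, file.path(config$outdir, "regression_table.csv"),
            row.names = FALSE)

  ## stage: inequality --------------------------------------------------
  stage <- "inequality"
  y <- data[[outcome_col]]
  rk <- data[[ranking_col]]
  w <- data$weight
  cres <- concentration_index(y, rk, w, ranking_name = config$ranking)
  decomp_factors <- unique(c("consumption",
                             intersect(pds$selected_controls, names(data))))
  dec <- wagstaff_decomposition(y, rk, data[decomp_factors], w)
  need <- intersect(config$need_factors, decomp_factors)
  hi <- horizontal_inequity(dec, need)
  write.csv(dec$table, file.path(config$outdir, "decomposition_table.csv"),
            row.names = FALSE)

  boot <- NULL
  if (config$bootstrap > 0) {
    boot <- bootstrap_inequality(y, rk, data[decomp_factors], need, w,
                                 B = config$bootstrap,
                                 seed = substream_seed(config$seed, 3))
  }

  ## stage: subgroup ----------------------------------------------------
  stage <- "subgroup"
  data$annual_income_3 <- cut(data$annual_income, c(0, 2, 4, 6),
                              labels = c("low", "middle", "higher"))
  sub <- tryCatch(
    subgroup_inequality(data, config$subgroup_by, outcome_col, ranking_col,
                        decomp_factors, need, weights = "weight"),
    error = function(e) NULL)
  if (!is.null(sub)) {
    write.csv(sub$summary, file.path(config$outdir, "subgroup_table.csv"),
              row.names = FALSE)
    write.csv(sub$quartile_table,
              file.path(config$outdir, "subgroup_quartiles.csv"),
              row.names = FALSE)
  }

  ## stage: report ------------------------------------------------------
  stage <- "report"
  results <- list(
    seed = config$seed,
    n = nrow(data),
    outcome = config$outcome,
    ranking = config$ranking,
    reliability = reliability,
    ols = list(coefficients = as.list(ols$coefficients),
               robust_se = as.list(ols$se), adj_r2 = ols$adj_r2),
    post_double = list(
      exposure_coefficient = unname(pds$exposure_coefficient),
      standard_error = unname(pds$standard_error),
      selected_controls = pds$selected_controls,
      selected_lambda_outcome = if (!is.null(pds$step_outcome)) pds$step_outcome$selected_lambda,
      selected_lambda_exposure = if (!is.null(pds$step_exposure)) pds$step_exposure$selected_lambda),
    concentration = list(ci = cres$ci, se = cres$se, ci95 = cres$ci95,
                         mu = cres$mu),
    decomposition = list(table = dec$table, residual = dec$residual,
                         residual_pct = dec$residual_pct),
    horizontal_inequity = list(hi = hi$hi, need_factors = hi$need_factors,
                               need_contribution_total = hi$need_contribution_total),
    bootstrap = if (!is.null(boot)) boot[c("ci_se", "hi_se", "ci_ci95", "hi_ci95")],
    subgroup = if (!is.null(sub)) list(summary = sub$summary,
                                       quartiles = sub$quartile_table)
  )
  jsonlite::write_json(results, file.path(config$outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)

  if (isTRUE(config$figures)) {
    stage <- "figures"
    tryCatch(write_figures(config$outdir, data, cres, dec, pds, outcome_col),
             error = function(e) warning("figure generation failed: ",
                                         conditionMessage(e)))
  }

  manifest$config_hash <- unname(tools::md5sum(file.path(config$outdir, "results.json")))
  stage <- "done"
  invisible(results)
}

## two-column regression report (OLS vs post-double-selection), with
## significance stars at 0.05 / 0.01 / 0.001
regression_table <- function(ols, pds) {
  stars <- function(p) as.character(cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                                        labels = c("***", "**", "*", "")))
  nm <- names(ols$coefficients)
  pd_coef <- pds$ols_coefficients[nm]
  pd_se <- rep(NA_real_, length(nm))
  pd_se[match(names(pds$final$se), nm)] <- pds$final$se
  data.frame(
    term = nm,
    ols = unname(ols$coefficients),
    ols_se = unname(ols$se),
    ols_sig = stars(ols$p_value),
    post_double = unname(pd_coef),
    post_double_se = pd_se,
    row.names = NULL
  )
}
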