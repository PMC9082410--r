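#' Min-max standardization to the unit interval
#'
#' Rescales values by `(v - min) / (max - min)`, the convention used for
#' asset/consumption composites so that a score near 1 marks the
#' highest-consumption households. The transform is strictly increasing and
#' affine, so it preserves ranks (and therefore every rank-based inequality
#' measure downstream).
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Numeric vector in `[0, 1]` with minimum exactly 0 and maximum 1.
#' @export
#' @examples
#' minmax_standardize(c(2, 4, 6))
minmax_standardize <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("values must be finite numeric", call. = FALSE)
  }
  r <- range(values)
  if (r[2] - r[1] <= 0) {
    stop("degenerate range: all values are equal, cannot min-max standardize",
         call. = FALSE)
  }
  (values - r[1]) / (r[2] - r[1])
}

#' Health-education score from four item responses
#'
#' Each of the four health-education items (community health education,
#' pandemic-prevention education, psychological self-report, infectious-illness
#' education) is scored 1-8, with "do not know" coded 0, so the total runs
#' 0-32. Because 0 totals occur, the log transform is `ln(1 + total)`.
#'
#' @param items Integer matrix or data frame with 4 columns, entries in 0..8.
#' @return A data frame with columns `total` (0-32) and `log_total`.
#' @export
health_education_score <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 4) stop("exactly 4 item columns are required", call. = FALSE)
  bad <- which(!is.finite(items) | items < 0 | items > 8 | items != round(items),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("item score outside {0,...,8} at row %d", bad[1, 1]),
         call. = FALSE)
  }
  total <- as.integer(rowSums(items))
  data.frame(total = total, log_total = log1p(total))
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = K/(K-1) * (1 - sum(item variances) / var(row sums))` with sample
#' (n-1) variances. For K equicorrelated items with common correlation r the
#' population value is `K*r / (1 + (K-1)*r)`.
#'
#' @param item_matrix Numeric matrix/data frame, rows = respondents,
#'   columns = K >= 2 items, no missing values.
#' @return Scalar alpha (<= 1; can be negative for inconsistent items).
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  if (ncol(x) < 2) stop("at least 2 items are required", call. = FALSE)
  if (nrow(x) < 2) stop("at least 2 rows are required", call. = FALSE)
  if (any(!is.finite(x))) stop("missing or non-finite item values", call. = FALSE)
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var <= 0) {
    stop("zero total-score variance: reliability undefined", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' First-principal-component composite index
#'
#' Standard construction for a household consumption (or asset) index:
#' columns are z-scored, the first eigenvector of the correlation matrix
#' supplies the weights, and the resulting score is min-max standardized to
#' `[0, 1]`. The sign convention makes the largest-magnitude loading positive,
#' so the index is invariant to column order and to any positive affine
#' rescaling of an input dimension.
#'
#' @param item_matrix Numeric matrix/data frame, rows x D dimensions
#'   (D >= 1, at least D+1 rows, no constant column).
#' @return An object of class `composite_index`: `loadings` (unit norm),
#'   `explained_variance_ratio`, `cronbach_alpha` (NA when D = 1),
#'   `raw_scores`, `standardized_scores` in `[0, 1]`.
#' @export
pca_composite <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("dim", seq_len(ncol(x)))
  if (nrow(x) < ncol(x) + 1) stop("need at least D+1 rows", call. = FALSE)
  if (any(!is.finite(x))) stop("missing or non-finite values", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds <= 0)) {
    stop(sprintf("degenerate input: column '%s' is constant",
                 colnames(x)[which(sds <= 0)[1]]), call. = FALSE)
  }
  z <- scale(x)
  cr <- cor(x)
  e <- eigen(cr, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  raw <- drop(z %*% v)
  structure(list(
    loadings = setNames(v, colnames(x)),
    explained_variance_ratio = e$values[1] / sum(e$values),
    cronbach_alpha = if (ncol(x) >= 2) cronbach_alpha(x) else NA_real_,
    raw_scores = raw,
    standardized_scores = minmax_standardize(raw)
  ), class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  cat("Composite index (first principal component)\n")
  cat(sprintf("  dimensions: %d, explained variance ratio: %.3f\n",
              length(x$loadings), x$explained_variance_ratio))
  if (is.finite(x$cronbach_alpha)) {
    cat(sprintf("  Cronbach's alpha: %.3f\n", x$cronbach_alpha))
  }
  cat("  loadings:\n")
  print(round(x$loadings, 4))
  invisible(x)
}

#' Empirical quantile groups
#'
#' Assigns labels `1..n_groups` by quantile cut-points computed on the
#' *distinct* values, with observations equal to a cut-point assigned to the
#' lower group (the tie-to-lower rule used for the income groupings).
#'
#' @param values Numeric vector.
#' @param n_groups Number of groups (>= 2, at most the number of distinct values).
#' @return Integer vector of group labels in `1..n_groups`.
#' @export
#' @examples
#' quantile_group(c(1, 1, 2, 3), 2)  # 1 1 1 2
quantile_group <- function(values, n_groups) {
  if (n_groups < 2) stop("n_groups must be >= 2", call. = FALSE)
  if (length(values) < n_groups) stop("fewer rows than groups", call. = FALSE)
  ux <- sort(unique(values))
  if (length(ux) < 2) stop("infeasible grouping: all values are equal", call. = FALSE)
  if (n_groups > length(ux)) {
    stop("infeasible grouping: n_groups exceeds the number of distinct values",
         call. = FALSE)
  }
  cuts <- quantile(ux, probs = seq_len(n_groups - 1) / n_groups, names = FALSE)
  labels <- 1L + rowSums(outer(values, cuts, ">"))
  as.integer(labels)
}
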