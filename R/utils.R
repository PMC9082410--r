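#' @useDynLib healthineq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm pnorm qnorm quantile rnorm runif sd var
#'   complete.cases predict setNames rhyper weighted.mean model.matrix
#'   residuals fitted vcov uniroot
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## weighted population moments (denominator W, not W-1): the concentration
## index literature uses population covariances so the adding-up identity of
## the decomposition holds exactly
wmean <- function(x, w) sum(w * x) / sum(w)

wcov <- function(x, y, w) {
  W <- sum(w)
  sum(w * (x - wmean(x, w)) * (y - wmean(y, w))) / W
}

wvar <- function(x, w) wcov(x, x, w)

check_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("weights must have one entry per row", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be strictly positive and finite", call. = FALSE)
  }
  w
}

## deterministic per-stage seed derived from a root seed; kept within 32-bit
## integer range
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}

## run code with a locally-set RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
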