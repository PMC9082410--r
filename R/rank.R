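#' Weighted fractional ranks
#'
#' Midpoint fractional rank of each observation in the (weighted) distribution
#' of a socioeconomic ranking variable: sort by the ranking variable and set
#' `R_i = (cumulative weight before i + w_i/2) / W`. All members of a tied
#' block share the block's midpoint rank, so ranks lie strictly inside (0, 1)
#' and their weighted mean is exactly 1/2.
#'
#' @param ranking_variable Numeric vector (the living-standards measure).
#' @param weights Optional strictly positive sampling weights.
#' @return Numeric vector of ranks in (0, 1).
#' @export
#' @examples
#' fractional_rank(c(10, 20, 30, 40))        # 0.125 0.375 0.625 0.875
#' fractional_rank(c(1, 1, 2))               # 1/3 1/3 5/6
fractional_rank <- function(ranking_variable, weights = NULL) {
  x <- ranking_variable
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("ranking variable must be finite", call. = FALSE)
  w <- check_weights(weights, n)
  ord <- order(x)
  xs <- x[ord]
  ws <- w[ord]
  W <- sum(ws)
  cw <- cumsum(ws)
  block <- cumsum(c(TRUE, xs[-1] != xs[-n]))           # run id of tied blocks
  cw_end <- cw[!duplicated(block, fromLast = TRUE)]    # cum weight at block end
  cw_before <- c(0, cw_end[-length(cw_end)])
  mid <- (cw_before + cw_end) / 2
  R <- numeric(n)
  R[ord] <- mid[block] / W
  R
}
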