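#' Normality-gated correlation
#'
#' Correlation with the test chosen by a Shapiro-Wilk normality gate at
#' `alpha`: if both variables are consistent with normality the coefficient
#' is Pearson's r, otherwise Spearman's rho. Shapiro-Wilk is limited to 5000
#' observations, so larger inputs are gated on a deterministic evenly-spaced
#' subsample of 5000 points (the correlation itself always uses all points).
#'
#' @param x,y numeric vectors of equal length (pairs with missing values are
#'   dropped)
#' @param alpha normality-gate level, default 0.05
#' @return list with `r`, `p`, `test_used` (`"pearson"`/`"spearman"`), `n`
#' @export
gated_correlation <- function(x, y, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs for a correlation")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a correlation variable")
  gate <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    if (length(v) > 5000)
      v <- v[round(seq(1, length(v), length.out = 5000))]
    shapiro.test(v)$p.value > alpha
  }
  method <- if (gate(x) && gate(y)) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, test_used = method, n = n)
}
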