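#' Pearson correlation t-test
#'
#' The worked-example statistic used when reporting correlations such as
#' average geographic distance vs. range size or vs. species age: given a
#' correlation `r` on `df = n - 2` degrees of freedom,
#' `t = r sqrt(df) / sqrt(1 - r^2)` with a two-sided Student-t p-value.
#' Either supply `r` and `df` directly, or a data frame plus two column
#' names, in which case `r` is computed first.
#'
#' With |r| = 1 the statistic is infinite and the p-value 0 by convention.
#'
#' @param data Optional data frame.
#' @param x,y Column names (strings) in `data`; used when `data` is given.
#' @param r Pearson correlation (when `data` is not given).
#' @param df Degrees of freedom, `n - 2`.
#' @return Tibble: `r`, `df`, `statistic` (t), `p.value`.
#' @examples
#' correlation_test(r = 0.0428, df = 24)
#' @export
correlation_test <- function(data = NULL, x = NULL, y = NULL, r = NULL, df = NULL) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data), is.character(x), is.character(y))
    xv <- data[[x]]; yv <- data[[y]]
    keep <- complete.cases(xv, yv)
    xv <- xv[keep]; yv <- yv[keep]
    if (length(xv) < 3) abort("need at least 3 complete pairs")
    r <- cor(xv, yv)
    df <- length(xv) - 2L
  }
  if (is.null(r) || is.null(df)) abort("supply either data + columns, or r and df")
  stopifnot(df >= 1)
  if (abs(r) > 1) abort("|r| must be <= 1")
  if (abs(r) == 1) {
    return(tibble::tibble(r = r, df = as.integer(df),
                          statistic = sign(r) * Inf, p.value = 0))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  tibble::tibble(r = r, df = as.integer(df), statistic = t,
                 p.value = 2 * pt(-abs(t), df))
}
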