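#' Jarque-Bera normality statistic
#'
#' JB = m/6 * (S^2 + (K - 3)^2 / 4), where m is the sample size, S the
#' sample skewness and K the sample kurtosis (population-moment
#' definitions). Under normality JB is asymptotically chi-square with 2
#' degrees of freedom.
#'
#' @param x numeric sample.
#' @return list with `statistic` and `p_value`.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  m <- length(x)
  if (m < 4) stop("need at least 4 observations", call. = FALSE)
  cx <- x - mean(x)
  m2 <- mean(cx^2)
  if (m2 == 0) return(list(statistic = Inf, p_value = 0))
  S <- mean(cx^3) / m2^1.5
  K <- mean(cx^4) / m2^2
  jb <- m / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Significance of trained models against a null distribution
#'
#' Compares the MSEs of models trained on real data against the MSE
#' distribution of models trained on randomized data or randomized
#' networks. With `method = "zscore"` each real MSE gets a one-sided
#' normal-tail p-value from the null mean and sd (a real MSE equal to the
#' null mean gives p = 0.5). With `method = "empirical"` the p-value is the
#' fraction of null MSEs at or below the real MSE; when that fraction is
#' zero the p-value is reported as the upper bound 1/|null| (flagged in the
#' `upper_bound` column). With `method = "auto"` a Jarque-Bera test on the
#' null sample (alpha 0.001) decides: a normal-looking null uses the
#' z-score, otherwise the empirical count.
#'
#' @param real_mses MSEs of models trained on the real data.
#' @param null_mses MSEs of models trained on the randomized controls.
#' @param method `"auto"`, `"zscore"` or `"empirical"`.
#' @param alpha normality cutoff for `"auto"` (default 0.001).
#' @return data.frame with one row per real model: `real_mse`, `p`,
#'   `method`, `upper_bound`.
#' @export
significance_vs_null <- function(real_mses, null_mses,
                                 method = c("auto", "zscore", "empirical"),
                                 alpha = 0.001) {
  method <- match.arg(method)
  null_mses <- null_mses[!is.na(null_mses)]
  if (!length(null_mses)) stop("empty null distribution", call. = FALSE)
  if (method == "auto") {
    jb <- jarque_bera(null_mses)
    method <- if (jb$p_value >= alpha) "zscore" else "empirical"
  }
  if (method == "zscore") {
    s <- stats::sd(null_mses)
    if (is.na(s) || s == 0) stop("degenerate null (sd = 0) under zscore method",
                                 call. = FALSE)
    p <- stats::pnorm(real_mses, mean = mean(null_mses), sd = s)
    ub <- rep(FALSE, length(real_mses))
  } else {
    cnt <- vapply(real_mses, function(r) sum(null_mses <= r), 0)
    ub <- cnt == 0
    p <- ifelse(ub, 1 / length(null_mses), cnt / length(null_mses))
  }
  data.frame(real_mse = real_mses, p = p, method = method, upper_bound = ub)
}
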