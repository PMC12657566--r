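#' Convert Cohen's f to partial eta squared
#'
#' `eta_p^2 = f^2 / (1 + f^2)`.
#'
#' @param f Cohen's f, non-negative
#' @return partial eta squared in \[0, 1)
#' @export
f_to_eta2p <- function(f) {
  if (any(!is.numeric(f)) || any(f < 0)) stop_param("f must be non-negative")
  f^2 / (1 + f^2)
}

#' Partial eta squared from Cohen's f: inverse conversion
#' @param eta2p partial eta squared in \[0, 1)
#' @return Cohen's f
#' @export
eta2p_to_f <- function(eta2p) {
  if (any(eta2p < 0) || any(eta2p >= 1)) stop_param("eta2p must lie in [0, 1)")
  sqrt(eta2p / (1 - eta2p))
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`, the standard identity for reporting
#' ANOVA effect sizes from the test statistic alone.
#'
#' @param F F statistic, non-negative
#' @param df1 numerator degrees of freedom (>= 1)
#' @param df2 denominator degrees of freedom (>= 1)
#' @return partial eta squared
#' @export
eta2p_from_F <- function(F, df1, df2) {
  if (any(F < 0)) stop_param("F must be non-negative")
  if (any(df1 < 1) || any(df2 < 1)) stop_param("degrees of freedom must be >= 1")
  F * df1 / (F * df1 + df2)
}

#' Kendall's W from a Friedman chi-squared statistic
#'
#' `W = chi2 / (n (k - 1))`, the concordance effect size of the Friedman
#' test with `n` subjects and `k` conditions; capped at 1.
#'
#' @param chi2 Friedman chi-squared statistic, non-negative
#' @param n number of subjects (>= 2)
#' @param k number of conditions (>= 2)
#' @return Kendall's W in \[0, 1\]
#' @export
kendalls_w <- function(chi2, n, k) {
  if (any(chi2 < 0)) stop_param("chi2 must be non-negative")
  if (any(n < 2) || any(k < 2)) stop_param("need n >= 2 subjects and k >= 2 conditions")
  pmin(chi2 / (n * (k - 1)), 1)
}
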