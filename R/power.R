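# Analytic power for two-sample MR, normal-approximation (mRnd-style).

#' Power of two-sample MR with a binary outcome
#'
#' Normal-approximation power on the log odds ratio scale:
#' `power = Phi( sqrt(N R2 K (1 - K)) |ln OR| - z_{1 - alpha/2} )`,
#' where `N` is the outcome-study sample size, `K` its case fraction and
#' `R2` the proportion of exposure variance explained by the instruments.
#' At `OR = 1` this returns `alpha / 2` (the one tail in the direction of
#' the hypothesized effect).
#'
#' @param n Outcome-study sample size (cases + controls).
#' @param case_fraction Case fraction `K` in (0, 1).
#' @param r2 Variance of the exposure explained by the instruments.
#' @param or Causal odds ratio to detect.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\], unrounded; round to the reporting precision at
#'   the presentation layer.
#' @export
mr_power_binary <- function(n, case_fraction, r2, or, alpha = 0.05) {
  if (any(case_fraction <= 0 | case_fraction >= 1)) {
    stop("case_fraction must lie in (0, 1)")
  }
  if (any(n <= 0) || any(r2 < 0 | r2 >= 1) || any(or <= 0)) {
    stop("need n > 0, r2 in [0, 1), or > 0")
  }
  z <- qnorm(1 - alpha / 2)
  ncp <- sqrt(n * r2 * case_fraction * (1 - case_fraction)) * abs(log(or))
  pnorm(ncp - z)
}

#' Power of two-sample MR with a continuous outcome
#'
#' Companion to [mr_power_binary()] for standardized continuous traits:
#' `power = Phi( sqrt(N R2) |beta| - z_{1 - alpha/2} )`.
#'
#' @param n Outcome-study sample size.
#' @param r2 Variance of the exposure explained by the instruments.
#' @param beta Standardized causal effect to detect.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\], unrounded.
#' @export
mr_power_continuous <- function(n, r2, beta, alpha = 0.05) {
  if (any(n <= 0) || any(r2 < 0 | r2 >= 1)) stop("need n > 0, r2 in [0, 1)")
  z <- qnorm(1 - alpha / 2)
  pnorm(sqrt(n * r2) * abs(beta) - z)
}
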