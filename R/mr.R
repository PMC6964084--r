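# Two-sample MR estimators: Wald ratios, fixed-effect IVW, MR-Egger,
# Cochran's Q heterogeneity, odds-ratio transforms.

.z95 <- function() qnorm(0.975)

#' Per-SNP Wald ratio estimate
#'
#' The ratio of outcome to exposure effect, with first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (uncertainty in the
#' exposure beta is ignored at first order, adequate for strong
#' instruments).
#'
#' @param beta_exposure,beta_outcome,se_outcome Harmonized per-SNP effects;
#'   vectorized. Alternatively pass a `harmonized_pairs` table as the single
#'   first argument.
#' @return A data.frame with columns `beta` and `se`.
#' @export
ratio_estimate <- function(beta_exposure, beta_outcome, se_outcome) {
  if (is.data.frame(beta_exposure)) {
    pairs <- kept_pairs(beta_exposure)
    beta_outcome <- pairs$beta_outcome
    se_outcome <- pairs$se_outcome
    beta_exposure <- pairs$beta_exposure
  }
  if (any(beta_exposure == 0)) stop("beta_exposure must be nonzero for a Wald ratio")
  data.frame(beta = beta_outcome / beta_exposure,
             se = se_outcome / abs(beta_exposure))
}

#' Cochran's Q heterogeneity of Wald ratios
#'
#' `Q = sum(w_j (ratio_j - beta_ref)^2)` with IVW weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2`, compared to a chi-square with
#' `n - 1` degrees of freedom. Substantial heterogeneity among instruments
#' is suggestive of pleiotropy.
#'
#' @param pairs A `harmonized_pairs` table with at least 2 usable SNPs.
#' @param beta_ref Reference causal estimate, typically the IVW estimate.
#' @return A list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, beta_ref) {
  pairs <- kept_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2) stop("Cochran's Q needs at least 2 SNPs")
  w <- pairs$beta_exposure^2 / pairs$se_outcome^2
  r <- pairs$beta_outcome / pairs$beta_exposure
  q <- sum(w * (r - beta_ref)^2)
  df <- n - 1L
  list(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Exponentiate a log effect to an odds ratio with 95% CI
#'
#' @param beta Log odds ratio.
#' @param se Its standard error (> 0).
#' @return A list with `or`, `ci_low`, `ci_high`.
#' @export
to_or <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0")
  z <- .z95()
  list(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

mr_result <- function(method, beta, se, pval, n_snps, q = NULL,
                      egger = NULL, random_effects = FALSE,
                      ci_low = NULL, ci_high = NULL) {
  if (is.null(ci_low)) ci_low <- beta - .z95() * se
  if (is.null(ci_high)) ci_high <- beta + .z95() * se
  res <- list(
    method = method,
    beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pval = pval,
    or = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    n_snps = n_snps,
    q_stat = if (is.null(q)) NA_real_ else q$q,
    q_df = if (is.null(q)) NA_integer_ else q$df,
    q_pval = if (is.null(q)) NA_real_ else q$pval,
    random_effects = random_effects
  )
  if (!is.null(egger)) res <- c(res, egger)
  class(res) <- "mr_result"
  res
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW over per-SNP Wald ratios: weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2`, estimate
#' `sum(w_j ratio_j) / sum(w_j)`, standard error `1 / sqrt(sum(w_j))`
#' (algebraically, the zero-intercept weighted least-squares slope of the
#' outcome betas on the exposure betas with weights `1 / se_outcome^2`).
#' Fixed effects are the default because upstream instrument selection
#' enforces homogeneity; `random_effects = TRUE` inflates the standard
#' error by `sqrt(Q / df)` when Q exceeds its degrees of freedom
#' (multiplicative random effects).
#'
#' @param pairs A `harmonized_pairs` table with at least one usable SNP and
#'   no zero exposure beta.
#' @param random_effects Use the multiplicative random-effects variant.
#' @return An `mr_result` with the estimate on the log scale, 95% CI,
#'   two-sided normal p-value, odds-ratio scale, and Cochran's Q.
#' @export
mr_ivw <- function(pairs, random_effects = FALSE) {
  pairs <- kept_pairs(pairs)
  n <- nrow(pairs)
  if (n < 1) stop("mr_ivw needs at least 1 SNP")
  if (any(pairs$beta_exposure == 0)) stop("zero exposure beta among instruments")
  w <- pairs$beta_exposure^2 / pairs$se_outcome^2
  r <- pairs$beta_outcome / pairs$beta_exposure
  beta <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- if (n >= 2) cochran_q(pairs, beta) else NULL
  if (random_effects && !is.null(q) && q$df > 0) {
    se <- se * max(1, sqrt(q$q / q$df))
  }
  pval <- 2 * pnorm(-abs(beta / se))
  mr_result("ivw", beta, se, pval, n, q = q, random_effects = random_effects)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' unconstrained intercept, each pair first oriented so the exposure beta is
#' non-negative. The slope is the causal estimate; the intercept estimates
#' the average directional pleiotropic effect, and its two-sided test is the
#' MR-Egger pleiotropy test. Standard errors are residual-scaled
#' (multiplicative random effects) and inference uses a t reference with
#' `n - 2` degrees of freedom, following the usual MR-Egger formulation.
#'
#' @param pairs A `harmonized_pairs` table with at least 3 usable SNPs.
#' @param intercept `FALSE` constrains the intercept to zero with
#'   fixed-effect standard errors, a validation mode that reproduces
#'   [mr_ivw()] exactly.
#' @return An `mr_result` with slope, intercept (`egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pval`) and Q on `n - 2` degrees
#'   of freedom.
#' @export
mr_egger <- function(pairs, intercept = TRUE) {
  pairs <- kept_pairs(pairs)
  n <- nrow(pairs)
  if (intercept && n < 3) {
    stop("mr_egger needs at least 3 SNPs to identify slope and intercept")
  }
  if (any(pairs$beta_exposure == 0)) stop("zero exposure beta among instruments")
  s <- ifelse(pairs$beta_exposure < 0, -1, 1)
  bx <- pairs$beta_exposure * s
  by <- pairs$beta_outcome * s
  w <- 1 / pairs$se_outcome^2

  if (!intercept) {
    fit <- lm(by ~ 0 + bx, weights = w)
    beta <- unname(coef(fit)[["bx"]])
    se <- 1 / sqrt(sum(w * bx^2))
    pval <- 2 * pnorm(-abs(beta / se))
    rss <- sum(w * residuals(fit)^2)
    q <- list(q = rss, df = n - 1L, pval = pchisq(rss, n - 1L, lower.tail = FALSE))
    return(mr_result("egger", beta, se, pval, n, q = q,
                     egger = list(egger_intercept = 0,
                                  egger_intercept_se = NA_real_,
                                  egger_intercept_pval = NA_real_)))
  }

  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  beta <- cf["bx", "Estimate"]
  se <- cf["bx", "Std. Error"]
  a <- cf["(Intercept)", "Estimate"]
  a_se <- cf["(Intercept)", "Std. Error"]
  df <- n - 2L
  tcrit <- qt(0.975, df)
  rss <- sum(w * residuals(fit)^2)
  q <- list(q = rss, df = df, pval = pchisq(rss, df, lower.tail = FALSE))
  mr_result("egger", beta, se,
            pval = 2 * pt(-abs(beta / se), df),
            n_snps = n, q = q,
            ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
            egger = list(egger_intercept = a,
                         egger_intercept_se = a_se,
                         egger_intercept_pval = 2 * pt(-abs(a / a_se), df)))
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s%s): %d SNP(s)\n", x$method,
              if (isTRUE(x$random_effects)) ", random effects" else "", x$n_snps))
  cat(sprintf("  beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", x$or, x$or_ci_low, x$or_ci_high))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Q = %.3g (df %d, p = %.3g)\n", x$q_stat, x$q_df, x$q_pval))
  }
  if (!is.null(x$egger_intercept) && x$method == "egger") {
    cat(sprintf("  Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_pval))
  }
  invisible(x)
}

#' Flatten an `mr_result` to a one-row data.frame
#'
#' @param x An `mr_result`.
#' @param label Optional analysis label stored in an `analysis` column.
#' @return A one-row data.frame suitable for TSV report assembly.
#' @export
mr_result_row <- function(x, label = NA_character_) {
  data.frame(
    analysis = label, method = x$method, n_snps = x$n_snps,
    beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    pval = x$pval, or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
    q_stat = x$q_stat, q_df = x$q_df, q_pval = x$q_pval,
    egger_intercept = if (is.null(x$egger_intercept)) NA_real_ else x$egger_intercept,
    egger_intercept_pval = if (is.null(x$egger_intercept_pval)) NA_real_ else x$egger_intercept_pval,
    stringsAsFactors = FALSE
  )
}
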