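# Network MR: three-step mediation framework and bidirectional analyses.

#' Instrument-selection configuration
#'
#' Parameters shared by every MR leg of a network analysis.
#'
#' @param pval_threshold Exposure-association screen for candidate
#'   instruments (inclusive; default 5e-4).
#' @param clump_r2,clump_window_bp LD-clumping thresholds (defaults 0.001
#'   and 5e5 bp).
#' @param clump Whether to clump at all (requires chrom/pos; default TRUE).
#' @param ld An `ld_info` table, or `NULL` for no recorded LD.
#' @param method `"greedy"` (default): variance-explained-maximizing
#'   selection under the Cochran's Q constraint ([greedy_select()]);
#'   `"pvalue"`: keep everything surviving the screen and clumping.
#' @param het_alpha Heterogeneity threshold for the greedy method
#'   (default 0.05).
#' @param palindromic_eaf_window Passed to [harmonize()].
#' @param alpha Two-sided significance level used to declare causal paths
#'   (default 0.05).
#' @param random_effects Use multiplicative random-effects IVW.
#' @return A `selection_config` list.
#' @export
selection_config <- function(pval_threshold = 5e-4,
                             clump_r2 = 0.001,
                             clump_window_bp = 5e5,
                             clump = TRUE,
                             ld = NULL,
                             method = c("greedy", "pvalue"),
                             het_alpha = 0.05,
                             palindromic_eaf_window = 0.08,
                             alpha = 0.05,
                             random_effects = FALSE) {
  method <- match.arg(method)
  stopifnot(pval_threshold > 0, pval_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_window_bp >= 0,
            het_alpha > 0, het_alpha < 1, alpha > 0, alpha < 1)
  structure(list(
    pval_threshold = pval_threshold, clump_r2 = clump_r2,
    clump_window_bp = clump_window_bp, clump = clump, ld = ld,
    method = method, het_alpha = het_alpha,
    palindromic_eaf_window = palindromic_eaf_window,
    alpha = alpha, random_effects = random_effects
  ), class = "selection_config")
}

#' Select instruments for one exposure and fit IVW against one outcome
#'
#' One MR leg: screen the exposure summary statistics on p-value, clump,
#' harmonize against the outcome, optionally apply greedy
#' homogeneity-constrained selection, and estimate the causal effect by
#' IVW.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param config A [selection_config()].
#' @return A list with `mr` (an `mr_result`), `pairs` (the harmonized table
#'   restricted to the instruments), `instruments` (an `instrument_set` or
#'   `NULL` for the `"pvalue"` method), `report` (harmonization report) and
#'   `status` (`"ok"`, or `"no_instruments"` with `mr = NULL`).
#' @export
select_and_fit <- function(exposure, outcome, config = selection_config()) {
  cand <- pvalue_filter(exposure, config$pval_threshold)
  if (nrow(cand) == 0) {
    return(list(mr = NULL, pairs = NULL, instruments = NULL,
                report = NULL, status = "no_instruments"))
  }
  if (isTRUE(config$clump)) {
    cand <- ld_clump(cand, ld = config$ld, r2_threshold = config$clump_r2,
                     window_bp = config$clump_window_bp)
  }
  harm <- harmonize(cand, outcome,
                    palindromic_eaf_window = config$palindromic_eaf_window)
  usable <- kept_pairs(harm)
  if (nrow(usable) == 0) {
    return(list(mr = NULL, pairs = harm, instruments = NULL,
                report = harmonization_report(harm), status = "no_instruments"))
  }
  instruments <- NULL
  if (config$method == "greedy") {
    n_exp <- suppressWarnings(stats::median(usable$n_exposure, na.rm = TRUE))
    r2 <- snp_r2(usable$beta_exposure, usable$se_exposure, usable$n_exposure)
    instruments <- greedy_select(usable, setNames(r2, usable$snp),
                                 het_alpha = config$het_alpha,
                                 n = if (is.finite(n_exp)) n_exp else NULL)
    usable <- subset_pairs(usable, instruments)
  }
  est <- mr_ivw(usable, random_effects = config$random_effects)
  list(mr = est, pairs = usable, instruments = instruments,
       report = harmonization_report(harm), status = "ok")
}

#' Mediated proportion on the log-effect scale
#'
#' The indirect effect (product of the exposure-to-mediator and
#' mediator-to-outcome path coefficients) divided by the total effect, all
#' on the beta / log-odds scale. Invariant to rescaling the mediator's
#' units.
#'
#' @param a_beta Exposure-to-mediator estimate.
#' @param b_beta Mediator-to-outcome estimate.
#' @param total_beta Total exposure-to-outcome estimate (nonzero).
#' @return `a_beta * b_beta / total_beta`.
#' @export
mediated_proportion <- function(a_beta, b_beta, total_beta) {
  if (any(total_beta == 0)) stop("total effect is zero; mediated proportion undefined")
  a_beta * b_beta / total_beta
}

#' Three-step network MR with one candidate mediator
#'
#' Step I estimates the total effect of the exposure on the outcome using
#' exposure-derived instruments; step II the exposure-to-mediator path with
#' the same instrument source; step III the mediator-to-outcome path with
#' instruments re-selected from the mediator's own summary statistics. The
#' mediator is declared "potential" only when both step II and step III are
#' significant at `config$alpha`; the mediated proportion is computed on the
#' log-effect scale. Optionally a reverse (mediator-to-exposure) MR is run
#' with mediator-derived instruments.
#'
#' @param exposure,mediator,outcome `sumstats` tables for the three traits
#'   (from non-overlapping studies).
#' @param config A [selection_config()].
#' @param reverse Also run the mediator-to-exposure direction.
#' @return A `network_result`: list with `total`, `a_path`, `b_path`
#'   (each a [select_and_fit()] leg), `mediated_proportion`,
#'   `mediator_declared`, optional `reverse`, and `status` (`"ok"` or
#'   `"partial"` when a leg had no instruments).
#' @export
run_network <- function(exposure, mediator, outcome,
                        config = selection_config(), reverse = FALSE) {
  total <- select_and_fit(exposure, outcome, config)
  a_path <- select_and_fit(exposure, mediator, config)
  b_path <- select_and_fit(mediator, outcome, config)
  legs_ok <- !vapply(list(total, a_path, b_path), function(l) is.null(l$mr), logical(1))

  med_prop <- NA_real_
  declared <- NA
  if (all(legs_ok)) {
    declared <- a_path$mr$pval < config$alpha && b_path$mr$pval < config$alpha
    if (total$mr$beta != 0) {
      med_prop <- mediated_proportion(a_path$mr$beta, b_path$mr$beta, total$mr$beta)
    }
  }
  rev_leg <- NULL
  if (isTRUE(reverse)) rev_leg <- select_and_fit(mediator, exposure, config)

  structure(list(
    total = total, a_path = a_path, b_path = b_path,
    mediated_proportion = med_prop,
    mediator_declared = declared,
    reverse = rev_leg,
    alpha = config$alpha,
    status = if (all(legs_ok)) "ok" else "partial"
  ), class = "network_result")
}

#' Bidirectional MR between two traits
#'
#' Two independent MR runs with the roles of the traits exchanged;
#' instruments are re-selected from the exposure-side summary statistics in
#' each direction. The forward run is identical to a standalone
#' [select_and_fit()] on the same inputs.
#'
#' @param trait1,trait2 `sumstats` tables.
#' @param config A [selection_config()].
#' @return List with `forward` (trait1 -> trait2) and `reverse`
#'   (trait2 -> trait1) legs.
#' @export
bidirectional <- function(trait1, trait2, config = selection_config()) {
  list(forward = select_and_fit(trait1, trait2, config),
       reverse = select_and_fit(trait2, trait1, config))
}

.leg_label <- function(leg) {
  if (is.null(leg$mr)) return("  (no instruments)\n")
  m <- leg$mr
  r2 <- if (!is.null(leg$instruments)) sprintf(" R2 = %.3g,", leg$instruments$r2_total) else ""
  sprintf("  %d IV(s),%s beta = %.4g, OR = %.3f [%.3f, %.3f], p = %.3g\n",
          m$n_snps, r2, m$beta, m$or, m$or_ci_low, m$or_ci_high, m$pval)
}

#' @export
print.network_result <- function(x, ...) {
  cat("Network MR (three-step mediation)\n")
  cat("Step I   exposure -> outcome (total effect):\n", .leg_label(x$total), sep = "")
  cat("Step II  exposure -> mediator:\n", .leg_label(x$a_path), sep = "")
  cat("Step III mediator -> outcome:\n", .leg_label(x$b_path), sep = "")
  if (!is.na(x$mediator_declared)) {
    cat(sprintf("Mediator declared at alpha = %.3g: %s\n", x$alpha,
                if (x$mediator_declared) "yes" else "no"))
  }
  if (!is.na(x$mediated_proportion)) {
    cat(sprintf("Mediated proportion (log scale): %.1f%%\n",
                100 * x$mediated_proportion))
  }
  if (!is.null(x$reverse)) {
    cat("Reverse  mediator -> exposure:\n", .leg_label(x$reverse), sep = "")
  }
  if (x$status != "ok") cat("Status:", x$status, "\n")
  invisible(x)
}

#' Human-readable network report table
#'
#' One row per MR leg (exposure, outcome, number of instruments, variance
#' explained, beta, OR with CI, p-value), mirroring the usual reporting
#' layout for network MR causal estimates.
#'
#' @param x A `network_result`.
#' @param exposure,mediator,outcome Trait labels.
#' @return A data.frame.
#' @export
network_report <- function(x, exposure = "exposure", mediator = "mediator",
                           outcome = "outcome") {
  leg_row <- function(leg, from, to) {
    if (is.null(leg$mr)) {
      return(data.frame(exposure = from, outcome = to, n_iv = 0L,
                        r2 = NA_real_, beta = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- leg$mr
    data.frame(
      exposure = from, outcome = to, n_iv = m$n_snps,
      r2 = if (is.null(leg$instruments)) NA_real_ else leg$instruments$r2_total,
      beta = m$beta, or = m$or, ci_low = m$or_ci_low, ci_high = m$or_ci_high,
      pval = m$pval, stringsAsFactors = FALSE
    )
  }
  rows <- list(
    leg_row(x$total, exposure, outcome),
    leg_row(x$a_path, exposure, mediator),
    leg_row(x$b_path, mediator, outcome)
  )
  if (!is.null(x$reverse)) rows <- c(rows, list(leg_row(x$reverse, mediator, exposure)))
  do.call(rbind, rows)
}
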