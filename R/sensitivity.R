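# Leave-one-out influence analysis over an instrument set.

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect with each SNP omitted in turn,
#' quantifying the influence of every instrument on the pooled estimate.
#' Rows follow the input SNP order; the full-set estimate is appended as a
#' final row with `snp = "none"`.
#'
#' @param pairs A `harmonized_pairs` table with at least 2 usable SNPs.
#' @param random_effects Passed to [mr_ivw()].
#' @return A `loo_table` data.frame with columns `snp` (the omitted SNP),
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`; `n + 1` rows for `n` SNPs.
#' @export
leave_one_out <- function(pairs, random_effects = FALSE) {
  pairs <- kept_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2) stop("leave_one_out needs at least 2 SNPs")
  one_row <- function(omit) {
    sub <- if (is.null(omit)) pairs else pairs[pairs$snp != omit, , drop = FALSE]
    est <- mr_ivw(sub, random_effects = random_effects)
    data.frame(snp = if (is.null(omit)) "none" else omit,
               beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval, stringsAsFactors = FALSE)
  }
  rows <- lapply(pairs$snp, one_row)
  out <- do.call(rbind, c(rows, list(one_row(NULL))))
  rownames(out) <- NULL
  class(out) <- c("loo_table", "data.frame")
  out
}

#' Flag influential SNPs from a leave-one-out table
#'
#' A SNP is flagged when omitting it moves the IVW p-value across `alpha`
#' (in either direction), or reverses the sign of a significant full-set
#' estimate. Sign reversals are only counted when the full-set estimate is
#' significant at `alpha`: around a null estimate the sign is noise and
#' every omission would "flip" it. The paper trail for any real analysis
#' should report this rule alongside the flags: it is a convention, not a
#' canonical definition of influence.
#'
#' @param table A `loo_table` from [leave_one_out()].
#' @param alpha Two-sided significance level for the crossing rule
#'   (default 0.05).
#' @param rule `"both"` (default), `"pval"` or `"sign"`: which criteria can
#'   trigger a flag.
#' @return Character vector of flagged SNP ids (possibly empty).
#' @export
flag_influential <- function(table, alpha = 0.05, rule = c("both", "pval", "sign")) {
  rule <- match.arg(rule)
  full <- table[table$snp == "none", , drop = FALSE]
  if (nrow(full) != 1) stop("table must contain exactly one full-set row (snp == 'none')")
  rows <- table[table$snp != "none", , drop = FALSE]
  crosses <- (rows$pval <= alpha) != (full$pval <= alpha)
  flips <- full$pval <= alpha & sign(rows$beta) != sign(full$beta)
  hit <- switch(rule,
    both = crosses | flips,
    pval = crosses,
    sign = flips
  )
  rows$snp[hit]
}
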