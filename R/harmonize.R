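# Allele harmonization between an exposure and an outcome summary-stat table.

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Matches SNPs present in both tables and aligns the outcome association to
#' the exposure's effect allele. Outcome records whose alleles are swapped
#' relative to the exposure have their beta negated and allele frequency
#' complemented (`action = "flipped"`); alleles matching only as reverse
#' complements are strand-flipped first. Palindromic SNPs (A/T or C/G) are
#' strand-ambiguous: they are oriented by comparing allele frequencies when
#' both are informative, and dropped (`action = "dropped_palindromic"`) when
#' either frequency is missing or within `palindromic_eaf_window` of 0.5.
#' Irreconcilable allele pairs are dropped (`action = "dropped_mismatch"`).
#'
#' @param exposure,outcome `sumstats` tables. Duplicate SNP ids within either
#'   table are an error; SNPs absent from one table are skipped and counted
#'   in the harmonization report.
#' @param palindromic_eaf_window Half-width of the frequency window around
#'   0.5 inside which a palindromic SNP is considered unresolvable
#'   (default 0.08, common MR practice; the orientation of palindromic
#'   variants is an analysis assumption, surfaced in the report).
#' @return A `harmonized_pairs` data.frame with columns `snp`, `chrom`,
#'   `pos`, `beta_exposure`, `se_exposure`, `pval_exposure`, `n_exposure`,
#'   `eaf` (exposure effect-allele frequency), `beta_outcome`, `se_outcome`,
#'   `pval_outcome`, `action`. Dropped SNPs keep their row with the drop
#'   action recorded and outcome effects set to `NA`. The per-action counts
#'   are attached as attribute `"report"` (see [harmonization_report()]).
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  for (nm in c("exposure", "outcome")) {
    x <- get(nm)
    if (!all(.SUM_REQUIRED %in% names(x))) {
      stop(nm, " is not a summary-statistics table")
    }
    if (anyDuplicated(x$snp)) {
      stop("duplicate snp id(s) in ", nm, ": ",
           paste(unique(x$snp[duplicated(x$snp)]), collapse = ", "))
    }
  }
  common <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(common, exposure$snp), , drop = FALSE]
  ou <- outcome[match(common, outcome$snp), , drop = FALSE]

  n <- length(common)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele

  for (i in seq_len(n)) {
    if (.is_palindromic(ea_x[i], oa_x[i])) {
      if (!.is_palindromic(ea_y[i], oa_y[i]) ||
          !all(c(ea_y[i], oa_y[i]) %in% c(ea_x[i], oa_x[i]))) {
        action[i] <- "dropped_mismatch"
        next
      }
      fx <- ex$eaf[i]; fy <- eaf_out[i]
      if (is.na(fx) || is.na(fy) ||
          abs(fx - 0.5) < palindromic_eaf_window ||
          abs(fy - 0.5) < palindromic_eaf_window) {
        action[i] <- "dropped_palindromic"
        next
      }
      # expected outcome frequency if the letters are on the same strand
      f_expect <- if (ea_y[i] == ea_x[i]) fx else 1 - fx
      concordant <- (f_expect - 0.5) * (fy - 0.5) > 0
      swapped_letters <- ea_y[i] == oa_x[i]
      flip <- xor(swapped_letters, !concordant)
      if (flip) {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      } else {
        action[i] <- "none"
      }
      next
    }
    if (ea_y[i] == ea_x[i] && oa_y[i] == oa_x[i]) {
      action[i] <- "none"
    } else if (ea_y[i] == oa_x[i] && oa_y[i] == ea_x[i]) {
      action[i] <- "flipped"
    } else if (.complement(ea_y[i]) == ea_x[i] && .complement(oa_y[i]) == oa_x[i]) {
      action[i] <- "none"       # strand flip only
    } else if (.complement(ea_y[i]) == oa_x[i] && .complement(oa_y[i]) == ea_x[i]) {
      action[i] <- "flipped"    # strand flip + swap
    } else {
      action[i] <- "dropped_mismatch"
    }
    if (action[i] == "flipped") {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    }
  }

  dropped <- grepl("^dropped", action)
  out <- data.frame(
    snp = common,
    chrom = ex$chrom,
    pos = ex$pos,
    effect_allele = ea_x,
    other_allele = oa_x,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    pval_exposure = ex$pval,
    n_exposure = ex$n,
    eaf = ex$eaf,
    beta_outcome = ifelse(dropped, NA_real_, beta_out),
    se_outcome = ifelse(dropped, NA_real_, ou$se),
    pval_outcome = ifelse(dropped, NA_real_, ou$pval),
    action = action,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_pairs", "data.frame")
  attr(out, "report") <- list(
    n_exposure = nrow(exposure),
    n_outcome = nrow(outcome),
    n_common = n,
    exposure_only = nrow(exposure) - n,
    outcome_only = nrow(outcome) - n,
    actions = as.list(table(factor(action, levels = c(
      "none", "flipped", "dropped_palindromic", "dropped_mismatch"
    )))),
    palindromic_eaf_window = palindromic_eaf_window,
    note = paste("palindromic SNPs oriented by allele frequency;",
                 "dropped when EAF missing or within the window of 0.5",
                 "(assumed rule; the orientation of palindromic variants",
                 "is not identifiable from alleles alone)")
  )
  out
}

#' Harmonization report
#'
#' Per-action counts and merge bookkeeping for a harmonized table, suitable
#' for JSON serialization.
#'
#' @param pairs A `harmonized_pairs` object from [harmonize()].
#' @return A list of counts (SNPs per table, intersection size, SNPs dropped
#'   on either side, counts per `action`).
#' @export
harmonization_report <- function(pairs) {
  rep <- attr(pairs, "report")
  if (is.null(rep)) stop("no harmonization report attached")
  rep
}

# Usable rows (aligned, not dropped) of a harmonized table.
kept_pairs <- function(pairs) {
  if ("action" %in% names(pairs)) {
    pairs <- pairs[pairs$action %in% c("none", "flipped"), , drop = FALSE]
  }
  pairs
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("Harmonized pairs: %d SNP(s) in common", nrow(x)))
  if (!is.null(rep)) {
    a <- rep$actions
    cat(sprintf(" (none %d, flipped %d, dropped_palindromic %d, dropped_mismatch %d)",
                a$none, a$flipped, a$dropped_palindromic, a$dropped_mismatch))
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}
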