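# Instrument construction: p-value filtering, LD clumping, greedy
# variance-explained selection under a homogeneity constraint, and
# instrument-strength statistics.

#' Pairwise LD lookup table
#'
#' A symmetric lookup of pairwise r-squared values. Pairs not recorded are
#' treated as r-squared 0; the diagonal is 1. The LD source is an explicit
#' input (e.g. precomputed from a reference panel); an empty table makes
#' clumping a per-window no-op since no pair exceeds any threshold.
#'
#' @param snp_a,snp_b Character vectors of SNP ids.
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return An `ld_info` object.
#' @export
ld_info <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 values must lie in [0, 1]")
  key <- paste(pmin(snp_a, snp_b), pmax(snp_a, snp_b), sep = "\r")
  tab <- setNames(r2, key)
  tab <- tab[!duplicated(names(tab))]
  structure(list(table = tab), class = "ld_info")
}

#' Read an LD table from 3-column delimited text (snp_a, snp_b, r2)
#'
#' @param path Path to a tab- or comma-delimited file with a header.
#' @return An `ld_info` object.
#' @export
read_ld <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("LD file needs columns snp_a, snp_b, r2")
  ld_info(as.character(x[[1]]), as.character(x[[2]]), as.numeric(x[[3]]))
}

#' Query pairwise r-squared from an `ld_info` table
#'
#' @param ld An `ld_info` object (or `NULL`, meaning no LD recorded).
#' @param a,b SNP id vectors (recycled to common length).
#' @return Numeric vector of r-squared values; 1 on the diagonal, 0 for
#'   unrecorded pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_info"))
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    hit <- !is.na(match(key, names(ld$table))) & a != b
    out[hit] <- unname(ld$table[key[hit]])
  }
  out
}

#' Filter summary statistics on association p-value
#'
#' Retains records with `pval <= threshold` (inclusive bound).
#'
#' @param records A `sumstats` table.
#' @param threshold P-value threshold in (0, 1); default 5e-4, the
#'   exposure-association screen used for instrument discovery.
#' @return The filtered `sumstats` table.
#' @export
pvalue_filter <- function(records, threshold = 5e-4) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  out <- records[records$pval <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as an index
#' SNP and removes all remaining SNPs on the same chromosome within
#' `window_bp` of it whose r-squared with the index exceeds `r2_threshold`.
#' Ties are broken by smaller p-value, then lexicographic SNP id, so output
#' is deterministic.
#'
#' @param records A `sumstats` table with `chrom` and `pos` present.
#' @param ld An `ld_info` table, or `NULL` (no recorded LD: r-squared is 0
#'   for every pair, so nothing is removed).
#' @param r2_threshold r-squared above which two SNPs are considered
#'   correlated (default 0.001).
#' @param window_bp Clumping window in base pairs (default 5e5, i.e. 500 kb).
#' @return The index SNPs, in selection order, as a `sumstats` table.
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.001, window_bp = 5e5) {
  if (nrow(records) == 0) return(records)
  if (any(is.na(records$pos)) || any(is.na(records$chrom))) {
    stop("ld_clump requires chrom and pos on every record")
  }
  ord <- order(records$pval, records$snp)
  x <- records[ord, , drop = FALSE]
  keep <- character(0)
  while (nrow(x) > 0) {
    idx <- x[1, , drop = FALSE]
    keep <- c(keep, idx$snp)
    x <- x[-1, , drop = FALSE]
    if (nrow(x) == 0) break
    in_window <- x$chrom == idx$chrom & abs(x$pos - idx$pos) <= window_bp
    correlated <- in_window & ld_r2(ld, idx$snp, x$snp) > r2_threshold
    x <- x[!correlated, , drop = FALSE]
  }
  out <- records[match(keep, records$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained from summary statistics
#'
#' Estimates the proportion of trait variance explained by one SNP as
#' `t^2 / (t^2 + n - 2)` with `t = beta / se`; this equals the squared
#' sample correlation between genotype and trait in a simple regression, and
#' unlike `2 f (1 - f) beta^2` it needs no allele frequency.
#'
#' @param beta,se Marginal effect and standard error.
#' @param n Sample size of the association (required).
#' @return Variance explained in \[0, 1); vectorized.
#' @export
snp_r2 <- function(beta, se, n) {
  if (missing(n) || any(is.na(n))) {
    stop("sample size n is required to estimate variance explained")
  }
  if (any(n < 3)) stop("n must be at least 3")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' F-statistic for instrument strength
#'
#' `F = (n - k - 1) / k * r2 / (1 - r2)` for `k` instruments jointly
#' explaining `r2_total` of the exposure variance in a study of size `n`.
#' F > 10 is the conventional weak-instrument rule of thumb.
#'
#' @param r2_total Total variance explained, in \[0, 1).
#' @param n Exposure-study sample size.
#' @param k Number of instruments.
#' @return The F-statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (any(r2_total < 0) || any(r2_total >= 1)) stop("r2_total must lie in [0, 1)")
  if (any(k < 1) || any(n <= k + 1)) stop("need n > k + 1 >= 2")
  (n - k - 1) / k * r2_total / (1 - r2_total)
}

#' Greedy instrument selection under a homogeneity constraint
#'
#' Builds an instrument set by seeding with the SNP explaining the largest
#' variance in the exposure, then repeatedly adding the candidate that
#' maximizes cumulative variance explained subject to the augmented set
#' showing no heterogeneity against the outcome: Cochran's Q p-value of the
#' candidate set (around its own IVW estimate) must stay at or above
#' `het_alpha`. Selection stops when no remaining candidate qualifies.
#' Cumulative variance explained is the sum of per-SNP values, appropriate
#' for instruments in linkage equilibrium (i.e. after clumping). Q is
#' undefined for a single SNP (0 degrees of freedom) and treated as passing.
#' Ties are broken by smaller exposure p-value, then lexicographic SNP id.
#'
#' @param pairs A `harmonized_pairs` table.
#' @param per_snp_r2 Named numeric vector of per-SNP variance explained,
#'   covering every usable SNP in `pairs` (see [snp_r2()]).
#' @param het_alpha Heterogeneity p-value threshold below which a candidate
#'   set is rejected (default 0.05; "no heterogeneity" made operational).
#' @param n Optional exposure sample size; when given, the set's
#'   F-statistic is attached via [f_statistic()].
#' @return An `instrument_set`: list with `snp_ids`, `r2_total`, `f_stat`,
#'   `q_stat`, `q_df`, `q_pval`, `het_alpha` and a per-iteration
#'   `selection_log` data.frame.
#' @export
greedy_select <- function(pairs, per_snp_r2, het_alpha = 0.05, n = NULL) {
  pairs <- kept_pairs(pairs)
  if (nrow(pairs) == 0) stop("no usable harmonized pairs to select from")
  miss <- setdiff(pairs$snp, names(per_snp_r2))
  if (length(miss) > 0) {
    stop("per_snp_r2 missing for: ", paste(miss, collapse = ", "))
  }
  r2 <- per_snp_r2[pairs$snp]
  ord <- order(-r2, pairs$pval_exposure, pairs$snp)
  pairs <- pairs[ord, , drop = FALSE]
  r2 <- r2[ord]

  selected <- integer(0)
  remaining <- seq_len(nrow(pairs))
  log_rows <- list()
  repeat {
    accepted <- FALSE
    for (j in remaining) {
      cand <- c(selected, j)
      sub <- pairs[cand, , drop = FALSE]
      if (length(cand) == 1) {
        q <- list(q = NA_real_, df = NA_integer_, pval = NA_real_)
        pass <- TRUE
      } else {
        est <- mr_ivw(sub)
        q <- cochran_q(sub, est$beta)
        pass <- q$pval >= het_alpha
      }
      if (pass) {
        selected <- cand
        remaining <- setdiff(remaining, j)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          step = length(selected),
          snp = pairs$snp[j],
          r2_snp = unname(r2[j]),
          r2_total = sum(r2[selected]),
          q_stat = q$q,
          q_pval = q$pval,
          stringsAsFactors = FALSE
        )
        accepted <- TRUE
        break
      }
    }
    if (!accepted || length(remaining) == 0) break
  }

  sel_log <- do.call(rbind, log_rows)
  snp_ids <- pairs$snp[selected]
  r2_total <- sum(r2[selected])
  final <- pairs[selected, , drop = FALSE]
  if (length(selected) >= 2) {
    qf <- cochran_q(final, mr_ivw(final)$beta)
  } else {
    qf <- list(q = NA_real_, df = NA_integer_, pval = NA_real_)
  }
  structure(list(
    snp_ids = snp_ids,
    r2_total = r2_total,
    f_stat = if (!is.null(n)) f_statistic(r2_total, n, length(snp_ids)) else NA_real_,
    n_exposure = if (!is.null(n)) n else NA_real_,
    q_stat = qf$q,
    q_df = qf$df,
    q_pval = qf$pval,
    het_alpha = het_alpha,
    selection_log = sel_log
  ), class = "instrument_set")
}

#' Subset a harmonized table to an instrument set
#'
#' @param pairs A `harmonized_pairs` table.
#' @param instruments An `instrument_set` or character vector of SNP ids.
#' @return The matching rows of `pairs`, in instrument order.
#' @export
subset_pairs <- function(pairs, instruments) {
  ids <- if (inherits(instruments, "instrument_set")) instruments$snp_ids else instruments
  out <- pairs[match(ids, pairs$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d SNP(s), cumulative R2 = %.4g", length(x$snp_ids), x$r2_total))
  if (!is.na(x$f_stat)) cat(sprintf(", F = %.2f", x$f_stat))
  if (!is.na(x$q_stat)) {
    cat(sprintf(", Q = %.3g (df %d, p = %.3g)", x$q_stat, x$q_df, x$q_pval))
  }
  cat("\n")
  invisible(x)
}

#' Serialize an instrument set (including its selection log) to JSON
#'
#' @param x An `instrument_set`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
instrument_set_json <- function(x, path = NULL) {
  obj <- unclass(x)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
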