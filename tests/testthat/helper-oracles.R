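# Independent oracles and small fixture builders shared across the suite.

# Build a minimal sumstats table from vectors.
make_records <- function(snp, ea = "A", oa = "G", beta = 0.1, se = 0.05,
                         pval = 1e-6, eaf = NA, chrom = "1",
                         pos = seq_along(snp) * 1e6, n = NA,
                         trait_id = "t", trait_type = "continuous") {
  suppressWarnings(as_sumstats(data.frame(
    snp = snp, effect_allele = ea, other_allele = oa, beta = beta, se = se,
    pval = pval, eaf = eaf, chrom = chrom, pos = pos, n = n,
    stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type))
}

# Build a harmonized_pairs table directly.
make_pairs <- function(bx, by, sy, sx = 0.01, snp = sprintf("rs%d", seq_along(bx))) {
  out <- data.frame(
    snp = snp, chrom = "1", pos = seq_along(bx) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx,
    pval_exposure = 2 * pnorm(-abs(bx / sx)),
    n_exposure = NA_real_, eaf = NA_real_,
    beta_outcome = by, se_outcome = sy,
    pval_outcome = 2 * pnorm(-abs(by / sy)),
    action = "none", stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

# Zero-intercept weighted least squares of by on bx with weights w, solved
# through the normal equations with explicit matrix algebra (independent of
# the IVW closed form).
wls_zero_intercept <- function(bx, by, w) {
  X <- matrix(bx, ncol = 1)
  W <- diag(w, nrow = length(w))
  xtwx <- t(X) %*% W %*% X
  beta <- solve(xtwx, t(X) %*% W %*% by)
  list(beta = beta[1, 1], se = sqrt(solve(xtwx)[1, 1]))
}

# Exhaustive reference for LD clumping: scan candidates in p-value order,
# eliminating every pair that violates the window/r2 rule.
clump_oracle <- function(records, ld, r2_threshold, window_bp) {
  recs <- records[order(records$pval, records$snp), , drop = FALSE]
  alive <- rep(TRUE, nrow(recs))
  kept <- character(0)
  for (i in seq_len(nrow(recs))) {
    if (!alive[i]) next
    kept <- c(kept, recs$snp[i])
    for (j in seq_len(nrow(recs))) {
      if (j == i || !alive[j] || recs$snp[j] %in% kept) next
      if (recs$chrom[j] == recs$chrom[i] &&
          abs(recs$pos[j] - recs$pos[i]) <= window_bp &&
          ld_r2(ld, recs$snp[i], recs$snp[j]) > r2_threshold) {
        alive[j] <- FALSE
      }
    }
  }
  kept
}

# Exhaustive-subset reference for greedy instrument selection: the
# feasible subset with the largest cumulative r2 whose descending-r2
# prefixes all pass the heterogeneity test (the order a greedy pass
# traverses when it never has to skip).
exhaustive_select <- function(pairs, per_snp_r2, het_alpha = 0.05) {
  n <- nrow(pairs)
  stopifnot(n <= 12)
  r2 <- per_snp_r2[pairs$snp]
  prefixes_feasible <- function(idx) {
    idx <- idx[order(-r2[idx], pairs$pval_exposure[idx], pairs$snp[idx])]
    if (length(idx) < 2) return(TRUE)
    for (k in 2:length(idx)) {
      sub <- pairs[idx[1:k], , drop = FALSE]
      if (cochran_q(sub, mr_ivw(sub)$beta)$pval < het_alpha) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  best_r2 <- -Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    tot <- sum(r2[idx])
    if (tot <= best_r2) next
    if (prefixes_feasible(idx)) {
      best <- idx
      best_r2 <- tot
    }
  }
  sort(pairs$snp[best])
}
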