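# Synthetic GWAS summary statistics: individual-level generator emulating
# the two-sample setting (exposure, mediator, binary outcome, three
# disjoint cohorts), plus a fast summary-level generator for calibration
# studies, and a registry of small deterministic test fixtures.

#' Configuration for the synthetic GWAS generator
#'
#' Defines a three-trait system: a continuous exposure with its own SNP
#' panel, a continuous mediator with an independent SNP panel, and a binary
#' outcome generated from a logistic model. Genotypes are drawn per
#' individual as binomial(2, MAF) under Hardy-Weinberg equilibrium, in
#' linkage equilibrium across SNPs; the three cohorts are disjoint
#' (two-sample setting). Structural model, with `Ux` and `Um` the latent
#' exposure/mediator components (unit variance each):
#' `X = Ux + theta_mx * Um`, `M = Um + theta_xm * Ux`,
#' `logit P(Y=1) = logit(prevalence) + theta_xy_direct * X + theta_my * M +
#' sum(alpha_j G_j)`. The cross-loading form keeps the system acyclic while
#' letting both directions carry genetic signal for bidirectional analyses.
#'
#' @param n_snps Number of exposure SNPs.
#' @param n_snps_mediator Number of mediator SNPs (0 for no mediator panel).
#' @param maf_range Range minor-allele frequencies are drawn from
#'   (default 0.05-0.5).
#' @param h2_exposure,h2_mediator Variance of the latent exposure/mediator
#'   explained by their own SNP panels, each in \[0, 1).
#' @param theta_xm Exposure-to-mediator effect.
#' @param theta_my Mediator-to-outcome effect (log-odds per mediator unit).
#' @param theta_xy_direct Direct exposure-to-outcome effect (log-odds).
#' @param theta_mx Reverse (mediator-to-exposure) effect, for bidirectional
#'   scenarios.
#' @param pleio_frac Fraction of exposure SNPs with direct outcome effects.
#' @param pleio_mean,pleio_sd Mean and SD of those direct (pleiotropic)
#'   log-odds effects.
#' @param n_exposure,n_mediator,n_outcome Cohort sizes (disjoint studies).
#' @param prevalence Baseline outcome prevalence in (0, 1).
#' @param gamma_exposure,gamma_mediator Optional explicit per-SNP effect
#'   vectors; by default effects are drawn and rescaled to the variance
#'   budget.
#' @param scramble_alleles Randomly swap reported effect/other alleles in
#'   the mediator and outcome tables (negating betas, complementing
#'   frequencies) so the downstream harmonization step has real work to do.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 30, n_snps_mediator = 10,
                       maf_range = c(0.05, 0.5),
                       h2_exposure = 0.15, h2_mediator = 0.10,
                       theta_xm = 0, theta_my = 0, theta_xy_direct = 0,
                       theta_mx = 0,
                       pleio_frac = 0, pleio_mean = 0, pleio_sd = 0,
                       n_exposure = 6000, n_mediator = 6000, n_outcome = 6000,
                       prevalence = 0.3,
                       gamma_exposure = NULL, gamma_mediator = NULL,
                       scramble_alleles = FALSE, seed = NULL) {
  if (h2_exposure < 0 || h2_exposure >= 1 || h2_mediator < 0 || h2_mediator >= 1) {
    stop("infeasible variance budget: h2 values must lie in [0, 1)")
  }
  stopifnot(n_snps >= 1, n_snps_mediator >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            pleio_frac >= 0, pleio_frac <= 1, pleio_sd >= 0,
            n_exposure >= 10, n_outcome >= 10, n_mediator >= 0,
            prevalence > 0, prevalence < 1)
  if (!is.null(gamma_exposure) && length(gamma_exposure) != n_snps) {
    stop("gamma_exposure must have length n_snps")
  }
  if (!is.null(gamma_mediator) && length(gamma_mediator) != n_snps_mediator) {
    stop("gamma_mediator must have length n_snps_mediator")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Scale raw effects so the panel explains exactly h2 of a unit-variance trait.
.scale_to_h2 <- function(raw, maf, h2) {
  if (h2 == 0 || length(raw) == 0) return(rep(0, length(raw)))
  v <- sum(2 * maf * (1 - maf) * raw^2)
  raw * sqrt(h2 / v)
}

.draw_genotypes <- function(n, maf) {
  matrix(rbinom(n * length(maf), 2, rep(maf, each = n)), nrow = n)
}

# Vectorized marginal simple linear regression of y on each column of G.
.linear_gwas <- function(G, y) {
  n <- nrow(G)
  gc <- scale(G, center = TRUE, scale = FALSE)
  sxx <- colSums(gc^2)
  beta <- as.vector(crossprod(gc, y - mean(y))) / sxx
  tss <- sum((y - mean(y))^2)
  rss <- pmax(tss - beta^2 * sxx, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  list(beta = beta, se = se, pval = 2 * pt(-abs(tval), n - 2))
}

# Vectorized one-step score approximation to marginal logistic regression;
# accurate for the small per-SNP effects typical of GWAS. method = "glm"
# fits each SNP by full maximum likelihood instead.
.logistic_gwas <- function(G, y, method = c("score", "glm")) {
  method <- match.arg(method)
  if (method == "glm") {
    fits <- apply(G, 2, function(g) {
      fit <- stats::glm(y ~ g, family = stats::binomial())
      summary(fit)$coefficients["g", c("Estimate", "Std. Error")]
    })
    beta <- fits[1, ]
    se <- fits[2, ]
  } else {
    gc <- scale(G, center = TRUE, scale = FALSE)
    sxx <- colSums(gc^2)
    v <- mean(y) * (1 - mean(y))
    beta <- as.vector(crossprod(gc, y - mean(y))) / (v * sxx)
    se <- 1 / sqrt(v * sxx)
  }
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)))
}

.make_table <- function(assoc, G, snp, chrom, pos, ea, oa, trait_id, trait_type,
                        n, n_case = NA, n_control = NA, scramble = FALSE) {
  eaf <- colMeans(G) / 2
  beta <- assoc$beta
  if (scramble) {
    swap <- runif(length(snp)) < 0.5
    tmp <- ea[swap]; ea[swap] <- oa[swap]; oa[swap] <- tmp
    beta[swap] <- -beta[swap]
    eaf[swap] <- 1 - eaf[swap]
  }
  as_sumstats(data.frame(
    snp = snp, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = assoc$se, pval = assoc$pval,
    n = n, n_case = n_case, n_control = n_control,
    stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type)
}

#' Simulate GWAS summary statistics for three disjoint cohorts
#'
#' Generates individual-level data under the structural model of
#' [sim_config()] for three non-overlapping cohorts (exposure study,
#' mediator study, outcome study), then reduces each to per-SNP marginal
#' summary statistics: simple linear regression for the continuous traits
#' and marginal logistic regression for the binary outcome. Fully
#' reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param logistic_method `"score"` (vectorized one-step approximation,
#'   default) or `"glm"` (per-SNP maximum likelihood).
#' @return A list with `exposure`, `mediator` (or `NULL` when the config has
#'   no mediator cohort), `outcome` (each a `sumstats` table over the full
#'   SNP panel) and `truth` (per-SNP genetic effects, pleiotropic effects,
#'   structural coefficients, MAFs).
#' @export
simulate_gwas <- function(config, logistic_method = c("score", "glm")) {
  stopifnot(inherits(config, "sim_config"))
  logistic_method <- match.arg(logistic_method)
  if (!is.null(config$seed)) set.seed(config$seed)

  jx <- config$n_snps
  jm <- config$n_snps_mediator
  J <- jx + jm
  maf <- runif(J, config$maf_range[1], config$maf_range[2])
  x_idx <- seq_len(jx)
  m_idx <- if (jm > 0) jx + seq_len(jm) else integer(0)

  gamma_x <- if (is.null(config$gamma_exposure)) {
    .scale_to_h2(rnorm(jx), maf[x_idx], config$h2_exposure)
  } else config$gamma_exposure
  gamma_m <- if (is.null(config$gamma_mediator)) {
    .scale_to_h2(rnorm(jm), maf[m_idx], config$h2_mediator)
  } else config$gamma_mediator

  alpha <- rep(0, J)
  n_pleio <- round(config$pleio_frac * jx)
  pleio_idx <- if (n_pleio > 0) sort(sample(x_idx, n_pleio)) else integer(0)
  if (n_pleio > 0) alpha[pleio_idx] <- rnorm(n_pleio, config$pleio_mean, config$pleio_sd)

  snp <- sprintf("rs%d", seq_len(J))
  chrom <- as.character(((seq_len(J) - 1L) %% 22L) + 1L)
  pos <- (((seq_len(J) - 1L) %/% 22L) + 1L) * 1e6

  latents <- function(G) {
    ux <- as.vector(G[, x_idx, drop = FALSE] %*% gamma_x) +
      rnorm(nrow(G), 0, sqrt(1 - config$h2_exposure))
    um <- if (jm > 0) {
      as.vector(G[, m_idx, drop = FALSE] %*% gamma_m) +
        rnorm(nrow(G), 0, sqrt(1 - config$h2_mediator))
    } else rnorm(nrow(G))
    list(x = ux + config$theta_mx * um, m = um + config$theta_xm * ux)
  }

  # exposure cohort
  G1 <- .draw_genotypes(config$n_exposure, maf)
  exposure <- .make_table(.linear_gwas(G1, latents(G1)$x), G1, snp, chrom, pos,
                          rep("A", J), rep("G", J), "exposure", "continuous",
                          n = config$n_exposure)

  # mediator cohort
  mediator <- NULL
  if (config$n_mediator > 0 && jm > 0) {
    G2 <- .draw_genotypes(config$n_mediator, maf)
    mediator <- .make_table(.linear_gwas(G2, latents(G2)$m), G2, snp, chrom, pos,
                            rep("A", J), rep("G", J), "mediator", "continuous",
                            n = config$n_mediator,
                            scramble = config$scramble_alleles)
  }

  # outcome cohort (binary, logistic)
  G3 <- .draw_genotypes(config$n_outcome, maf)
  l3 <- latents(G3)
  eta <- qlogis(config$prevalence) + config$theta_xy_direct * l3$x +
    config$theta_my * l3$m + as.vector(G3 %*% alpha)
  y <- rbinom(config$n_outcome, 1, plogis(eta))
  outcome <- .make_table(.logistic_gwas(G3, y, logistic_method), G3, snp, chrom,
                         pos, rep("A", J), rep("G", J), "outcome", "binary",
                         n = config$n_outcome, n_case = sum(y),
                         n_control = config$n_outcome - sum(y),
                         scramble = config$scramble_alleles)

  truth <- list(
    snp = snp, maf = maf,
    exposure_snps = snp[x_idx], mediator_snps = snp[m_idx],
    gamma_exposure = gamma_x, gamma_mediator = gamma_m,
    alpha = alpha, pleiotropic_snps = snp[pleio_idx],
    theta_xm = config$theta_xm, theta_my = config$theta_my,
    theta_xy_direct = config$theta_xy_direct, theta_mx = config$theta_mx,
    theta_total = config$theta_xy_direct + config$theta_xm * config$theta_my,
    prevalence = config$prevalence
  )
  list(exposure = exposure, mediator = mediator, outcome = outcome, truth = truth)
}

#' Simulate harmonized summary pairs directly at the summary level
#'
#' Draws exposure and outcome betas from their sampling distributions given
#' true per-SNP effects, skipping individual-level data. This is the
#' calibration workhorse: under `theta = 0` and no pleiotropy the Wald
#' ratios are exactly homogeneous, so heterogeneity and pleiotropy tests
#' can be checked against their nominal behaviour at scale.
#'
#' @param n_snps Number of SNPs.
#' @param theta True causal effect.
#' @param gamma True per-SNP exposure effects (default: evenly spaced in
#'   0.05-0.2).
#' @param se_exposure,se_outcome Per-SNP standard errors (recycled).
#' @param pleio_mean,pleio_sd Directional pleiotropy: per-SNP direct outcome
#'   effects drawn from `N(pleio_mean, pleio_sd)` (0, 0 for none).
#' @return A `harmonized_pairs` table (all actions `"none"`), with the true
#'   `gamma`, `alpha` and `theta` attached as attribute `"truth"`.
#' @export
simulate_pairs <- function(n_snps, theta = 0, gamma = NULL,
                           se_exposure = 0.02, se_outcome = 0.05,
                           pleio_mean = 0, pleio_sd = 0) {
  if (is.null(gamma)) gamma <- seq(0.05, 0.2, length.out = n_snps)
  stopifnot(length(gamma) == n_snps)
  se_x <- rep_len(se_exposure, n_snps)
  se_y <- rep_len(se_outcome, n_snps)
  alpha <- if (pleio_mean != 0 || pleio_sd > 0) {
    rnorm(n_snps, pleio_mean, pleio_sd)
  } else rep(0, n_snps)
  bx <- gamma + rnorm(n_snps, 0, se_x)
  by <- theta * gamma + alpha + rnorm(n_snps, 0, se_y)
  out <- data.frame(
    snp = sprintf("rs%d", seq_len(n_snps)),
    chrom = "1", pos = seq_len(n_snps) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = se_x,
    pval_exposure = 2 * pnorm(-abs(bx / se_x)),
    n_exposure = NA_real_, eaf = NA_real_,
    beta_outcome = by, se_outcome = se_y,
    pval_outcome = 2 * pnorm(-abs(by / se_y)),
    action = "none", stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_pairs", "data.frame")
  attr(out, "truth") <- list(gamma = gamma, alpha = alpha, theta = theta)
  out
}

.FIXTURES <- list(
  null = function() sim_config(
    n_snps = 20, n_snps_mediator = 10,
    n_exposure = 4000, n_mediator = 4000, n_outcome = 6000,
    prevalence = 0.3, seed = 101
  ),
  mediation = function() sim_config(
    n_snps = 25, n_snps_mediator = 10,
    theta_xm = 0.25, theta_my = 0.4, theta_xy_direct = 0.3,
    n_exposure = 5000, n_mediator = 5000, n_outcome = 8000,
    prevalence = 0.3, seed = 102
  ),
  pleiotropy = function() sim_config(
    n_snps = 20, n_snps_mediator = 0,
    theta_xy_direct = 0.1,
    pleio_frac = 0.4, pleio_mean = 0.08, pleio_sd = 0.04,
    n_exposure = 4000, n_mediator = 0, n_outcome = 6000,
    prevalence = 0.3, seed = 103
  ),
  outlier_snp = function() sim_config(
    n_snps = 20, n_snps_mediator = 0,
    pleio_frac = 0.05, pleio_mean = 0.6, pleio_sd = 0,
    gamma_exposure = rep(0.14, 20),
    n_exposure = 5000, n_mediator = 0, n_outcome = 8000,
    prevalence = 0.3, seed = 104
  ),
  bidirectional = function() sim_config(
    n_snps = 20, n_snps_mediator = 10,
    theta_xm = 0.3,
    n_exposure = 5000, n_mediator = 5000, n_outcome = 6000,
    prevalence = 0.3, seed = 105
  )
)

#' Deterministic test-bed fixtures
#'
#' Small, fully reproducible simulated datasets used throughout the test
#' suite. Scenarios: `"null"` (all causal effects zero), `"mediation"`
#' (planted paths with mediated proportion a*b/c = 0.25: a = 0.25,
#' b = 0.4, direct = 0.3, total = 0.4), `"pleiotropy"` (40% of exposure
#' SNPs with directional direct effects), `"outlier_snp"` (one SNP with a
#' direct outcome effect large enough that its Wald ratio deviates by >= 10
#' standard errors), `"bidirectional"` (one-way exposure-to-mediator
#' causation).
#'
#' @param name Scenario name.
#' @return A list with `name`, `config`, the simulated `stats`
#'   (exposure/mediator/outcome tables) and `truth`.
#' @export
make_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% names(.FIXTURES))) {
    stop("unknown fixture; available scenarios: ",
         paste(names(.FIXTURES), collapse = ", "))
  }
  config <- .FIXTURES[[name]]()
  sim <- simulate_gwas(config)
  list(name = name, config = config,
       stats = sim[c("exposure", "mediator", "outcome")],
       truth = sim$truth)
}
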