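test_that("Wald ratios follow the delta-method form", {
  expect_equal(ratio_estimate(0.5, 0, 0.05), data.frame(beta = 0, se = 0.1))
  expect_equal(ratio_estimate(0.5, 0.1, 0.05), data.frame(beta = 0.2, se = 0.1))
  expect_equal(ratio_estimate(-0.5, 0.1, 0.05)$se, 0.1)
  expect_error(ratio_estimate(0, 0.1, 0.05), "nonzero")

  # the first-order se matches the sampling SD of the ratio at small noise
  set.seed(3)
  bx <- 0.5
  by <- rnorm(10000, 0.1, 0.05)
  expect_equal(sd(by / bx), ratio_estimate(bx, 0.1, 0.05)$se, tolerance = 0.03)
})

test_that("IVW reduces to the ratio for one SNP and obeys weight algebra", {
  p1 <- make_pairs(0.5, 0.1, 0.05)
  est <- mr_ivw(p1)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$q_df, NA_integer_)

  p3 <- make_pairs(c(0.2, 0.3, 0.4), c(0.05, 0.04, 0.09), c(0.04, 0.05, 0.06))
  est3 <- mr_ivw(p3)
  dup <- make_pairs(rep(c(0.2, 0.3, 0.4), 2), rep(c(0.05, 0.04, 0.09), 2),
                    rep(c(0.04, 0.05, 0.06), 2))
  estd <- mr_ivw(dup)
  expect_equal(estd$beta, est3$beta)
  expect_equal(estd$se, est3$se / sqrt(2))
  expect_error(mr_ivw(p3[0, ]), "at least 1")
})

test_that("IVW equals a zero-intercept WLS fit solved by normal equations", {
  set.seed(21)
  for (rep_i in 1:20) {
    n <- sample(3:30, 1)
    bx <- runif(n, -0.3, 0.3)
    bx[bx == 0] <- 0.1
    by <- rnorm(n, 0.2 * bx, 0.05)
    sy <- runif(n, 0.02, 0.1)
    pairs <- make_pairs(bx, by, sy)
    est <- mr_ivw(pairs)
    ref <- wls_zero_intercept(bx, by, 1 / sy^2)
    expect_equal(est$beta, ref$beta, tolerance = 1e-12)
    expect_equal(est$se, ref$se, tolerance = 1e-12)
  }
})

test_that("IVW is invariant to a common rescaling of the exposure", {
  pairs <- make_pairs(c(0.2, 0.3, 0.4), c(0.05, 0.04, 0.09), c(0.04, 0.05, 0.06))
  scaled <- pairs
  scaled$beta_exposure <- pairs$beta_exposure * 3
  scaled$se_exposure <- pairs$se_exposure * 3
  est <- mr_ivw(pairs)
  est_s <- mr_ivw(scaled)
  expect_equal(est_s$beta * 3, est$beta)
  expect_equal(est_s$se * 3, est$se)
  expect_equal(est_s$q_stat, est$q_stat)
})

test_that("multiplicative random effects inflate the SE only under overdispersion", {
  hom <- make_pairs(rep(0.2, 5), rep(0.04, 5), 0.05)
  expect_equal(mr_ivw(hom, random_effects = TRUE)$se, mr_ivw(hom)$se)
  het <- make_pairs(rep(0.2, 5), c(0.0, 0.05, 0.1, 0.2, 0.4), 0.02)
  fe <- mr_ivw(het)
  re <- mr_ivw(het, random_effects = TRUE)
  expect_equal(re$se, fe$se * sqrt(re$q_stat / re$q_df))
})

test_that("Cochran's Q is zero under homogeneity and extreme for a planted outlier", {
  bx <- rep(0.2, 6)
  hom <- make_pairs(bx, 0.3 * bx, 0.05)
  q <- cochran_q(hom, mr_ivw(hom)$beta)
  expect_equal(q$q, 0)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 5)

  by <- 0.3 * bx
  by[6] <- by[6] + 10 * 0.05  # 10-sigma displacement of one outcome beta
  out <- make_pairs(bx, by, 0.05)
  expect_lt(cochran_q(out, mr_ivw(out)$beta)$pval, 1e-6)
  expect_error(cochran_q(hom[1, ], 0), "at least 2")
})

test_that("MR-Egger recovers an exact line and needs three SNPs", {
  expect_error(mr_egger(make_pairs(c(0.2, 0.3), c(0.1, 0.1), 0.05)), "at least 3")
  bx <- c(0.1, 0.2, 0.3, 0.4)
  a <- 0.03
  b <- 0.25
  pairs <- make_pairs(bx, a + b * bx, 0.05)
  est <- mr_egger(pairs)
  expect_equal(est$beta, b, tolerance = 1e-10)
  expect_equal(est$egger_intercept, a, tolerance = 1e-10)
  expect_equal(est$q_df, 2L)
})

test_that("MR-Egger orients pairs so the exposure beta is non-negative", {
  bx <- c(0.1, -0.2, 0.3, -0.4)
  pairs <- make_pairs(bx, 0.03 * sign(bx) + 0.25 * bx, 0.05)
  est <- mr_egger(pairs)
  expect_equal(est$beta, 0.25, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.03, tolerance = 1e-10)
})

test_that("Egger with the intercept constrained to zero reproduces IVW exactly", {
  set.seed(29)
  bx <- runif(8, 0.05, 0.3)
  by <- rnorm(8, 0.2 * bx, 0.05)
  pairs <- make_pairs(bx, by, runif(8, 0.02, 0.08))
  ivw <- mr_ivw(pairs)
  egg0 <- mr_egger(pairs, intercept = FALSE)
  expect_equal(egg0$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(egg0$se, ivw$se, tolerance = 1e-12)
})

test_that("the Egger intercept covers the mean directional pleiotropic effect", {
  set.seed(31)
  a <- 0.05
  hits <- 0
  reps <- 500
  for (i in seq_len(reps)) {
    pairs <- simulate_pairs(50, theta = 0.2, gamma = runif(50, 0.05, 0.25),
                            se_exposure = 0.005, se_outcome = 0.04,
                            pleio_mean = a, pleio_sd = 0.02)
    est <- mr_egger(pairs)
    hits <- hits + (abs(est$egger_intercept - a) <= 2 * est$egger_intercept_se)
  }
  expect_gte(hits / reps, 0.93)
})

test_that("odds-ratio transforms are exact inverses", {
  expect_equal(to_or(0, 0.1)$or, 1)
  expect_equal(to_or(log(1.05), 0.012)$or, 1.05)
  x <- to_or(0.3, 0.1)
  expect_equal(log(x$or), 0.3)
  expect_equal(x$ci_low, exp(0.3 - qnorm(0.975) * 0.1))
  expect_error(to_or(0.1, 0), "se")

  # mr_result carries the same transform
  est <- mr_ivw(make_pairs(c(0.2, 0.3), c(0.05, 0.04), 0.05))
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
  expect_true(est$ci_low < est$beta && est$beta < est$ci_high)
})
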