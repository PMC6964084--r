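test_that("delimited files round-trip through the canonical columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp\tchrom\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\t1\t1000\tA\tG\t0.3\t0.10\t0.02\t1e-6\t5000",
    "rs2\t1\t600000\tC\tT\t0.2\t-0.05\t0.02\t1e-4\t5000",
    "rs3\t2\t1000\tT\tG\t0.4\t0.02\t0.02\t0.2\t5000"
  ), path)
  x <- read_sumstats(path, trait_id = "exp")
  expect_s3_class(x, "sumstats")
  expect_equal(nrow(x), 3)
  expect_equal(x$snp, c("rs1", "rs2", "rs3"))
  expect_equal(x$beta, c(0.10, -0.05, 0.02))

  # write-then-read with a shuffled column order and a column_map gives back
  # identical records
  shuffled <- withr::local_tempfile(fileext = ".tsv")
  y <- as.data.frame(x)[, rev(names(x))]
  names(y)[names(y) == "snp"] <- "rsid"
  names(y)[names(y) == "beta"] <- "logOR"
  write.table(y, shuffled, sep = "\t", quote = FALSE, row.names = FALSE)
  x2 <- read_sumstats(shuffled, column_map = c(snp = "rsid", beta = "logOR"),
                      trait_id = "exp")
  expect_equal(as.data.frame(x2), as.data.frame(x))
})

test_that("invalid rows are reported with line numbers and skipped, or fatal when strict", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "snp,effect_allele,other_allele,beta,se,pval",
    "rs1,A,G,0.1,0.02,1e-6",
    "rs2,A,G,0.1,0,1e-6",
    "rs3,A,N,0.1,0.02,1e-6"
  ), path)
  expect_warning(x <- read_sumstats(path), "rejected")
  expect_equal(x$snp, "rs1")
  rej <- attr(x, "rejected")
  expect_equal(rej$line, c(3L, 4L))
  expect_match(rej$reason[1], "se")
  expect_match(rej$reason[2], "other_allele")
  expect_error(read_sumstats(path, strict = TRUE), "invalid")
})

test_that("missing mandatory columns are fatal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tbeta\tse\tpval", "rs1\t0.1\t0.02\t1e-6"), path)
  expect_error(read_sumstats(path), "mandatory")
})

test_that("binary-trait case/control counts must be consistent", {
  base <- data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
                     beta = 0.1, se = 0.02, pval = 1e-6,
                     n = 100, n_case = 40, n_control = 50)
  expect_warning(x <- as_sumstats(base, trait_type = "binary"), "n_case")
  expect_equal(nrow(x), 0)
  base$n_control <- 60
  expect_silent(x <- as_sumstats(base, trait_type = "binary"))
  expect_equal(nrow(x), 1)
})

test_that("harmonize aligns, flips, strand-flips and drops as required", {
  ex <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                     ea = c("A", "A", "A", "A", "A"),
                     oa = c("G", "G", "G", "T", "G"),
                     beta = 0.1, eaf = c(0.3, 0.3, 0.3, 0.5, 0.3))
  ou <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                     ea = c("A", "G", "T", "A", "A"),
                     oa = c("G", "A", "C", "T", "C"),
                     beta = 0.2, eaf = c(0.3, 0.7, 0.3, 0.5, 0.3))
  h <- harmonize(ex, ou)
  expect_equal(h$action,
               c("none", "flipped", "none", "dropped_palindromic", "dropped_mismatch"))
  expect_equal(h$beta_outcome[1], 0.2)    # identical orientation
  expect_equal(h$beta_outcome[2], -0.2)   # swapped alleles: sign reversed
  expect_equal(h$beta_outcome[3], 0.2)    # reverse complement, same orientation
  expect_true(all(is.na(h$beta_outcome[4:5])))
  rep <- harmonization_report(h)
  expect_equal(rep$actions$flipped, 1)
  expect_equal(rep$actions$dropped_palindromic, 1)
})

test_that("palindromic SNPs are oriented by allele frequency outside the window", {
  ex <- make_records(c("rs1", "rs2"), ea = "A", oa = "T", beta = 0.1,
                     eaf = c(0.2, 0.2))
  # rs1: same letters, concordant frequency -> untouched
  # rs2: same letters, discordant frequency -> treated as strand+order flip
  ou <- make_records(c("rs1", "rs2"), ea = "A", oa = "T", beta = 0.2,
                     eaf = c(0.25, 0.75))
  h <- harmonize(ex, ou)
  expect_equal(h$action, c("none", "flipped"))
  expect_equal(h$beta_outcome, c(0.2, -0.2))
})

test_that("duplicate SNP ids are fatal", {
  ex <- make_records(c("rs1", "rs1"))
  ou <- make_records("rs1")
  expect_error(harmonize(ex, ou), "duplicate")
})

test_that("harmonize is idempotent and invariant to outcome allele orientation", {
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 30
    pairs_alleles <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("A", "T"), c("C", "G"))
    al <- pairs_alleles[sample.int(5, n, replace = TRUE)]
    ea <- vapply(al, `[`, "", 1)
    oa <- vapply(al, `[`, "", 2)
    eaf <- runif(n, 0.05, 0.95)
    ex <- make_records(sprintf("rs%d", 1:n), ea = ea, oa = oa,
                       beta = rnorm(n, 0, 0.1), eaf = eaf)
    swap <- runif(n) < 0.5
    ea_o <- ifelse(swap, oa, ea)
    oa_o <- ifelse(swap, ea, oa)
    ou <- make_records(sprintf("rs%d", 1:n), ea = ea_o, oa = oa_o,
                       beta = ifelse(swap, -1, 1) * rnorm(n, 0, 0.1),
                       eaf = ifelse(swap, 1 - eaf, eaf) + rnorm(n, 0, 0.01))
    h1 <- harmonize(ex, ou)

    # idempotence: rebuild the outcome from the harmonized output and rerun
    kept <- h1[h1$action %in% c("none", "flipped"), ]
    ou2 <- make_records(kept$snp, ea = kept$effect_allele, oa = kept$other_allele,
                        beta = kept$beta_outcome, se = kept$se_outcome,
                        pval = kept$pval_outcome, eaf = kept$eaf)
    h2 <- harmonize(ex, ou2)
    expect_true(all(h2$action == "none"))
    expect_equal(h2$beta_outcome, kept$beta_outcome)

    # orientation invariance: flip every outcome record's reported allele
    ou_flip <- ou
    ou_flip$effect_allele <- oa_o
    ou_flip$other_allele <- ea_o
    ou_flip$beta <- -ou$beta
    ou_flip$eaf <- 1 - ou$eaf
    h3 <- harmonize(ex, ou_flip)
    expect_equal(h3$beta_outcome, h1$beta_outcome)
    expect_equal(grepl("dropped", h3$action), grepl("dropped", h1$action))
  }
})
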