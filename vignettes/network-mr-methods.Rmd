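---
title: "Methods: network Mendelian randomization in netmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network Mendelian randomization in netmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmr)
```

## The problem

Observationally, ischemic stroke and atrial fibrillation travel together,
and each is entangled with blood pressure, adiposity, inflammation and
glycemic traits. Mendelian randomization (MR) uses genetic variants as
instrumental variables to ask the causal question: because alleles are
assorted at conception, a variant that raises an exposure can stand in for
a randomized nudge to that exposure, provided it (i) is genuinely
associated with the exposure, (ii) shares no confounders with the outcome,
and (iii) affects the outcome only through the exposure (no horizontal
pleiotropy).

`netmr` implements the two-sample, summary-statistics flavour of this
design, organised as a *network*: a three-step mediation scheme

* **Step I** — exposure → outcome (the total effect),
* **Step II** — exposure → mediator, with the exposure's instruments,
* **Step III** — mediator → outcome, with instruments re-selected from the
  mediator's own GWAS,

plus bidirectional runs (roles exchanged, direction-specific instruments)
and analytic power. A trait is declared a *potential mediator* only when
both step II and step III are significant at the configured two-sided
$\alpha$ (default 0.05).

## Estimators

For SNP $j$ with harmonized exposure effect $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) and outcome effect $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$), the
Wald ratio is $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
first-order delta-method SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ (the
second-order term in $\sigma_{Xj}$ is ignored; adequate when instruments
are strong, and stated as a limitation otherwise). The
inverse-variance-weighted (IVW) estimate pools the ratios with weights
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$:

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
\qquad SE = \Big(\sum_j w_j\Big)^{-1/2},$$

algebraically the zero-intercept weighted least-squares slope of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$.
Fixed-effect weighting is the default because the instrument-selection
algorithm below enforces homogeneity before estimation; a multiplicative
random-effects variant (SE inflated by $\sqrt{Q/df}$ when $Q > df$) is
available behind `random_effects = TRUE`. Inference uses a normal
reference; 95% intervals use $z_{0.975} = 1.959964$; binary-outcome
estimates are reported on both the log-odds and the OR scale.

Heterogeneity is measured by Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$ on $n-1$ degrees of
freedom; substantial heterogeneity among valid instruments is the
signature of pleiotropy.

MR-Egger re-fits the weighted regression with a free intercept after
orienting every pair so $\hat\beta_{Xj} \ge 0$. The slope is the
pleiotropy-adjusted causal estimate; the intercept estimates the average
directional pleiotropic effect and its two-sided test is the pleiotropy
test. Egger standard errors are residual-sigma-scaled (multiplicative
overdispersion) with a $t_{n-2}$ reference — under exact weights this
makes the intercept test exactly sized, and under balanced excess
variation it absorbs the overdispersion into the SE. The internal
validation mode `mr_egger(..., intercept = FALSE)` constrains the
intercept to zero with fixed-effect SEs and reproduces IVW exactly; it
exists to pin the algebraic relationship down in tests, not for analysis.
MR-Egger additionally requires the InSIDE assumption (instrument strength
independent of direct effects), which cannot be verified from summary
data; the package tests its *consequences* (intercept calibration and
coverage) on synthetic data where InSIDE holds by construction.

## Instrument construction

Candidate instruments pass an exposure-association screen
($p \le$ `pval_threshold`, default $5\times10^{-4}$, inclusive), then
greedy LD clumping (index SNP = smallest p-value; removal within
`clump_window_bp` = 500 kb when $r^2 >$ `clump_r2` = 0.001). LD is an
explicit input (`ld_info`), since summary files carry no LD; with no LD
table supplied every pairwise $r^2$ is 0 and clumping is a no-op, which is
also the correct behaviour for generated panels in linkage equilibrium.

Per-SNP variance explained is estimated from summary statistics as
$r^2_j = t_j^2/(t_j^2 + n - 2)$, $t_j = \hat\beta_{Xj}/\sigma_{Xj}$ — the
squared genotype–trait correlation — rather than
$2f(1-f)\hat\beta^2$, so it works when allele frequencies are missing.
The greedy selection then seeds with the largest-$r^2$ SNP and repeatedly
adds the candidate maximizing cumulative $r^2$ subject to the augmented
set's Q p-value staying $\ge$ `het_alpha` (default 0.05, the package's
operationalisation of "no heterogeneity", which descriptions of this
selection scheme usually leave unquantified). Q on a single SNP has zero
degrees of freedom and is
treated as passing. Cumulative $r^2$ is the sum of per-SNP values, valid
for instruments in linkage equilibrium (i.e. after clumping). Ties break
on smaller p-value, then lexicographic SNP id, so runs are deterministic.
Instrument strength is summarised by
$F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$ with the conventional $F>10$
rule of thumb.

Greediness is not globally optimal: if the deviant-ratio SNP happens to
carry the largest $r^2$ it seeds the set and blocks every homogeneous
partner. The test suite constructs this counterexample explicitly rather
than hiding it; exhaustive subset search agrees with the greedy result on
all well-separated fixtures up to 12 SNPs.

## Harmonization

SNPs present in both tables are aligned to the exposure's effect allele:
swapped alleles negate the outcome beta and complement its frequency;
alleles matching as reverse complements are strand-flipped first.
Palindromic SNPs (A/T, C/G) are strand-ambiguous: they are oriented by
comparing allele frequencies when both sides are informative and dropped
when either frequency is missing or within `palindromic_eaf_window`
(default 0.08) of 0.5. The window value follows common MR practice; it is
an assumption, surfaced in the harmonization report rather than silently
applied. Harmonization is idempotent, and a wholesale reversal of the
outcome file's reported orientation leaves the harmonized betas unchanged
— both are enforced as property tests.

## Sensitivity analysis

`leave_one_out()` re-estimates IVW with each SNP omitted.
`flag_influential()` flags a SNP when its omission moves the p-value
across $\alpha$ in either direction, or reverses the sign of a
*significant* full-set estimate. The significance condition on sign flips
is a deliberate refinement: around a null estimate the sign is noise and
every omission would "flip" it. No canonical influence criterion exists;
the rule is configurable and always reported. Re-estimation without
flagged SNPs is an explicit, separate step — never automatic — so the
analyst decides what leaves the instrument set.

## Power

For a binary outcome the package uses the normal-approximation log-OR
formula
$\mathrm{power} = \Phi\big(\sqrt{N R^2 K(1-K)}\,|\ln OR| -
z_{1-\alpha/2}\big)$ with $N$ the outcome-study size, $K$ its case
fraction and $R^2$ the instrument variance explained; the continuous
companion replaces $\sqrt{N R^2 K(1-K)}$ by $\sqrt{N R^2}$. At $OR = 1$
both return $\alpha/2$ (one tail). The formula's empirical accuracy is
checked against the IVW rejection rate across simulated datasets. Not
every published mRnd-style power value is reproducible from printed
inputs — web calculators have internal variants — and the package makes
no attempt to chase values whose inputs are not fully stated.

## The synthetic generator

`simulate_gwas()` is the package's test bed, emulating what consortium
summary files provide without any real data: three disjoint cohorts
(two-sample setting), genotypes binomial(2, MAF) under Hardy–Weinberg
equilibrium in linkage equilibrium, a continuous exposure with its own SNP
panel, a mediator with an independent panel, and a binary outcome from a
logistic model whose intercept is set from the baseline prevalence.
Structurally, with latent unit-variance components $U_x, U_m$:

$$X = U_x + \theta_{mx} U_m,\quad M = U_m + \theta_{xm} U_x,\quad
\mathrm{logit}\,P(Y{=}1) = \mathrm{logit}(\pi_0) + \theta_{XY}^{dir} X +
\theta_{MY} M + \textstyle\sum_j \alpha_j G_j.$$

The cross-loading form keeps the system acyclic while letting both
directions carry genetic signal for bidirectional scenarios. Directional
pleiotropy plants $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$ on a
configurable fraction of exposure SNPs. Effects are set by variance
budget (`h2_exposure`, `h2_mediator`), with explicit per-SNP effect
vectors accepted; a budget $\ge 1$ is an error. Marginal binary-trait
associations use a vectorized one-step score approximation (standard GWAS
practice at small per-SNP effects), cross-checked against per-SNP
logistic maximum likelihood in the tests; `logistic_method = "glm"` gives
the exact fits.

What the generator deliberately does **not** emulate: realistic LD maps
(SNPs are independent; clumping is exercised through explicit `ld_info`
tables), sample overlap between studies, population stratification
(adjusted upstream in real consortium GWAS), and binary exposures
measured as diagnoses (the exposure is continuous, matching the
interpretation of a log-odds-scale genetically determined liability).
Consequently, passing tests demonstrate the estimators and pipeline are
correct under the stated model — not that any particular real-data result
is right.

### Fixture scenarios

`make_fixture()` registers five deterministic scenarios: `null`,
`mediation` (paths $a = 0.25$, $b = 0.4$, direct $= 0.3$, hence total
$c = 0.4$ and planted mediated proportion $ab/c = 0.25$), `pleiotropy`,
`outlier_snp` (equal exposure effects $\gamma = 0.14$ and one SNP with a
direct outcome effect of 0.6, so its Wald ratio deviates by $\ge 10$ SE
and its pooled influence is guaranteed rather than left to a random
effect-size draw), and `bidirectional` (one-way causation).

## Numerical and design choices

* **Mediated proportion** is computed on the log-odds/beta scale,
  $(\beta_a \beta_b)/\beta_{total}$; it is invariant to the mediator's
  units. OR-scale conventions disagree with rounded published tables
  either way, so one scale is fixed and reported transparently.
* **Monte-Carlo summaries of ratios.** In the replicate study that checks
  mediated-proportion recovery, the estimate is the ratio of means
  (mean indirect over mean total) with a delta-method Monte-Carlo SE,
  not the mean of per-replicate ratios: at a finite replicate count the
  latter carries an $O(\mathrm{relSE}^2)$ ratio bias that has nothing to
  do with the estimator under test.
* **Recovery-study conditions.** The replicate studies use effects small
  on the log-odds scale (total 0.1) so that logistic non-collapsibility
  — which attenuates marginal per-SNP log-odds effects and is a genuine
  feature of binary outcomes, not a bug — is negligible against the
  Monte-Carlo resolution; and a stricter instrument screen
  ($5\times10^{-6}$) so weak cross-trait associations (exposure SNPs
  leaking into the mediator's instrument set, which violates the
  exclusion restriction for step III) do not contaminate the
  mediator-derived instruments. Problem sizes are 25 + 10 SNPs and
  cohorts of 8,000/8,000/30,000 for mediation recovery (500 replicates),
  20 SNPs and 5,000/5,000 for IVW coverage (1,000 replicates), and
  summary-level draws for the calibration studies (2,000 replicates for
  Q uniformity, 1,000 for the Egger intercept size).
* **Q calibration at the global null.** The uniformity check uses
  $\theta = 0$, where Q is exactly $\chi^2_{n-1}$ conditional on the
  exposure betas (the exposure beta cancels between weight and ratio), so
  the check is exact rather than asymptotic.
* **Degenerate inputs.** Zero exposure betas are errors for ratios and
  IVW; one SNP passes selection trivially; two SNPs cannot support Egger;
  an empty LD table means "no recorded LD", not "missing data".
* **Significance conventions.** Two-sided $\alpha = 0.05$ throughout;
  normal reference for IVW, $t_{n-2}$ for Egger slope and intercept.

## Worked example

```{r example}
fx <- make_fixture("mediation")
net <- run_network(fx$stats$exposure, fx$stats$mediator, fx$stats$outcome,
                   selection_config(pval_threshold = 5e-6), reverse = TRUE)
net
network_report(net, "exposure", "mediator", "outcome")
```

## Known limitations

First-order ratio SEs understate uncertainty for weak instruments; the
greedy selection conditions on the outcome, so its homogeneity guarantee
is in-sample; palindromic-SNP orientation by frequency fails near
MAF 0.5 (hence the drop window); and the mediated proportion inherits the
noise of all three path estimates — single-dataset values should be read
with their implied uncertainty, which the replicate machinery here
quantifies.
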