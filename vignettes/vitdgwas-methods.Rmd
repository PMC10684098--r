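---
title: "Models and methods in vitdgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in vitdgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models the package implements, the
assumptions behind them, the numerical choices that matter, and what the
simulation-based validation does and does not establish. It is the place
where genuinely open design decisions are argued; the README shows the
user-facing surface.

## The synthetic cohort generator

Real biobank genotype-phenotype data for serum 25-hydroxyvitamin D
(25OHD) are access-restricted, so every method in the package is
validated against cohorts generated by `simulate_cohort()`, whose truth
record exposes all planted parameters.

**Allele frequencies.** Ancestry differentiation follows the
Balding–Nichols model: given an ancestral frequency $p$ (uniform on
[0.05, 0.95] unless supplied) and a differentiation parameter $F$, each
ancestry draws its frequency from $\mathrm{Beta}(p(1-F)/F,
(1-p)(1-F)/F)$, with mean $p$ and variance $Fp(1-p)$. $F=0$ returns the
ancestral frequencies; $F=1$ is rejected (degenerate Beta). Drawn
frequencies are clamped to [1e-4, 1-1e-4] so variants keep segregating
and genotype standardization stays defined.

**Linkage disequilibrium.** Haplotypes come from an equicorrelated
latent Gaussian within blocks of `ld_block_size` variants (correlation
`ld_rho`), thresholded at the frequency quantile, and two haplotypes are
summed per sample, so Hardy–Weinberg holds within each ancestry. This
gives controllable block LD without a recombination map — the
downstream methods need LD only as a nuisance/reference structure.
Thresholding a latent Gaussian attenuates the correlation of the binary
alleles relative to `ld_rho` (a tetrachoric effect, strongest at
extreme frequencies), so `ld_rho` is an upper bound on the realized
genotypic correlation; tests therefore assert LD *structure*
(within-block vs across-block) rather than an exact value, and tests
needing a specific $r^2$ construct proxies directly.

**Relatedness.** `related_pairs` pairs share one haplotype (the second
member re-uses the first member's maternal haplotype), giving an
expected genomic relationship of 0.5 — exactly the structure the bK
threshold at 0.05 is meant to separate. A `familial_frac` variance
component is shared within pairs and is untagged by the SNPs, so it
loads on the thresholded-GRM component downstream (covariance within a
pair $\approx 0.5\,\sigma^2_{bK}$, hence $\sigma^2_{bK} \approx 2\times$
the familial variance fraction).

**Skin colour.** An ordinal six-level report (very fair … black) is
obtained by thresholding a latent liability = weighted standardized
pigmentation genotypes + a PC component scaled to `skin_pc_frac` of the
liability variance + Gaussian noise completing the variance to 1.
Thresholds are the standard-normal quantiles of the cumulative
`skin_props`, so configured category proportions are realized in
expectation. The default proportions put roughly 79% of samples in the
light (very fair + fair) group, matching the light:dark contrast the
stratified analysis is designed around.

**Phenotype.** The latent trait sums centred additive
($\beta_a$ per allele), dominance ($\beta_d$ per heterozygote),
genotype-by-skin ($\beta_{g\times e}$ per allele per centred skin
level), a per-level skin shift, a seasonal sinusoid over assessment
month scaled to `month_variance_frac` (default 0.15 — seasonality is
the dominant non-genetic predictor of 25OHD), and Gaussian noise that
completes the variance to approximately 1. It maps to nmol/L as
`baseline_nmol + noise_sd * latent` with defaults 50 and 18.8 nmol/L, a
plausible serum distribution at the residual scale the preprocessing
reports; values outside the 10–375 nmol/L assay range are flagged
excluded. Because effects are in latent-s.d. units on a unit-variance
trait, a planted additive effect $\beta$ at frequency $p$ contributes
$2p(1-p)\beta^2$ of trait variance — the same algebra the power module
uses, which is what makes end-to-end power calibration checks possible.

What the generator does **not** emulate: realistic human LD maps,
admixture tracts and within-group admixture (ancestry groups are
discrete populations), imputation dosages, genotyping batch structure,
and assay measurement error beyond Gaussian noise. Passing tests
demonstrate correctness of the estimators under the stated generative
model, not robustness to those real-data features.

## Ancestry assignment

Reference PCA standardizes genotypes by reference frequencies (mean
$2p$, scale $\sqrt{2p(1-p)}$), drops monomorphic variants, and takes
the top-$k$ right singular vectors ($k = 3$ by default, the number of
PCs used for ancestry calls). Study samples are matched by (chr, pos,
unordered allele pair) — strand-ambiguous A/T and C/G variants are
dropped — standardized by the *reference* moments, and projected onto
the loadings, so reference samples reproduce their own scores exactly
and allele swaps only flip the dosage. Each population's reference
scores are summarized by a Gaussian (mean, covariance ridged by
$10^{-6}\times$ the mean diagonal); assignment is the maximum posterior
with equal priors. Equal priors are a deliberate choice: reference
panel sizes are design artifacts, not population prevalence. No
projection-shrinkage correction is applied; with small reference panels
projected scores shrink toward the origin, a known bias documented here
rather than corrected. Ties are broken by population order and flagged.

## Heritability: two-component GREML

The GRM uses the standard standardized-genotype estimator with
in-sample frequencies and mean imputation of missing calls (the
per-pair SNP count is adjusted). `threshold_grm()` zeroes off-diagonal
entries below 0.05, preserving the diagonal. The two-component model
$V = \sigma^2_g A + \sigma^2_{bK} A_{bK} + \sigma^2_e I$ estimates
SNP-tagged and pedigree-like variance simultaneously without removing
relatives; by the bK convention $h^2_{SNP} = \sigma^2_g/\sigma^2_P$ and
$h^2_{ped} = (\sigma^2_g+\sigma^2_{bK})/\sigma^2_P$.

Numerics: average-information REML with 3 EM warm-up iterations
(stable far from the optimum), AI updates afterwards with step-halving
if an update overshoots twice the phenotypic variance, components
clamped to $[10^{-6}\sigma^2_P, \sigma^2_P]$, convergence when the
restricted log-likelihood changes by less than $10^{-6}$, maximum 100
iterations (non-convergence warns and returns partial results).
Standard errors come from the inverse AI matrix at the solution, with
the delta method for the heritability ratios. The single-component
special case is validated against a brute-force restricted-likelihood
grid search; the test suite uses $n = 300$ for the grid oracle and
$n = 2{,}000$, $m = 5{,}000$ with 150 related pairs for the recovery
check — sizes at which the dense $n \times n$ solves stay in seconds
while leaving the estimates well identified.

Estimate differences are compared with the two-sided Z-test
$z = (\hat\theta_1-\hat\theta_2)/\sqrt{se_1^2+se_2^2}$. Whether such
tests should be one- or two-sided is genuinely open; two-sided is
implemented throughout because no directional hypothesis precedes the
comparison.

## Association testing

**RINT.** $\Phi^{-1}((r - 3/8)/(n + 1/4))$ with average ranks for ties
(the Blom offset — the conventional choice where none is dictated);
degenerate inputs (all values equal) are rejected.

**Additive scan.** OLS mode residualizes the phenotype and every
genotype on the covariates once (QR), then fits per-variant simple
regressions — by Frisch–Waugh this *equals* the full multiple
regression coefficient, standard error and p, and the suite asserts
that equality at $10^{-10}$. GLS mode estimates
$(\sigma^2_g, \sigma^2_e)$ once on the null model from a (typically
bK-sparse) GRM and then whitens — the one-variance-estimate
approximation used by sparse-GRM mixed-model GWAS; it is exact when
$V \propto I$ and approximate otherwise, by design. Collinear
covariates are rejected with the offending columns named.

**Dominance scan.** The joint model fits additive (0,1,2) and
dominance (0,1,0) codings; the dominance term is tested by the Wald
$\chi^2_1$. The (0,1,0) indicator is deliberately uncentred and
non-orthogonal to the additive coding, so additive coefficients from
this joint fit are computed but not reported as effect estimates — on
skewed frequencies they differ from the marginal additive estimate, and
a test asserts that inequality rather than hiding it. Variants with no
heterozygotes are flagged inestimable rather than erroring.

**Meta-analysis and scores.** Fixed-effect IVW with weights
$1/se_i^2$; alleles are harmonized across strata by negation/reflection
and unresolvable mismatches are skipped with a warning. The
implementation is cross-checked against an independent fixed-effect
meta-analysis implementation in the test suite. Polygenic scores are
weighted allele sums with mean imputation ($2p \times$ weight) for
missing genotypes.

## Conditional-and-joint selection from summary statistics

For a candidate set $S$ the machinery reconstructs the sufficient
statistics of the multiple regression from the `.ma` rows: the diagonal
scale $D_j$ (variance-weighted sample size), the score $X^\top y = D_j
b_j$, and $y^\top y$ from $D_j(se_j^2(N_j-2)+b_j^2)$, taken as the
median across variants for robustness to per-SNP sample-size
variation. Off-diagonal cross-products come from the LD reference, with
pairs farther apart than the 10-Mb window (or on different
chromosomes) fixed at exactly zero.

Two scale modes: `"freq"` sets $D_j = 2p_j(1-p_j)N_j$ from the summary
rows (appropriate with an external LD panel); `"genotype"` takes the
centred cross-products of the reference genotypes directly, which makes
the joint estimates *exactly* equal the individual-level multiple
regression when the reference is the GWAS sample itself — the oracle
equivalence the acceptance suite asserts at $10^{-6}$ (it holds at
machine precision). Stepwise selection seeds with the most significant
variant below $5\times10^{-8}$, adds the best conditionally significant
candidate each round unless collinear (multiple-regression $R^2 \ge
0.9$ with the selected set), drops selected variants whose joint p
rises above threshold, and reports joint effects with explained
variance $2p(1-p)b_J^2$. Ties in minimal conditional p break by smaller
position then lexicographic id — a deterministic pipeline needs *some*
rule. Variants whose summary frequency deviates from the reference
frequency by more than 0.2 are excluded as probable allele mislabeling.

The residual-based dominance conditional test regresses the adjusted
phenotype on both codings of the conditioning SNP and re-runs the
dominance scan on the residuals. The residuals are *not* re-RINTed:
re-transforming would break the self-conditioning identity (the
conditioned SNP's effect must vanish exactly) and the phenotype is
already normalized; this is a divergence risk relative to descriptions
that mention transformed residuals, and it is the choice made here.

## Cross-analysis comparison

The error-adjusted effect correlation
$r_b = \mathrm{cov}(\hat b_x,\hat b_y) / \sqrt{(\mathrm{var}(\hat b_x)-\overline{se_x^2})(\mathrm{var}(\hat b_y)-\overline{se_y^2})}$
removes the attenuation sampling noise induces in the naive Pearson
correlation (reliability $= \mathrm{var}(b)/(\mathrm{var}(b)+\overline{se^2})$
per side). Its standard error is a leave-one-variant-out jackknife: the
estimator is a smooth functional of variant-level moments, the
jackknife is the defensible generic choice, and no closed-form se
formula is adopted (the t-statistic sometimes presented alongside this
estimator is a per-variant difference test, not a standard error).
Estimates slightly outside [−1, 1] can occur when the subtracted noise
terms are large; values beyond 1.05 are flagged. A side whose effect
variance does not exceed its mean squared standard error has no
detectable signal and the function errors naming that side.

Locus classification between two GWAS uses only thresholds, positions
and LD: shared (genome-wide significant in both), new (GWS in one,
sub-labelled by whether the other shows suggestive evidence at
$10^{-6}$), lost (the converse), with 1-Mb-radius distance and maximal
LD $r^2$ annotation against the other analysis's GWS variants.

## Stratified analysis

Skin-colour strata follow the light (very fair, fair) / dark (light
olive, dark olive, brown) grouping; "black" reports within the light
skin ancestry group, inconsistent repeat reports, and unknown
categories are excluded with per-reason counts. Within each stratum the
phenotype is RINT-transformed *per stratum* and PCs are recomputed on
the stratum's samples before the additive scan; per-stratum RINT is the
interpretation of "adjusting for both mean and variance differences"
between strata — pooled RINT would preserve the variance gap the
stratification exists to remove. The meta-analysis is restricted to
variants passing the MAF floor (0.01) in *every* stratum.

## Gene-by-skin-colour interaction

Preprocessing runs within sex × supplement strata (up to 8): regress on
covariates, drop |standardized residual| > 5 (a configurable rule;
5 s.d. removes essentially nothing under Gaussian noise,
$2\Phi(-5) \approx 5.7\times10^{-7}$, while catching data errors),
re-standardize, and report each stratum's pre-standardization residual
s.d. in nmol/L — the scale `sd_to_nmol()` uses to convert model
coefficients. The vQTL screen is the median-based Levene
(Brown–Forsythe) test across genotype groups — a self-contained stand-in
for an externally supplied vQTL list, letting the pipeline run without
one. The interaction model `y ~ g + e + g×e` mean-centres the genotype
and codes skin as indicators against the very-fair reference; the
family-wise threshold is 0.05 divided by the number of vQTLs tested
(0.002 for 25). The genome-wide interaction scan is restricted to two
skin levels and MAF > 0.05, where interaction coefficients of common
variants are well behaved. With a single skin level present the model
reduces exactly to the additive fit.

## Enrichment and power

The permutation enrichment draws `n_perm` (default 10,000) same-size
SNP sets without replacement from the supplied pool and reports the
one-tailed empirical p as the count of null sets with at least the
observed number of trait-associated SNPs, divided by `n_perm` — no +1
pseudo-count, faithful to the stated rule, with the 1/`n_perm` floor
reported alongside so a zero count is never read as p = 0. The pool is
used verbatim (test-set SNPs are not excluded), matching the design
where the pool is the full locus list. "Associated" means minimum p
across the queried traits below the threshold. On the single-trait
reduction the empirical p converges to the exact hypergeometric tail,
which the acceptance suite checks.

Power composes $h^2_{QTL} = 2p(1-p)\beta^2$,
$\lambda = N h^2_{QTL}/(1-h^2_{QTL})$, and
$P(\chi^2_1(\lambda) > q_\alpha)$; at $\lambda = 0$ power equals
$\alpha$ exactly, which doubles as a correctness identity in the tests.

## Problem sizes and budgets

The validation sizes were chosen so each estimator is well identified
while the full suite runs in well under a minute per module:
COJO-vs-oracle at $n = 2{,}000$, $m = 200$; REML at $n = 2{,}000$,
$m = 5{,}000$; dominance calibration on 1,000 variants at $n = 4{,}000$
and power at $n = 20{,}000$ over 200–300 replicates; $r_b$ over 200
replicates of 1,000 variants; the Monte-Carlo power oracle at $10^5$
draws; ancestry at 4 × 500 reference samples. The acceptance script
re-runs the same designs seeded from `--seed`.

## Known limitations

* The GLS association mode fixes variance components at their null-model
  estimates (no per-variant refit, no score/saddlepoint refinement).
* The bK heritability split identifies $\sigma^2_{bK}$ only through
  related-pair covariances; with few pairs its standard error is large,
  and the simulator's expected $\sigma^2_{bK} \approx 2\times$
  `familial_frac` holds only at pair relatedness 0.5.
* Projection PCA shrinks study scores when reference panels are small.
* The `.ma`-based machinery assumes effects estimated on a standardized
  (RINT) trait; mixing scales across strata breaks the reconstruction.
* Genetic correlations across ancestry groups, Bayesian fine-mapping,
  admixture-aware models and X-chromosome analyses are out of scope.
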