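sim_gwas_ma <- function(cfg) {
  sim <- simulate_cohort(cfg)
  y <- rint(sim$cohort$vitd)
  rec <- additive_gwas(y, sim$genotypes, NULL)
  list(sim = sim, y = y, rec = rec, ma = as_ma(rec),
       ld = make_ld_ref(sim$genotypes))
}

test_that("a single significant variant is selected with joint equal to marginal", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 2000), m_variants = 100, fst = 0,
                    ld_block_size = 10, ld_rho = 0, month_variance_frac = 0,
                    causal_additive = data.frame(index = 42, beta = 0.35),
                    n_chr = 1, seed = 40)
  x <- sim_gwas_ma(cfg)
  res <- cojo_select(x$ma, x$ld, scale = "genotype")
  expect_identical(res$selected$SNP, "snp000042")
  expect_lt(abs(res$selected$bJ - res$selected$b), 1e-10)
  expect_lt(abs(res$selected$seJ - res$selected$se), 1e-3)
  expect_true(all(res$selected$pJ < 5e-8))
})

test_that("independent causal variants are both selected with near-marginal joints", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 3000), m_variants = 100, fst = 0,
                    ld_block_size = 10, ld_rho = 0, month_variance_frac = 0,
                    causal_additive = data.frame(index = c(15, 85),
                                                 beta = c(0.3, 0.3)),
                    n_chr = 1, seed = 41)
  x <- sim_gwas_ma(cfg)
  res <- cojo_select(x$ma, x$ld, scale = "genotype")
  expect_setequal(res$selected$SNP, c("snp000015", "snp000085"))
  expect_lt(max(abs(res$selected$bJ - res$selected$b)), 0.05)
})

test_that("summary-based joint fit equals individual-level regression across seeds", {
  for (seed in c(42, 142, 242)) {
    cfg <- sim_config(n_per_ancestry = c(EUR = 2000), m_variants = 200,
                      fst = 0, ld_block_size = 10, ld_rho = 0.4,
                      month_variance_frac = 0,
                      causal_additive = data.frame(index = c(25, 90, 160),
                                                   beta = c(0.3, 0.25, 0.3)),
                      n_chr = 1, seed = seed)
    x <- sim_gwas_ma(cfg)
    res <- cojo_select(x$ma, x$ld, scale = "genotype")
    expect_gt(nrow(res$selected), 0)
    idx <- match(res$selected$SNP, x$sim$genotypes$variants$id)
    f <- summary(lm(x$y ~ x$sim$genotypes$values[, idx, drop = FALSE]))$coefficients
    expect_lt(max(abs(res$selected$bJ - f[-1, 1])), 1e-6)
    expect_lt(max(abs(res$selected$seJ - f[-1, 2])), 1e-6)
    # explained variances of a standardized trait stay below 1 in total
    expect_lt(sum(res$selected$varexp), 1 + 0.05)
  }
})

test_that("selection is invariant to input row order", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 2000), m_variants = 100, fst = 0,
                    ld_block_size = 10, ld_rho = 0.5, month_variance_frac = 0,
                    causal_additive = data.frame(index = c(12, 66),
                                                 beta = c(0.3, 0.3)),
                    n_chr = 1, seed = 43)
  x <- sim_gwas_ma(cfg)
  res1 <- cojo_select(x$ma, x$ld, scale = "genotype")
  set.seed(1)
  res2 <- cojo_select(x$ma[sample(nrow(x$ma)), ], x$ld, scale = "genotype")
  expect_identical(res1$selected$SNP, res2$selected$SNP)
  expect_equal(res1$selected$bJ, res2$selected$bJ, tolerance = 1e-12)
})

test_that("no variant below threshold yields an empty, non-error result", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 500), m_variants = 50, fst = 0,
                    ld_block_size = 10, month_variance_frac = 0, n_chr = 1,
                    seed = 44)
  x <- sim_gwas_ma(cfg)
  res <- cojo_select(x$ma, x$ld, scale = "genotype")
  expect_identical(nrow(res$selected), 0L)
})

test_that("conditional scan kills LD proxies but not independent signals", {
  set.seed(45)
  n <- 4000
  causal <- rbinom(n, 2, 0.4)
  proxy <- causal
  swap <- sample(n, round(0.1 * n))      # ~r2 0.8 with the causal variant
  proxy[swap] <- rbinom(length(swap), 2, 0.4)
  indep <- rbinom(n, 2, 0.3)
  g <- make_geno(cbind(causal, proxy, indep), ids = c("causal", "proxy", "indep"))
  y <- 0.25 * causal + 0.2 * indep + rnorm(n)
  y <- rint(y)
  rec <- additive_gwas(y, g, NULL)
  ma <- as_ma(rec)
  ld <- make_ld_ref(g)
  expect_gt(cor(causal, proxy)^2, 0.6)
  expect_lt(ma$p[ma$SNP == "proxy"], 5e-8)   # pure-LD proxy is marginally GWS
  cs <- conditional_scan(ma, ld, condition_set = "causal", scale = "genotype")
  # the conditioned variant itself: zero effect, collinear flag
  self <- cs[cs$SNP == "causal", ]
  expect_true(self$collinear)
  expect_identical(self$b, 0)
  # the proxy loses significance once the causal variant is conditioned on
  expect_gt(cs$p[cs$SNP == "proxy"], 0.05)
  # the independent signal survives
  expect_lt(cs$p[cs$SNP == "indep"], 1e-4)
})

test_that("conditioning on a windowed-out variant changes nothing", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 1000), m_variants = 20, fst = 0,
                    ld_block_size = 10, month_variance_frac = 0,
                    causal_additive = data.frame(index = 15, beta = 0.3),
                    n_chr = 2, seed = 46)
  x <- sim_gwas_ma(cfg)
  # condition set on chromosome 1; test variants on chromosome 2 are
  # beyond the window rule, so their conditional effects equal marginals
  cs <- conditional_scan(x$ma, x$ld, condition_set = "snp000003",
                         scale = "genotype")
  chr2 <- x$sim$genotypes$variants$id[x$sim$genotypes$variants$chr == 2]
  got <- cs$b[match(chr2, cs$SNP)]
  want <- x$ma$b[match(chr2, x$ma$SNP)]
  expect_lt(max(abs(got - want)), 1e-10)
  sewant <- x$ma$se[match(chr2, x$ma$SNP)]
  expect_lt(max(abs(cs$se[match(chr2, cs$SNP)] / sewant - 1)), 0.05)
})

test_that("dominance conditional procedure separates independent QTLs", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 20000), m_variants = 30, fst = 0,
                    ld_block_size = 10, ld_rho = 0.1, month_variance_frac = 0,
                    causal_dominance = data.frame(index = c(5, 25),
                                                  beta = c(0.12, 0.12)),
                    n_chr = 1, seed = 46)
  sim <- simulate_cohort(cfg)
  y <- rint(sim$cohort$vitd)
  ids <- sim$genotypes$variants$id
  # self-conditioning nulls the effect
  dc_self <- dominance_conditional(y, sim$genotypes, ids[5], ids[5])
  expect_lt(abs(dc_self$beta), 1e-10)
  # the other planted QTL (different block, r2 ~ 0) survives conditioning
  dc <- dominance_conditional(y, sim$genotypes, ids[5], ids[25])
  expect_lt(dc$p, 1e-4)
  # a near-perfect proxy of the conditioning SNP is extinguished
  g2 <- sim$genotypes
  g2$values <- cbind(g2$values, g2$values[, 5])
  g2$variants <- rbind(g2$variants,
                       data.frame(chr = 1, pos = max(g2$variants$pos) + 5000,
                                  id = "proxy", A1 = "A", A2 = "G"))
  dcp <- dominance_conditional(y, g2, ids[5], "proxy")
  expect_gt(dcp$p, 0.05)
})
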