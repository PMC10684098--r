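test_that("RINT has Blom scores, symmetry, and unit moments", {
  expect_identical(rint(c(5, 1, 3))[3], 0)           # middle of 3 maps to 0
  x <- c(2.3, -1, 0.5, 7, NA)
  r <- rint(x)
  expect_identical(order(r[!is.na(r)]), order(x[!is.na(x)]))
  expect_true(is.na(r[5]))
  set.seed(24)
  big <- rint(rexp(10000))
  expect_lt(abs(mean(big)), 0.02)
  expect_lt(abs(var(big) - 1), 0.02)
  expect_error(rint(rep(1, 5)), "identical")
  # ties share the average-rank score
  rt <- rint(c(1, 2, 2, 3))
  expect_identical(rt[2], rt[3])
})

test_that("variant QC applies MAF, HWE and missingness filters with MAC report", {
  G <- cbind(rep(0L, 1000),                 # monomorphic
             rep(1L, 1000),                 # all hets: extreme HWE failure
             rbinom(1000, 2, 0.3))
  g <- make_geno(G)
  qc <- variant_qc(g, maf_min = 0.01, n_smallest = 2279)
  expect_false(qc$keep[1])
  expect_false(qc$keep[2])
  # all-het chi2: observed (0,1000,0) vs expected (250,500,250) -> huge
  expect_lt(qc$hwe_p[2], 1e-100)
  expect_true(qc$keep[3])
  # MAC arithmetic: MAF 0.002 x 2 x 2279 = 9.116
  G2 <- matrix(0L, 1000, 1); G2[1:2, 1] <- 1L
  qc2 <- variant_qc(make_geno(G2), maf_min = 0, n_smallest = 2279)
  expect_equal(qc2$mac_smallest, 0.001 * 2 * 2279)
  expect_equal(qc2$mac, 0.001 * 2 * 1000)
})

test_that("additive OLS scan equals brute-force multiple regression", {
  set.seed(25)
  cfg <- sim_config(n_per_ancestry = c(EUR = 400), m_variants = 30, fst = 0,
                    ld_block_size = 10, ld_rho = 0.3, seed = 26)
  sim <- simulate_cohort(cfg)
  y <- rint(sim$cohort$vitd)
  cov <- cbind(age = sim$cohort$age, month = sim$cohort$month)
  rec <- additive_gwas(y, sim$genotypes, cov)
  for (j in c(1, 11, 30)) {
    f <- summary(lm(y ~ sim$genotypes$values[, j] + cov))$coefficients
    expect_lt(abs(rec$beta[j] - f[2, 1]), 1e-10)
    expect_lt(abs(rec$se[j] - f[2, 2]), 1e-10)
  }
  expect_error(additive_gwas(y, sim$genotypes, cbind(cov, age2 = cov[, "age"])),
               "collinear")
})

test_that("allele flip negates beta, reflects freq, leaves p unchanged", {
  set.seed(27)
  cfg <- sim_config(n_per_ancestry = c(EUR = 300), m_variants = 10, fst = 0,
                    ld_block_size = 10, seed = 28)
  sim <- simulate_cohort(cfg)
  y <- rint(sim$cohort$vitd)
  rec <- additive_gwas(y, sim$genotypes, NULL)
  flip <- sim$genotypes
  flip$values <- 2L - flip$values
  rec2 <- additive_gwas(y, flip, NULL)
  expect_equal(rec2$beta, -rec$beta, tolerance = 1e-10)
  expect_equal(rec2$freq, 1 - rec$freq, tolerance = 1e-12)
  expect_equal(rec2$p, rec$p, tolerance = 1e-10)
})

test_that("additive scan is null-calibrated and recovers a planted QTL", {
  set.seed(29)
  cfg0 <- sim_config(n_per_ancestry = c(EUR = 1000), m_variants = 1000,
                     fst = 0, ld_block_size = 10, month_variance_frac = 0,
                     seed = 30)
  sim0 <- simulate_cohort(cfg0)
  rec0 <- additive_gwas(rint(sim0$cohort$vitd), sim0$genotypes, NULL)
  expect_lt(abs(mean(rec0$p < 0.05) - 0.05), 0.014)

  beta <- sqrt(0.01 / (2 * 0.25))
  cfg1 <- sim_config(n_per_ancestry = c(EUR = 5000), m_variants = 20, fst = 0,
                     ld_block_size = 10, month_variance_frac = 0,
                     causal_additive = data.frame(index = 7, beta = beta),
                     seed = 31)
  sim1 <- simulate_cohort(cfg1)
  rec1 <- additive_gwas(rint(sim1$cohort$vitd), sim1$genotypes, NULL)
  expect_lt(abs(rec1$beta[7] - sim1$truth$effects$beta_a[7]), 2 * rec1$se[7])
})

test_that("GLS with V proportional to identity reproduces OLS exactly", {
  set.seed(32)
  cfg <- sim_config(n_per_ancestry = c(EUR = 200), m_variants = 20, fst = 0,
                    ld_block_size = 10, seed = 33)
  sim <- simulate_cohort(cfg)
  y <- rint(sim$cohort$vitd)
  eye <- structure(list(A = diag(200), nsnp = NULL, ids = sim$genotypes$samples$id),
                   class = "grm")
  a <- additive_gwas(y, sim$genotypes, NULL, mode = "ols")
  b <- additive_gwas(y, sim$genotypes, NULL, mode = "gls", grm = eye)
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-8)
})

test_that("dominance scan matches the joint OLS Wald statistic and flags no-het variants", {
  set.seed(34)
  cfg <- sim_config(n_per_ancestry = c(EUR = 500), m_variants = 10, fst = 0,
                    ld_block_size = 10, month_variance_frac = 0, seed = 35)
  sim <- simulate_cohort(cfg)
  y <- rint(sim$cohort$vitd)
  rec <- dominance_gwas(y, sim$genotypes)
  j <- 4
  f <- summary(lm(y ~ sim$genotypes$values[, j] +
                    I(as.numeric(sim$genotypes$values[, j] == 1))))$coefficients
  expect_lt(abs(rec$beta[j] - f[3, 1]), 1e-8)
  chi2 <- (f[3, 1] / f[3, 2])^2
  expect_lt(abs((rec$beta[j] / rec$se[j])^2 - chi2), 1e-8)

  g2 <- sim$genotypes
  g2$values[, 1] <- ifelse(g2$values[, 1] == 1L, 0L, g2$values[, 1])
  rec2 <- dominance_gwas(y, g2)
  expect_identical(rec2$flag[1], "no_heterozygotes")
  expect_true(is.na(rec2$beta[1]))
})

test_that("joint-fit additive estimate differs from the marginal at skewed frequency", {
  set.seed(36)
  n <- 4000
  x <- rbinom(n, 2, 0.15)
  d <- 0.4
  y <- 0.2 * x + d * as.numeric(x == 1) + rnorm(n)
  marg <- coef(lm(y ~ x))[2]
  joint <- coef(lm(y ~ x + I(as.numeric(x == 1))))[2]
  expect_gt(abs(marg - joint), 0.05)   # non-orthogonal codings
})

test_that("IVW meta reproduces hand arithmetic, identities, and metafor", {
  mk <- function(beta, se, A1 = "A", A2 = "G", freq = 0.3, n = 100)
    data.frame(chr = 1, pos = 1, id = "s", A1 = A1, A2 = A2, freq = freq,
               n = n, beta = beta, se = se, p = 0.5, test = "additive")
  # single stratum passes through
  one <- meta_ivw(list(mk(0.1, 0.02)))
  expect_equal(one$beta, 0.1)
  expect_identical(one$test, "meta")
  # equal se: mean and se/sqrt(2)
  eq <- meta_ivw(list(mk(0.1, 0.02), mk(0.3, 0.02)))
  expect_equal(eq$beta, 0.2)
  expect_equal(eq$se, 0.02 / sqrt(2))
  # hand-worked weights
  hw <- meta_ivw(list(mk(0.10, 0.02), mk(0.02, 0.01)))
  expect_equal(hw$beta, 0.036, tolerance = 1e-12)
  expect_equal(hw$se, 1 / sqrt(12500), tolerance = 1e-12)
  # allele flip harmonized
  fl <- meta_ivw(list(mk(0.1, 0.02), mk(-0.1, 0.02, A1 = "G", A2 = "A", freq = 0.7)))
  expect_equal(fl$beta, 0.1)
  # independent implementation cross-check
  rf <- metafor::rma(yi = c(0.10, 0.02), sei = c(0.02, 0.01), method = "FE")
  expect_equal(hw$beta, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(hw$se, rf$se, tolerance = 1e-10)
})

test_that("polygenic scores equal dosage sums and track the genetic value", {
  set.seed(37)
  cfg <- sim_config(n_per_ancestry = c(EUR = 5000), m_variants = 50, fst = 0,
                    ld_block_size = 10, month_variance_frac = 0,
                    causal_additive = data.frame(index = c(5, 25, 45),
                                                 beta = c(0.2, -0.15, 0.1)),
                    seed = 38)
  sim <- simulate_cohort(cfg)
  v <- sim$genotypes$variants
  w0 <- data.frame(id = v$id[1:3], effect_allele = v$A1[1:3], weight = 0)
  expect_identical(unique(polygenic_score(sim$genotypes, w0)), 0)
  w1 <- data.frame(id = v$id[2], effect_allele = v$A1[2], weight = 1)
  expect_identical(polygenic_score(sim$genotypes, w1),
                   as.numeric(sim$genotypes$values[, 2]))
  tr <- sim$truth$effects
  wT <- data.frame(id = tr$id[tr$beta_a != 0], effect_allele = v$A1[tr$beta_a != 0],
                   weight = tr$beta_a[tr$beta_a != 0])
  expect_gt(cor(polygenic_score(sim$genotypes, wT), sim$truth$genetic_value), 0.95)
  expect_error(polygenic_score(sim$genotypes,
                               data.frame(id = "zz", effect_allele = "A", weight = 1)),
               "overlap")
})
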