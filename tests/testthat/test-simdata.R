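test_that("Balding-Nichols frequencies have the right limits and moments", {
  cfg0 <- sim_config(n_per_ancestry = c(EUR = 10, AFR = 10), m_variants = 50,
                     fst = 0, ld_block_size = 10, seed = 1)
  fr0 <- simulate_frequencies(cfg0)
  expect_lt(max(abs(fr0$EUR - fr0$ancestral)), 1e-6)
  expect_lt(max(abs(fr0$AFR - fr0$ancestral)), 1e-6)

  m <- 10000
  cfg <- sim_config(n_per_ancestry = c(EUR = 10), m_variants = m, fst = 0.1,
                    ld_block_size = 10, seed = 2)
  fr <- simulate_frequencies(cfg, ancestral = rep(0.5, m))
  v <- var(fr$EUR)
  expect_lt(abs(v - 0.1 * 0.25) / 0.025, 0.10)   # F p(1-p) within 10%
  expect_lt(abs(mean(fr$EUR) - 0.5), 0.01)

  fr2 <- simulate_frequencies(cfg, ancestral = rep(0.5, m))
  expect_identical(fr, fr2)
  expect_error(sim_config(fst = 1), "fst")
})

test_that("genotypes satisfy HWE, block LD structure, and determinism", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 10000), m_variants = 20,
                    fst = 0, ld_block_size = 10, ld_rho = 0, seed = 3)
  fr <- simulate_frequencies(cfg, ancestral = rep(0.5, 20))
  g <- simulate_genotypes(fr, cfg)
  tab <- table(g$values[, 1]) / 10000
  expect_lt(abs(tab[["0"]] - 0.25), 0.02)
  expect_lt(abs(tab[["1"]] - 0.50), 0.02)
  expect_lt(abs(tab[["2"]] - 0.25), 0.02)
  expect_true(all(g$values %in% 0:2))
  expect_true(all(tapply(g$variants$pos, g$variants$chr, function(p) all(diff(p) > 0))))

  cfg_ld <- sim_config(n_per_ancestry = c(EUR = 2000), m_variants = 40,
                       fst = 0, ld_block_size = 10, ld_rho = 0.6, seed = 4)
  gld <- simulate_genotypes(simulate_frequencies(cfg_ld), cfg_ld)
  R2 <- cor(gld$values)^2
  within <- R2[1:10, 1:10][upper.tri(R2[1:10, 1:10])]
  across <- R2[1:10, 11:20]
  expect_gt(mean(within), 0.1)          # clear within-block LD
  expect_lt(mean(across), 0.01)         # none across blocks

  g2 <- simulate_genotypes(simulate_frequencies(cfg_ld), cfg_ld)
  expect_identical(gld$values, g2$values)
})

test_that("related pairs share about half their genome on the GRM scale", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 200), m_variants = 2000,
                    fst = 0, ld_block_size = 10, related_pairs = 5, seed = 5)
  g <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  A <- compute_grm(g)$A
  pr <- g$related_pairs
  entries <- A[cbind(pr$a, pr$b)]
  expect_true(all(abs(entries - 0.5) < 0.1))
})

test_that("skin-colour liability realizes the configured PC variance share", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 10000), m_variants = 20,
                    fst = 0, ld_block_size = 10, skin_pc_frac = 0.15, seed = 6)
  g <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  pcs <- matrix(rnorm(10000), ncol = 1)
  sk <- simulate_skin_colour(g, pcs, cfg)
  r2 <- summary(lm(sk$liability ~ pcs))$r.squared
  expect_lt(abs(r2 - 0.15), 0.02)
  expect_identical(sum(table(sk$skin)), 10000L)
  expect_true(all(diff(sk$thresholds) > 0))

  # no genetic or PC weight: skin independent of genotype
  cfg0 <- sim_config(n_per_ancestry = c(EUR = 2000), m_variants = 20,
                     fst = 0, ld_block_size = 10, seed = 7)
  g0 <- simulate_genotypes(simulate_frequencies(cfg0), cfg0)
  sk0 <- simulate_skin_colour(g0, NULL, cfg0)
  p <- suppressWarnings(chisq.test(table(g0$values[, 1], sk0$skin))$p.value)
  expect_gt(p, 0.001)
})

test_that("phenotype variance decomposes as configured", {
  # all effects zero: variance equals noise_sd^2
  cfg0 <- sim_config(n_per_ancestry = c(EUR = 10000), m_variants = 20,
                     fst = 0, ld_block_size = 10, month_variance_frac = 0,
                     noise_sd = 18.8, seed = 8)
  sim0 <- simulate_cohort(cfg0)
  expect_lt(abs(var(sim0$cohort$vitd) / 18.8^2 - 1), 0.05)

  # single additive QTL recovered within 2 se
  cfg1 <- sim_config(n_per_ancestry = c(EUR = 10000), m_variants = 20,
                     fst = 0, ld_block_size = 10, month_variance_frac = 0,
                     causal_additive = data.frame(index = 3, beta = sqrt(0.01 / (2 * 0.25))),
                     seed = 9)
  sim1 <- simulate_cohort(cfg1)
  z <- scale(sim1$cohort$vitd)
  f <- summary(lm(z ~ sim1$genotypes$values[, 3]))$coefficients
  beta_true <- sim1$truth$effects$beta_a[3]
  expect_lt(abs(f[2, 1] - beta_true), 2 * f[2, 2])

  # month component realizes its variance fraction
  cfg2 <- sim_config(n_per_ancestry = c(EUR = 10000), m_variants = 20,
                     fst = 0, ld_block_size = 10, month_variance_frac = 0.15,
                     seed = 10)
  sim2 <- simulate_cohort(cfg2)
  r2 <- summary(lm(sim2$cohort$vitd ~ factor(sim2$cohort$month)))$r.squared
  expect_lt(abs(r2 - 0.15), 0.02)

  # realized per-variant h2 equals 2p(1-p)beta^2 from the truth record
  tr <- sim1$truth$effects[3, ]
  expect_lt(abs(var(sim1$truth$genetic_value) -
                  2 * tr$freq * (1 - tr$freq) * tr$beta_a^2), 0.002)
})

test_that("cohort summary reports deficiency prevalence per ancestry", {
  cohort <- data.frame(IID = 1:6, vitd = c(20, 30, 40, 15, 60, 70),
                       ancestry = c("A", "A", "A", "B", "B", "B"),
                       excluded = FALSE)
  s <- summarize_cohort(cohort, deficiency_threshold = 25)
  expect_equal(s$prevalence[s$ancestry == "A"], 1 / 3)
  expect_equal(s$prevalence[s$ancestry == "B"], 1 / 3)
  expect_equal(summarize_cohort(cohort, deficiency_threshold = 0)$prevalence,
               c(0, 0))
  expect_equal(summarize_cohort(cohort, deficiency_threshold = 10)$prevalence,
               c(0, 0))

  # darker-skin groups with negative skin effect are more often deficient
  cfg <- sim_config(n_per_ancestry = c(EUR = 8000), m_variants = 20,
                    fst = 0, ld_block_size = 10, skin_effect_sd = -0.5,
                    month_variance_frac = 0, seed = 11)
  sim <- simulate_cohort(cfg)
  dark <- sim$cohort$skin %in% c("dark olive", "brown", "black")
  prev <- tapply(sim$cohort$vitd < 25, dark, mean)
  expect_gt(prev[["TRUE"]], prev[["FALSE"]])
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- sim_config(n_per_ancestry = c(EUR = 200, AFR = 100), m_variants = 50,
                    fst = 0.05, ld_block_size = 10, ld_rho = 0.4,
                    related_pairs = 3, seed = 12)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(m_variants = 10, ld_block_size = 3), "divide")
  expect_error(sim_config(causal_additive = data.frame(index = 99999, beta = 1),
                          m_variants = 10, ld_block_size = 10), "indices")
  expect_error(sim_config(month_variance_frac = 0.7, familial_frac = 0.7),
               "sum")
  # non-causal variants carry exact zeros in the truth record
  cfg <- sim_config(n_per_ancestry = c(EUR = 50), m_variants = 20, fst = 0,
                    ld_block_size = 10,
                    causal_additive = data.frame(index = 4, beta = 0.3), seed = 1)
  sim <- simulate_cohort(cfg)
  expect_identical(sim$truth$effects$beta_a[-4], rep(0, 19))
})
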