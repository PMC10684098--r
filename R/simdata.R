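#' Simulation configuration for a multi-ancestry 25OHD cohort
#'
#' Collects every knob of the synthetic-cohort generator: sample sizes per
#' ancestry, number of variants, Balding-Nichols differentiation (Fst), block
#' LD structure, planted additive / dominance / genotype-by-skin-colour
#' effects, the ordinal skin-colour liability model, the seasonal phenotype
#' component, and the residual scale in nmol/L.
#'
#' Effect sizes are per-allele (additive, interaction) or per-heterozygote
#' (dominance) on the standardized latent trait, so a planted additive effect
#' `beta` at frequency `p` contributes `2p(1-p)beta^2` of trait variance.
#' The latent trait is mapped to nmol/L as `baseline + noise_sd * latent`,
#' with defaults (50, 18.8) giving a plausible serum 25OHD distribution.
#'
#' @param n_per_ancestry named integer vector, samples per ancestry label.
#' @param m_variants number of variants.
#' @param fst per-ancestry differentiation parameter(s) in [0, 1).
#' @param ld_block_size variants per LD block (must divide `m_variants`).
#' @param ld_rho latent haplotype correlation within a block, in [0, 1).
#' @param causal_additive,causal_dominance,causal_gxe data.frames with columns
#'   `index` (variant index) and `beta` (effect size, trait-s.d. units), or
#'   NULL for none.
#' @param skin_variants,skin_weights indices and liability weights of
#'   pigmentation variants driving skin colour.
#' @param skin_pc_frac fraction of skin-colour liability variance explained by
#'   the first genetic PC (ancestry axis).
#' @param skin_props population proportions of the six ordinal skin levels
#'   (very fair .. black); must sum to 1.
#' @param skin_effect_sd mean trait shift per skin level (s.d. units; negative
#'   values give darker-skin groups lower 25OHD).
#' @param month_variance_frac fraction of trait variance from the seasonal
#'   (assessment month) sinusoid.
#' @param familial_frac fraction of trait variance from a familial
#'   component shared within related pairs (untagged by the SNPs; loads on
#'   the thresholded-GRM variance component downstream).
#' @param noise_sd residual scale in nmol/L mapping the unit-variance latent
#'   trait to the measurement scale.
#' @param baseline_nmol location of the 25OHD distribution in nmol/L.
#' @param related_pairs number of sample pairs sharing one haplotype
#'   (expected genomic relationship 0.5).
#' @param n_chr number of chromosomes to spread the LD blocks over
#'   (default: one per block, up to 22).
#' @param missing_rate uniform genotype missingness rate (default 0).
#' @param seed integer seed; every downstream draw is deterministic given it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_ancestry = c(EUR = 1000L),
                       m_variants = 1000L,
                       fst = 0.1,
                       ld_block_size = 10L,
                       ld_rho = 0,
                       causal_additive = NULL,
                       causal_dominance = NULL,
                       causal_gxe = NULL,
                       skin_variants = integer(0),
                       skin_weights = numeric(0),
                       skin_pc_frac = 0,
                       skin_props = c(0.09, 0.66, 0.15, 0.06, 0.03, 0.01),
                       skin_effect_sd = 0,
                       month_variance_frac = 0.15,
                       familial_frac = 0,
                       noise_sd = 18.8,
                       baseline_nmol = 50,
                       related_pairs = 0L,
                       missing_rate = 0,
                       n_chr = NULL,
                       seed = 1L) {
  .assert(length(n_per_ancestry) >= 1 && all(n_per_ancestry > 0),
          "n_per_ancestry must be a named vector of positive counts")
  if (is.null(names(n_per_ancestry)))
    names(n_per_ancestry) <- paste0("POP", seq_along(n_per_ancestry))
  .assert(m_variants >= 1, "m_variants must be positive")
  .assert(all(fst >= 0) && all(fst < 1), "fst must lie in [0, 1); fst = 1 is degenerate")
  fst <- rep_len(fst, length(n_per_ancestry))
  names(fst) <- names(n_per_ancestry)
  .assert(m_variants %% ld_block_size == 0, "ld_block_size must divide m_variants")
  .assert(ld_rho >= 0 && ld_rho < 1, "ld_rho must lie in [0, 1)")
  norm_eff <- function(x, what) {
    if (is.null(x)) return(data.frame(index = integer(0), beta = numeric(0)))
    .assert(is.data.frame(x) && all(c("index", "beta") %in% names(x)),
            paste(what, "must be a data.frame with columns index, beta"))
    .assert(all(x$index >= 1 & x$index <= m_variants),
            paste(what, "indices must lie in 1..m_variants"))
    x[c("index", "beta")]
  }
  causal_additive  <- norm_eff(causal_additive, "causal_additive")
  causal_dominance <- norm_eff(causal_dominance, "causal_dominance")
  causal_gxe       <- norm_eff(causal_gxe, "causal_gxe")
  .assert(length(skin_variants) == length(skin_weights),
          "skin_variants and skin_weights must have equal length")
  .assert(all(skin_variants >= 1 & skin_variants <= m_variants),
          "skin_variants out of range")
  .assert(abs(sum(skin_props) - 1) < 1e-8 && length(skin_props) == 6,
          "skin_props must be 6 proportions summing to 1")
  fracs <- c(month_variance_frac, familial_frac, skin_pc_frac)
  .assert(all(fracs >= 0 & fracs <= 1),
          "variance fractions must lie in [0, 1]")
  .assert(month_variance_frac + familial_frac <= 1,
          "requested variance fractions sum to more than 1")
  .assert(sum(skin_weights^2) + skin_pc_frac <= 1,
          "skin liability variance fractions exceed 1")
  .assert(noise_sd > 0, "noise_sd must be positive")
  .assert(missing_rate >= 0 && missing_rate < 1, "missing_rate must lie in [0, 1)")
  structure(list(
    n_per_ancestry = n_per_ancestry, m_variants = as.integer(m_variants),
    fst = fst, ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    causal_additive = causal_additive, causal_dominance = causal_dominance,
    causal_gxe = causal_gxe, skin_variants = as.integer(skin_variants),
    skin_weights = skin_weights, skin_pc_frac = skin_pc_frac,
    skin_props = skin_props, skin_effect_sd = skin_effect_sd,
    month_variance_frac = month_variance_frac, familial_frac = familial_frac,
    noise_sd = noise_sd,
    baseline_nmol = baseline_nmol, related_pairs = as.integer(related_pairs),
    missing_rate = missing_rate,
    n_chr = if (is.null(n_chr)) NULL else as.integer(n_chr),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Skin-colour category labels (light to dark)
#' @export
SKIN_LEVELS <- c("very fair", "fair", "light olive", "dark olive", "brown", "black")

#' Draw ancestry-differentiated allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on [0.05, 0.95] unless supplied; each
#' ancestry's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`. `F = 0` returns the ancestral frequencies unchanged.
#'
#' @param config a [sim_config()].
#' @param ancestral optional vector of ancestral frequencies.
#' @return data.frame with column `ancestral` plus one frequency column per
#'   ancestry label; attribute `seed` records the generating seed.
#' @export
simulate_frequencies <- function(config, ancestral = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, "freqs"))
  m <- config$m_variants
  if (is.null(ancestral)) ancestral <- stats::runif(m, 0.05, 0.95)
  .assert(length(ancestral) == m, "ancestral frequency vector has wrong length")
  out <- data.frame(ancestral = ancestral)
  for (anc in names(config$n_per_ancestry)) {
    f <- config$fst[[anc]]
    if (f == 0) {
      out[[anc]] <- ancestral
    } else {
      a <- ancestral * (1 - f) / f
      b <- (1 - ancestral) * (1 - f) / f
      pf <- stats::rbeta(m, a, b)
      # keep variants segregating so downstream standardization is defined
      out[[anc]] <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
    }
  }
  attr(out, "seed") <- config$seed
  out
}

#' Simulate genotypes with block LD and optional related pairs
#'
#' Haplotypes are generated per ancestry from an equicorrelated latent
#' Gaussian within each LD block (correlation `ld_rho`), thresholded at the
#' ancestry-specific allele frequency; two haplotypes are summed per sample,
#' so Hardy-Weinberg holds within each ancestry. The last `2 * related_pairs`
#' samples of the first ancestry are arranged into pairs sharing one
#' haplotype (expected genomic relationship 0.5).
#'
#' @param freqs output of [simulate_frequencies()].
#' @param config a [sim_config()].
#' @return list of class `genotype_matrix`: `values` (samples x variants
#'   counts of A1), `variants` (chr, pos, id, A1, A2, data.frame), `samples`
#'   (id, ancestry).
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  n_tot <- sum(config$n_per_ancestry)
  m <- config$m_variants
  .assert(n_tot > 0 && m > 0, "need at least one sample and one variant")
  set.seed(.substream(config$seed, "genotypes"))
  B <- config$ld_block_size
  nblock <- m %/% B
  rho <- config$ld_rho
  G <- matrix(0L, n_tot, m)
  pairs <- data.frame(a = integer(0), b = integer(0))
  row0 <- 0L
  for (anc in names(config$n_per_ancestry)) {
    n <- config$n_per_ancestry[[anc]]
    p <- freqs[[anc]]
    thr <- stats::qnorm(p)
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), n, m)
      if (rho > 0) {
        shared <- matrix(stats::rnorm(n * nblock), n, nblock)
        shared_full <- shared[, rep(seq_len(nblock), each = B), drop = FALSE]
        z <- sqrt(rho) * shared_full + sqrt(1 - rho) * z
      }
      sweep(z, 2, thr, "<") + 0L
    }
    h1 <- hap(); h2 <- hap()
    G[row0 + seq_len(n), ] <- h1 + h2
    if (row0 == 0L && config$related_pairs > 0) {
      .assert(2 * config$related_pairs <= n,
              "related_pairs exceeds first ancestry's sample count")
      idx <- n - 2 * config$related_pairs + seq_len(2 * config$related_pairs)
      a <- idx[seq_len(config$related_pairs) * 2 - 1]
      b <- idx[seq_len(config$related_pairs) * 2]
      # pair member b re-uses haplotype 1 of member a
      G[row0 + b, ] <- h1[a, , drop = FALSE] + h2[b, , drop = FALSE]
      pairs <- data.frame(a = row0 + a, b = row0 + b)
    }
    row0 <- row0 + n
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(G)) < config$missing_rate
    G[miss] <- NA_integer_
  }
  nchr <- config$n_chr %||% min(22L, nblock)
  block_chr <- rep(seq_len(nchr), length.out = nblock)
  block_chr <- sort(block_chr)
  chr <- rep(block_chr, each = B)
  pos <- integer(m)
  for (cc in unique(chr)) {
    k <- sum(chr == cc)
    pos[chr == cc] <- seq_len(k) * 5000L
  }
  variants <- data.frame(
    chr = chr, pos = pos, id = sprintf("snp%06d", seq_len(m)),
    A1 = rep_len(c("A", "C"), m), A2 = rep_len(c("G", "T"), m),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("id%06d", seq_len(n_tot)),
    ancestry = rep(names(config$n_per_ancestry), config$n_per_ancestry),
    stringsAsFactors = FALSE)
  structure(list(values = G, variants = variants, samples = samples,
                 related_pairs = pairs),
            class = "genotype_matrix")
}

#' Simulate ordinal skin colour from a latent liability
#'
#' Liability = weighted standardized pigmentation genotypes + a PC component
#' scaled to explain `skin_pc_frac` of the liability variance + Gaussian
#' noise topping the variance up to 1. Categories are obtained by
#' thresholding at the standard-normal quantiles of the cumulative
#' `skin_props`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param pcs matrix of per-sample PC scores (first column used), or NULL.
#' @param config a [sim_config()].
#' @return list: `skin` (ordered factor over [SKIN_LEVELS]), `liability`,
#'   `thresholds`.
#' @export
simulate_skin_colour <- function(genotypes, pcs = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, "skin"))
  n <- nrow(genotypes$values)
  g_comp <- rep(0, n)
  vg <- 0
  if (length(config$skin_variants)) {
    Z <- .std_geno(genotypes$values[, config$skin_variants, drop = FALSE])
    g_comp <- drop(Z %*% config$skin_weights)
    vg <- sum(config$skin_weights^2)
  }
  pc_comp <- rep(0, n)
  if (config$skin_pc_frac > 0) {
    .assert(!is.null(pcs), "skin_pc_frac > 0 requires PC scores")
    s <- as.numeric(scale(pcs[, 1]))
    pc_comp <- sqrt(config$skin_pc_frac) * s
  }
  ve <- max(0, 1 - vg - config$skin_pc_frac)
  liab <- g_comp + pc_comp + stats::rnorm(n, 0, sqrt(ve))
  thresholds <- stats::qnorm(cumsum(config$skin_props))[1:5]
  .assert(all(diff(thresholds) > 0), "skin thresholds must be strictly increasing")
  lev <- findInterval(liab, thresholds) + 1L
  skin <- factor(SKIN_LEVELS[lev], levels = SKIN_LEVELS, ordered = TRUE)
  list(skin = skin, liability = liab, thresholds = thresholds)
}

#' Simulate the 25OHD phenotype and assemble the cohort table
#'
#' The unit-variance latent trait sums planted additive, dominance and
#' genotype-by-skin interaction effects (all centred), a per-skin-level mean
#' shift, a seasonal sinusoid over assessment month scaled to
#' `month_variance_frac` of the variance, and Gaussian noise with variance
#' `1 - month_variance_frac`. It is then mapped to nmol/L as
#' `baseline_nmol + noise_sd * latent`; values outside the 10-375 nmol/L
#' assay range are flagged `excluded`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param skin output of [simulate_skin_colour()] (or an ordered factor).
#' @param config a [sim_config()].
#' @return list: `cohort` (data.frame: IID, vitd, skin, sex, age, month,
#'   supplement, centre, ancestry, excluded), `truth` (per-variant true
#'   effects + realized variance fractions + seed).
#' @export
simulate_phenotype <- function(genotypes, skin, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(skin) && !is.null(skin$skin)) skin <- skin$skin
  set.seed(.substream(config$seed, "phenotype"))
  G <- genotypes$values
  n <- nrow(G); m <- ncol(G)
  p <- colMeans(G, na.rm = TRUE) / 2

  beta_a <- beta_d <- beta_gxe <- numeric(m)
  beta_a[config$causal_additive$index] <- config$causal_additive$beta
  beta_d[config$causal_dominance$index] <- config$causal_dominance$beta
  beta_gxe[config$causal_gxe$index] <- config$causal_gxe$beta

  centred <- function(j) {
    x <- G[, j]; x[is.na(x)] <- 2 * p[j]; x - 2 * p[j]
  }
  g_add <- rep(0, n)
  for (j in config$causal_additive$index)
    g_add <- g_add + beta_a[j] * centred(j)
  g_dom <- rep(0, n)
  for (j in config$causal_dominance$index) {
    h <- as.integer(G[, j] == 1L); h[is.na(G[, j])] <- 0L
    g_dom <- g_dom + beta_d[j] * (h - mean(h))
  }
  e_skin <- as.integer(skin) - 1L
  e_c <- e_skin - mean(e_skin)
  g_gxe <- rep(0, n)
  for (j in config$causal_gxe$index)
    g_gxe <- g_gxe + beta_gxe[j] * centred(j) * e_c
  skin_shift <- config$skin_effect_sd * e_c

  month <- sample.int(12L, n, replace = TRUE)
  amp <- sqrt(2 * config$month_variance_frac)
  month_term <- amp * cospi(2 * (month - 7) / 12)

  fam <- rep(0, n)
  if (config$familial_frac > 0) {
    fam <- stats::rnorm(n, 0, sqrt(config$familial_frac))
    pr <- genotypes$related_pairs
    if (!is.null(pr) && nrow(pr)) fam[pr$b] <- fam[pr$a]
  }

  # residual variance completes the latent trait to ~unit variance
  sys_var <- stats::var(g_add) + stats::var(g_dom) + stats::var(g_gxe) +
    stats::var(skin_shift) + config$month_variance_frac + config$familial_frac
  eps <- stats::rnorm(n, 0, sqrt(max(0.05, 1 - sys_var)))

  latent <- g_add + g_dom + g_gxe + skin_shift + month_term + fam + eps
  vitd <- config$baseline_nmol + config$noise_sd * latent

  cohort <- data.frame(
    IID = genotypes$samples$id,
    vitd = vitd,
    skin = skin,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(stats::runif(n, 40, 70)),
    month = month,
    supplement = sample(c("none", "other", "vitaminD", "missing"), n,
                        replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)),
    centre = sample(paste0("centre", 1:10), n, replace = TRUE),
    ancestry = genotypes$samples$ancestry,
    stringsAsFactors = FALSE)
  cohort$excluded <- cohort$vitd < 10 | cohort$vitd > 375

  truth <- list(
    effects = data.frame(id = genotypes$variants$id, freq = p,
                         beta_a = beta_a, beta_d = beta_d, beta_gxe = beta_gxe),
    genetic_value = g_add,
    h2_snp = stats::var(g_add) / stats::var(latent),
    familial_var = stats::var(fam),
    skin_effect_sd = config$skin_effect_sd,
    month_amplitude = amp,
    seed = config$seed)
  list(cohort = cohort, truth = truth)
}

#' Run the whole generator: frequencies, genotypes, skin colour, phenotype
#'
#' @param config a [sim_config()].
#' @param pcs optional PC scores passed to [simulate_skin_colour()].
#' @return list: `freqs`, `genotypes`, `skin`, `cohort`, `truth`.
#' @export
simulate_cohort <- function(config, pcs = NULL) {
  freqs <- simulate_frequencies(config)
  geno <- simulate_genotypes(freqs, config)
  skin <- simulate_skin_colour(geno, pcs, config)
  ph <- simulate_phenotype(geno, skin, config)
  list(freqs = freqs, genotypes = geno, skin = skin,
       cohort = ph$cohort, truth = ph$truth)
}

#' Per-ancestry summary and vitamin-D deficiency prevalence
#'
#' @param cohort a cohort data.frame (columns `vitd`, `ancestry`).
#' @param deficiency_threshold nmol/L cutoff; prevalence counts values
#'   strictly below it (default 25 nmol/L).
#' @param use_excluded include assay-range-excluded samples (default FALSE).
#' @return data.frame: ancestry, n, mean, median, prevalence.
#' @export
summarize_cohort <- function(cohort, deficiency_threshold = 25,
                             use_excluded = FALSE) {
  keep <- if (!use_excluded && "excluded" %in% names(cohort))
    !cohort$excluded else rep(TRUE, nrow(cohort))
  d <- cohort[keep, , drop = FALSE]
  groups <- split(d$vitd, d$ancestry)
  out <- do.call(rbind, lapply(names(groups), function(a) {
    v <- groups[[a]]
    data.frame(ancestry = a, n = length(v),
               mean = mean(v), median = stats::median(v),
               prevalence = if (length(v)) mean(v < deficiency_threshold) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n == 0)) warning("empty ancestry group: prevalence undefined")
  out
}
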