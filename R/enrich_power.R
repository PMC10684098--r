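#' Permutation enrichment of a SNP set for external-trait associations
#'
#' Observed count: test-set SNPs associated (minimum p across traits below
#' `threshold`) with at least one queried trait. Null: `n_perm` random sets
#' of the same size drawn without replacement from the pool. One-tailed
#' empirical p = (number of null sets with count >= observed) / n_perm —
#' no pseudo-count; the 1/n_perm reporting floor is returned alongside.
#'
#' @param test_set character vector of SNP ids.
#' @param pool character vector of candidate SNP ids (the sampling frame).
#' @param assoc_table data.frame: column `SNP` plus one p-value column per
#'   trait.
#' @param n_perm number of null sets (default 10000).
#' @param threshold association threshold (default 5e-8).
#' @param seed integer seed.
#' @return list of class `enrich_result`: `observed`, `null_counts`,
#'   `p_empirical`, `p_floor`, `n_perm`.
#' @export
enrichment_test <- function(test_set, pool, assoc_table,
                            n_perm = 10000, threshold = 5e-8, seed = 1) {
  .assert(length(test_set) <= length(pool), "test set larger than the pool")
  .assert("SNP" %in% names(assoc_table), "assoc_table needs a SNP column")
  pcols <- setdiff(names(assoc_table), "SNP")
  .assert(length(pcols) >= 1, "assoc_table needs at least one p-value column")
  minp <- do.call(pmin, c(assoc_table[pcols], na.rm = TRUE))
  hit <- stats::setNames(minp < threshold, assoc_table$SNP)
  count_hits <- function(ids) sum(hit[ids], na.rm = TRUE)
  .assert(all(test_set %in% assoc_table$SNP),
          "test_set contains SNPs absent from assoc_table")
  observed <- count_hits(test_set)
  set.seed(.substream(seed, "enrich"))
  k <- length(test_set)
  null_counts <- vapply(seq_len(n_perm), function(i)
    count_hits(sample(pool, k)), numeric(1))
  structure(list(observed = observed, null_counts = null_counts,
                 p_empirical = sum(null_counts >= observed) / n_perm,
                 p_floor = 1 / n_perm, n_perm = n_perm),
            class = "enrich_result")
}

#' Variance explained by a QTL under Hardy-Weinberg equilibrium
#'
#' `h2_qtl = 2 p (1 - p) beta^2` for allele frequency `p` and per-allele
#' effect `beta` on a unit-variance trait.
#'
#' @param p allele frequency in (0, 1).
#' @param beta per-allele effect (trait-s.d. units).
#' @return QTL heritability.
#' @export
qtl_h2 <- function(p, beta) {
  .assert(all(p > 0 & p < 1), "p must lie in (0, 1)")
  2 * p * (1 - p) * beta^2
}

#' Non-centrality parameter of the association chi-square test
#'
#' `lambda = N * h2_qtl / (1 - h2_qtl)`.
#'
#' @param N sample size.
#' @param h2_qtl QTL heritability in [0, 1).
#' @return non-centrality parameter.
#' @export
ncp <- function(N, h2_qtl) {
  .assert(all(h2_qtl >= 0 & h2_qtl < 1), "h2_qtl must lie in [0, 1)")
  N * h2_qtl / (1 - h2_qtl)
}

#' Analytic power of the 1-df association test
#'
#' `P(chi2_1(lambda) > q_alpha)` with `q_alpha` the central chi-square
#' upper-alpha quantile. At `lambda = 0` this equals alpha exactly.
#'
#' @param lambda non-centrality parameter(s).
#' @param alpha significance level (default genome-wide 5e-8).
#' @return detection probability.
#' @export
chisq_power <- function(lambda, alpha = 5e-8) {
  .assert(all(lambda >= 0), "lambda must be non-negative")
  .assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  q <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(q, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Power across variants and sample sizes
#'
#' Composes [qtl_h2()], [ncp()] and [chisq_power()] for every
#' (variant, N) combination.
#'
#' @param variants data.frame with columns `p` and `beta` (optionally `id`).
#' @param N_grid vector of sample sizes.
#' @param alpha significance level.
#' @return long-format data.frame: id, p, beta, N, h2_qtl, lambda, power.
#' @export
power_curve <- function(variants, N_grid, alpha = 5e-8) {
  .assert(length(N_grid) >= 1, "empty sample-size grid")
  .assert(all(c("p", "beta") %in% names(variants)), "variants needs p and beta")
  id <- variants$id %||% sprintf("v%d", seq_len(nrow(variants)))
  out <- expand.grid(row = seq_len(nrow(variants)), N = N_grid)
  h2 <- qtl_h2(variants$p[out$row], variants$beta[out$row])
  lam <- ncp(out$N, h2)
  data.frame(id = id[out$row], p = variants$p[out$row],
             beta = variants$beta[out$row], N = out$N,
             h2_qtl = h2, lambda = lam,
             power = chisq_power(lam, alpha),
             stringsAsFactors = FALSE)
}
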