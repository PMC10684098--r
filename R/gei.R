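#' Stratified phenotype pre-processing for interaction analysis
#'
#' Within each sex-by-supplement stratum (up to 8 groups): (1) regress
#' 25OHD on the supplied covariates, (2) drop outliers with
#' |standardized residual| > `outlier_sd`, (3) re-standardize the
#' residuals to mean 0, variance 1. Reports each stratum's
#' pre-standardization residual standard deviation in nmol/L and their
#' mean — the scale used by [sd_to_nmol()].
#'
#' @param cohort cohort data.frame (needs `vitd`, `sex`, `supplement`).
#' @param covariates character vector of cohort column names to adjust for
#'   (factors handled via model.matrix), or a numeric matrix.
#' @param outlier_sd outlier cutoff in residual s.d. units (default 5).
#' @return list: `adjusted` (data.frame IID, y_adj, stratum; outliers and
#'   dropped strata absent), `strata` (per-stratum n, residual s.d. nmol/L,
#'   outliers removed), `mean_resid_sd` (nmol/L).
#' @export
gei_preprocess <- function(cohort, covariates = c("age", "month", "centre"),
                           outlier_sd = 5) {
  keep0 <- if ("excluded" %in% names(cohort)) !cohort$excluded else TRUE
  d <- cohort[keep0, , drop = FALSE]
  stratum <- interaction(d$sex, d$supplement, drop = TRUE)
  out_rows <- list(); strat_rows <- list()
  for (s in levels(stratum)) {
    di <- d[stratum == s, , drop = FALSE]
    if (is.character(covariates)) {
      f <- stats::as.formula(paste("vitd ~", paste(covariates, collapse = " + ")))
      mm <- tryCatch(stats::model.matrix(f, di), error = function(e) NULL)
    } else {
      mm <- cbind(1, covariates[stratum == s, , drop = FALSE])
    }
    if (is.null(mm) || nrow(di) <= ncol(mm) + 1) {
      warning("stratum ", s, " too small for the covariate model; dropped")
      next
    }
    qrm <- qr(mm)
    res <- stats::residuals(stats::lm.fit(mm[, qrm$pivot[seq_len(qrm$rank)], drop = FALSE],
                                          di$vitd))
    sd0 <- stats::sd(res)
    z <- res / sd0
    ok <- abs(z) <= outlier_sd
    y_adj <- as.numeric(scale(res[ok]))
    out_rows[[s]] <- data.frame(IID = di$IID[ok], y_adj = y_adj,
                                stratum = s, stringsAsFactors = FALSE)
    strat_rows[[s]] <- data.frame(stratum = s, n = sum(ok),
                                  resid_sd_nmol = sd0,
                                  outliers_removed = sum(!ok),
                                  stringsAsFactors = FALSE)
  }
  .assert(length(out_rows) > 0, "no stratum could be processed")
  strata <- do.call(rbind, strat_rows)
  list(adjusted = do.call(rbind, out_rows), strata = strata,
       mean_resid_sd = mean(strata$resid_sd_nmol))
}

#' Variance-heterogeneity (vQTL) screen across genotype groups
#'
#' Median-based Levene (Brown-Forsythe) test: absolute deviations from
#' each genotype group's median compared across groups by one-way ANOVA.
#' Variants with fewer than two groups of at least `min_group` samples are
#' skipped.
#'
#' @param y_adjusted adjusted phenotype.
#' @param genotypes a `genotype_matrix`.
#' @param min_group minimum samples per genotype group (default 2).
#' @return data.frame: id, freq, statistic (F), df1, df2, p.
#' @export
vqtl_screen <- function(y_adjusted, genotypes, min_group = 2) {
  G <- genotypes$values
  m <- ncol(G)
  stat <- pval <- df1 <- df2 <- rep(NA_real_, m)
  p_a1 <- colMeans(G, na.rm = TRUE) / 2
  for (j in seq_len(m)) {
    x <- G[, j]
    ok <- !is.na(x) & !is.na(y_adjusted)
    g <- factor(x[ok])
    tab <- table(g)
    use_lv <- names(tab)[tab >= min_group]
    if (length(use_lv) < 2) next
    sel <- g %in% use_lv
    g2 <- droplevels(g[sel]); y2 <- y_adjusted[ok][sel]
    med <- tapply(y2, g2, stats::median)
    z <- abs(y2 - med[g2])
    ft <- stats::oneway.test(z ~ g2, var.equal = TRUE)
    stat[j] <- unname(ft$statistic)
    df1[j] <- unname(ft$parameter[1]); df2[j] <- unname(ft$parameter[2])
    pval[j] <- ft$p.value
  }
  data.frame(id = genotypes$variants$id, freq = p_a1, statistic = stat,
             df1 = df1, df2 = df2, p = pval, stringsAsFactors = FALSE)
}

#' Genotype-by-skin-colour interaction test at one variant
#'
#' Fits `y ~ g + e + g:e` with the genotype mean-centred and skin colour
#' coded as indicators against the very-fair reference; reports main and
#' interaction coefficients with Wald p-values, and the family-wise
#' Bonferroni verdict `alpha_family / n_tests`.
#'
#' @param y_adjusted standardized adjusted phenotype.
#' @param genotype allele-count vector for the tested variant.
#' @param skin ordered factor of skin levels.
#' @param alpha_family family-wise alpha (default 0.05).
#' @param n_tests number of vQTLs in the family (default 25).
#' @return list of class `gei_fit`: `coefficients` (term, estimate, se, p,
#'   kind), `threshold`, `significant`, `residual_sd_nmol` (NA unless set
#'   by the caller from [gei_preprocess()]).
#' @export
gei_test <- function(y_adjusted, genotype, skin, alpha_family = 0.05,
                     n_tests = 25) {
  ok <- !is.na(genotype) & !is.na(y_adjusted) & !is.na(skin)
  g <- genotype[ok] - mean(genotype[ok])
  all_lv <- if (is.factor(skin)) levels(skin) else sort(unique(as.character(skin)))
  e <- droplevels(factor(as.character(skin[ok]), levels = all_lv))
  y <- y_adjusted[ok]
  missing_levels <- setdiff(all_lv, levels(e))
  # a single skin level leaves no contrast: the model reduces to y ~ g
  fit <- if (nlevels(e) < 2) stats::lm(y ~ g) else stats::lm(y ~ g * e)
  cf <- summary(fit)$coefficients
  kind <- rep("main_skin", nrow(cf))
  kind[rownames(cf) == "(Intercept)"] <- "intercept"
  kind[rownames(cf) == "g"] <- "main_genotype"
  kind[grepl("^g:", rownames(cf))] <- "interaction"
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      p = cf[, 4], kind = kind, row.names = NULL,
                      stringsAsFactors = FALSE)
  thr <- alpha_family / n_tests
  ip <- coefs$p[coefs$kind == "interaction"]
  structure(list(coefficients = coefs, threshold = thr,
                 significant = any(ip < thr),
                 missing_levels = missing_levels,
                 n = length(y), residual_sd_nmol = NA_real_),
            class = "gei_fit")
}

#' Predicted between-skin-group trait difference by genotype class
#'
#' From a fitted main skin-group difference and a per-allele interaction
#' coefficient, the expected difference for carriers of 0, 1, 2 copies of
#' the interacting allele: `main + copies * interaction`.
#'
#' @param main_effect skin-group difference in the reference genotype
#'   class (s.d. units).
#' @param interaction_per_allele change in that difference per allele.
#' @return named vector for 0, 1, 2 allele copies.
#' @export
gei_group_difference <- function(main_effect, interaction_per_allele) {
  stats::setNames(main_effect + (0:2) * interaction_per_allele,
                  c("copies0", "copies1", "copies2"))
}

#' Genome-wide interaction scan between genotype and a skin-colour pair
#'
#' Restricted to variants with MAF > `maf_min` (default 0.05) and to
#' samples in exactly the two supplied skin levels. Per variant, fits
#' `y ~ g + e + g:e` (g mean-centred, e an indicator of the second level)
#' and reports the interaction term with genome-wide-significant and
#' suggestive flags.
#'
#' @param y_adjusted standardized adjusted phenotype.
#' @param genotypes a `genotype_matrix`.
#' @param skin skin factor.
#' @param skin_pair character vector of the two contrasted levels.
#' @param maf_min MAF floor (default 0.05).
#' @param gws,suggestive significance thresholds.
#' @return data.frame per kept variant: id, freq, n, b_g, b_e, b_gxe,
#'   se_gxe, p_gxe, gws, suggestive, contrast.
#' @export
gei_gwas <- function(y_adjusted, genotypes, skin, skin_pair,
                     maf_min = 0.05, gws = 5e-8, suggestive = 1e-6) {
  .assert(length(skin_pair) == 2, "skin_pair must name exactly two levels")
  sel <- skin %in% skin_pair & !is.na(y_adjusted)
  .assert(sum(sel) > 10, "too few samples in the two skin levels")
  e <- as.numeric(skin[sel] == skin_pair[2])
  .assert(length(unique(e)) == 2, "fewer than 2 skin levels present in the data")
  y <- y_adjusted[sel]
  G <- genotypes$values[sel, , drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(maf > maf_min)
  rows <- lapply(keep, function(j) {
    x <- G[, j]
    ok <- !is.na(x)
    g <- x[ok] - mean(x[ok])
    X <- cbind(1, g, e[ok], g * e[ok])
    if (qr(X)$rank < 4) return(NULL)
    XtX <- crossprod(X)
    b <- solve(XtX, crossprod(X, y[ok]))
    res <- y[ok] - X %*% b
    s2 <- sum(res^2) / (sum(ok) - 4)
    vb <- s2 * solve(XtX)
    se4 <- sqrt(vb[4, 4])
    p4 <- 2 * stats::pnorm(-abs(b[4] / se4))
    data.frame(id = genotypes$variants$id[j], freq = p[j], n = sum(ok),
               b_g = b[2], b_e = b[3], b_gxe = b[4], se_gxe = se4,
               p_gxe = p4, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$gws <- out$p_gxe < gws
  out$suggestive <- out$p_gxe < suggestive
  out$contrast <- paste(skin_pair, collapse = " vs ")
  out
}

#' Convert a trait difference from s.d. units to nmol/L
#'
#' Multiplies by the mean residual standard deviation in nmol/L and rounds
#' to one decimal for reporting.
#'
#' @param delta_sd difference in s.d. units.
#' @param residual_sd_nmol residual scale in nmol/L (e.g. the
#'   `mean_resid_sd` from [gei_preprocess()]).
#' @return difference in nmol/L, rounded to 1 decimal.
#' @export
sd_to_nmol <- function(delta_sd, residual_sd_nmol) {
  .assert(all(residual_sd_nmol > 0), "residual_sd_nmol must be positive")
  round(delta_sd * residual_sd_nmol, 1)
}
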