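#' Build an LD reference for conditional-and-joint analysis
#'
#' Stores mean-imputed, centred reference genotypes plus the windowing rule:
#' variant pairs farther apart than `window_bp` (or on different
#' chromosomes) are treated as uncorrelated.
#'
#' @param genotypes a `genotype_matrix` (reference or GWAS sample).
#' @param window_bp correlation window radius in bp (default 10 Mb).
#' @return list of class `ld_ref`: `Xc` (centred genotypes), `freq`, `D`
#'   (centred sums of squares), `variants`, `n`, `window_bp`.
#' @export
make_ld_ref <- function(genotypes, window_bp = 10e6) {
  .assert(window_bp > 0, "window_bp must be positive")
  G <- genotypes$values
  p <- colMeans(G, na.rm = TRUE) / 2
  Xc <- sweep(G, 2, 2 * p, "-")
  Xc[is.na(Xc)] <- 0
  structure(list(Xc = Xc, freq = p, D = colSums(Xc^2),
                 variants = genotypes$variants, n = nrow(G),
                 window_bp = window_bp),
            class = "ld_ref")
}

# Cross-product block between variant index sets, with pairs beyond the
# bp window (or across chromosomes) forced to exactly zero.
# scale = "genotype": raw centred cross-products (exact when the reference
# IS the GWAS sample). scale = "freq": correlations from the reference
# rescaled to sqrt(D_i D_j) with D = 2p(1-p)N from the summary rows.
.cojo_xtx <- function(ld, i_idx, j_idx, Dsum, scale) {
  W <- crossprod(ld$Xc[, i_idx, drop = FALSE], ld$Xc[, j_idx, drop = FALSE])
  if (scale == "freq") {
    R <- W / sqrt(outer(ld$D[i_idx], ld$D[j_idx]))
    W <- R * sqrt(outer(Dsum[i_idx], Dsum[j_idx]))
  }
  vi <- ld$variants[i_idx, ]; vj <- ld$variants[j_idx, ]
  far <- outer(vi$chr, vj$chr, "!=") |
    abs(outer(vi$pos, vj$pos, "-")) > ld$window_bp
  W[far] <- 0
  same <- outer(i_idx, j_idx, "==")
  if (any(same)) W[same] <- (if (scale == "freq") Dsum else ld$D)[i_idx[row(same)[same]]]
  W
}

# Map summary rows onto the LD reference; reconstruct the scalars the
# summary-based regression algebra needs.
.cojo_setup <- function(sumstats, ld_ref, scale, freq_mismatch_max = 0.2) {
  idx <- match(sumstats$SNP, ld_ref$variants$id)
  miss <- is.na(idx)
  if (any(miss))
    warning("variants missing from the LD reference, skipped: ",
            paste(utils::head(sumstats$SNP[miss], 5), collapse = ", "),
            if (sum(miss) > 5) " ..." else "")
  ss <- sumstats[!miss, , drop = FALSE]
  idx <- idx[!miss]
  # allele harmonization against the reference
  a1 <- ld_ref$variants$A1[idx]; a2 <- ld_ref$variants$A2[idx]
  swap <- ss$A1 == a2 & ss$A2 == a1
  bad <- !(swap | (ss$A1 == a1 & ss$A2 == a2))
  ss$b[swap] <- -ss$b[swap]
  ss$freq[swap] <- 1 - ss$freq[swap]
  fdev <- abs(ss$freq - ld_ref$freq[idx])
  bad <- bad | fdev > freq_mismatch_max
  if (any(bad)) {
    warning(sum(bad), " variant(s) dropped (allele or frequency mismatch)")
    ss <- ss[!bad, , drop = FALSE]; idx <- idx[!bad]
  }
  .assert(nrow(ss) > 0, "no usable variants after harmonization")
  Dsum <- if (scale == "genotype") ld_ref$D[idx] else 2 * ss$freq * (1 - ss$freq) * ss$N
  names(Dsum) <- NULL
  Dfull <- rep(NA_real_, ncol(ld_ref$Xc))
  Dfull[idx] <- Dsum
  xty <- Dsum * ss$b
  yty_j <- Dsum * (ss$se^2 * (ss$N - 2) + ss$b^2)
  list(ss = ss, idx = idx, D = Dsum, Dfull = Dfull, xty = xty,
       yty = stats::median(yty_j), neff = stats::median(ss$N))
}

# Joint fit of the candidate rows `sel` (positions into setup$ss).
.cojo_joint <- function(setup, ld, sel, scale) {
  k <- length(sel)
  ii <- setup$idx[sel]
  W <- .cojo_xtx(ld, ii, ii, setup$Dfull, scale)
  Wi <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Wi)) return(NULL)
  bJ <- drop(Wi %*% setup$xty[sel])
  rss <- setup$yty - sum(bJ * setup$xty[sel])
  df <- setup$neff - k - 1
  s2 <- max(rss, 0) / df
  seJ <- sqrt(s2 * diag(Wi))
  pJ <- 2 * stats::pnorm(-abs(bJ / seJ))
  list(bJ = bJ, seJ = seJ, pJ = pJ, Wi = Wi, W = W, s2 = s2, rss = rss)
}

# Conditional effect of every row in `cand` given the set `sel`.
.cojo_conditional <- function(setup, ld, sel, cand, scale, collinear_r2) {
  ii <- setup$idx[sel]
  jj <- setup$idx[cand]
  W_SS <- .cojo_xtx(ld, ii, ii, setup$Dfull, scale)
  Wi <- solve(W_SS)
  W_tS <- .cojo_xtx(ld, jj, ii, setup$Dfull, scale)   # cand x sel
  A <- W_tS %*% Wi                                     # cand x sel
  D_t <- setup$D[cand]
  r2 <- rowSums(A * W_tS) / D_t
  num <- setup$xty[cand] - drop(A %*% setup$xty[sel])
  den <- D_t - rowSums(A * W_tS)
  bJ_S <- drop(Wi %*% setup$xty[sel])
  rss_S <- setup$yty - sum(bJ_S * setup$xty[sel])
  b_c <- num / den
  rss_full <- rss_S - b_c * num
  df <- setup$neff - length(sel) - 2
  s2 <- pmax(rss_full, 0) / df
  se_c <- sqrt(s2 / den)
  collinear <- r2 >= collinear_r2 | den <= 0
  b_c[collinear] <- 0
  se_c[collinear] <- NA_real_
  p_c <- 2 * stats::pnorm(-abs(b_c / se_c))
  p_c[collinear] <- NA_real_
  list(b = b_c, se = se_c, p = p_c, r2 = r2, collinear = collinear)
}

#' Conditional-and-joint stepwise selection from summary statistics
#'
#' Seeds with the most significant variant below `p_threshold`, then
#' iterates: compute the p-value of every remaining variant conditional on
#' the selected set (LD from the reference, zero beyond `window_bp`), add
#' the best if below threshold and not collinear (multiple-regression
#' `R^2 < collinear_r2` against the set), drop any selected variant whose
#' joint p rises above threshold. Finishes with joint estimates of the
#' selected set. Ties in minimum conditional p break by smaller genomic
#' position, then lexicographic id.
#'
#' @param sumstats data.frame in `.ma` layout (SNP A1 A2 freq b se p N).
#' @param ld_ref an `ld_ref`.
#' @param p_threshold selection threshold (default 5e-8).
#' @param collinear_r2 collinearity cutoff (default 0.9).
#' @param scale "freq" (reconstruct scales from freq and N; use with an
#'   external reference) or "genotype" (raw cross-products; exact when the
#'   reference is the GWAS sample itself).
#' @return list of class `cojo_result`: `selected` (data.frame with
#'   marginal b/se/p, joint bJ/seJ/pJ, explained variance `varexp`
#'   = 2p(1-p)bJ^2), `log` (iteration log), `n_candidates`.
#' @export
cojo_select <- function(sumstats, ld_ref, p_threshold = 5e-8,
                        collinear_r2 = 0.9, scale = c("freq", "genotype")) {
  scale <- match.arg(scale)
  setup <- .cojo_setup(sumstats, ld_ref, scale)
  ss <- setup$ss
  ord_key <- order(ss$p, ld_ref$variants$pos[setup$idx], ss$SNP)
  log_df <- data.frame(iter = integer(0), action = character(0),
                       SNP = character(0), p = numeric(0))
  empty <- function() structure(list(
    selected = data.frame(SNP = character(0)), log = log_df,
    n_candidates = nrow(ss)), class = "cojo_result")
  if (min(ss$p) >= p_threshold) return(empty())
  sel <- ord_key[1]
  log_df <- rbind(log_df, data.frame(iter = 1L, action = "add",
                                     SNP = ss$SNP[sel], p = ss$p[sel]))
  iter <- 1L
  repeat {
    iter <- iter + 1L
    cand <- setdiff(seq_len(nrow(ss)), sel)
    added <- FALSE
    if (length(cand)) {
      cc <- .cojo_conditional(setup, ld_ref, sel, cand, scale, collinear_r2)
      ok <- !cc$collinear & is.finite(cc$p) & cc$p < p_threshold
      if (any(ok)) {
        pos <- ld_ref$variants$pos[setup$idx[cand]]
        o <- order(cc$p, pos, ss$SNP[cand])
        best <- o[which(ok[o])[1]]
        sel <- c(sel, cand[best])
        log_df <- rbind(log_df, data.frame(iter = iter, action = "add",
                                           SNP = ss$SNP[cand[best]],
                                           p = cc$p[best]))
        added <- TRUE
      }
    }
    # backward step: drop selected variants no longer jointly significant
    if (length(sel) > 1) {
      jt <- .cojo_joint(setup, ld_ref, sel, scale)
      if (!is.null(jt) && any(jt$pJ >= p_threshold)) {
        worst <- which.max(jt$pJ)
        log_df <- rbind(log_df, data.frame(iter = iter, action = "drop",
                                           SNP = ss$SNP[sel[worst]],
                                           p = jt$pJ[worst]))
        sel <- sel[-worst]
        next
      }
    }
    if (!added) break
  }
  jt <- .cojo_joint(setup, ld_ref, sel, scale)
  .assert(!is.null(jt), "joint fit of the selected set is singular")
  o <- order(ld_ref$variants$chr[setup$idx[sel]],
             ld_ref$variants$pos[setup$idx[sel]])
  sel <- sel[o]
  jt <- .cojo_joint(setup, ld_ref, sel, scale)
  pfreq <- ss$freq[sel]
  selected <- data.frame(
    SNP = ss$SNP[sel],
    chr = ld_ref$variants$chr[setup$idx[sel]],
    pos = ld_ref$variants$pos[setup$idx[sel]],
    A1 = ld_ref$variants$A1[setup$idx[sel]],
    A2 = ld_ref$variants$A2[setup$idx[sel]],
    freq = pfreq, b = ss$b[sel], se = ss$se[sel], p = ss$p[sel],
    N = ss$N[sel], bJ = jt$bJ, seJ = jt$seJ, pJ = jt$pJ,
    varexp = 2 * pfreq * (1 - pfreq) * jt$bJ^2,
    stringsAsFactors = FALSE)
  structure(list(selected = selected, log = log_df, n_candidates = nrow(ss)),
            class = "cojo_result")
}

#' Conditional association scan given a fixed SNP set
#'
#' Per-variant effect, standard error and p-value conditional on
#' `condition_set`, from summary statistics and reference LD. Variants
#' collinear with the set (`R^2 >= collinear_r2`) are flagged with NA
#' estimates.
#'
#' @inheritParams cojo_select
#' @param condition_set character vector of SNP ids to condition on.
#' @return data.frame of records (`test = "conditional"`) with columns
#'   SNP, b, se, p, r2_with_set, collinear.
#' @export
conditional_scan <- function(sumstats, ld_ref, condition_set,
                             collinear_r2 = 0.9, scale = c("freq", "genotype")) {
  scale <- match.arg(scale)
  .assert(length(condition_set) > 0, "condition_set is empty")
  setup <- .cojo_setup(sumstats, ld_ref, scale)
  ss <- setup$ss
  sel <- match(condition_set, ss$SNP)
  .assert(!anyNA(sel), "condition_set contains variants absent from sumstats/LD reference")
  cand <- seq_len(nrow(ss))
  cc <- .cojo_conditional(setup, ld_ref, sel, cand, scale, collinear_r2)
  data.frame(SNP = ss$SNP[cand], freq = ss$freq[cand], n = ss$N[cand],
             b = cc$b, se = cc$se, p = cc$p,
             r2_with_set = cc$r2, collinear = cc$collinear,
             test = "conditional", stringsAsFactors = FALSE)
}

#' Residual-based conditional test for dominance loci
#'
#' Two-step procedure: (1) residualize the adjusted phenotype on both the
#' additive (0,1,2) and dominance (0,1,0) codings of `condition_snp`;
#' (2) run the dominance scan of the residuals on each test SNP. A test
#' SNP in near-perfect LD with the condition SNP attenuates to null.
#'
#' @param y_adjusted adjusted, RINT phenotype.
#' @param genotypes a `genotype_matrix`.
#' @param condition_snp id of the SNP conditioned on.
#' @param test_snps ids of the SNPs tested (default: all others).
#' @return dominance association records on the conditioned residuals.
#' @export
dominance_conditional <- function(y_adjusted, genotypes, condition_snp,
                                  test_snps = NULL) {
  j <- match(condition_snp, genotypes$variants$id)
  .assert(!is.na(j), "condition_snp not found")
  x <- genotypes$values[, j]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  .assert(stats::var(x) > 0, "condition SNP is monomorphic")
  xd <- as.numeric(x == 1)
  X <- cbind(1, x, xd)
  resid <- drop(y_adjusted - X %*% solve(crossprod(X), crossprod(X, y_adjusted)))
  if (is.null(test_snps)) test_snps <- genotypes$variants$id
  keep <- match(test_snps, genotypes$variants$id)
  .assert(!anyNA(keep), "unknown test SNP id")
  sub <- list(values = genotypes$values[, keep, drop = FALSE],
              variants = genotypes$variants[keep, , drop = FALSE],
              samples = genotypes$samples)
  class(sub) <- "genotype_matrix"
  out <- dominance_gwas(resid, sub)
  out$test <- "conditional"
  out$condition_snp <- condition_snp
  out
}
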