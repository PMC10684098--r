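#' Rank-based inverse normal transformation (RINT)
#'
#' `qnorm((rank - 3/8) / (n + 1/4))` (Blom offset); ties get the average
#' rank; missing values are preserved.
#'
#' @param values numeric vector with at least 2 distinct non-missing values.
#' @return transformed vector of the same length.
#' @export
rint <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  .assert(length(v) >= 2, "need at least 2 non-missing values")
  .assert(length(unique(v)) >= 2, "all values identical: ranks degenerate")
  n <- length(v)
  out <- values
  out[ok] <- stats::qnorm((rank(v, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out
}

#' Per-variant quality control: MAF, HWE, missingness
#'
#' HWE is the 1-df chi-square goodness of fit of genotype counts to
#' (p^2, 2pq, q^2); MAC is reported as `MAF * 2N`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @param miss_max maximum missing call rate (default 0.05).
#' @param n_smallest optional sample size of the smallest analysis group;
#'   MAC is additionally reported for it.
#' @return data.frame per variant: id, freq, maf, mac, mac_smallest,
#'   hwe_p, missing_rate, keep.
#' @export
variant_qc <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-6,
                       miss_max = 0.05, n_smallest = NULL) {
  G <- genotypes$values
  n_obs <- colSums(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  n0 <- colSums(G == 0, na.rm = TRUE)
  n1 <- colSums(G == 1, na.rm = TRUE)
  n2 <- colSums(G == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    n <- n_obs[j]
    if (n == 0 || maf[j] == 0) return(1)
    pj <- p[j]; qj <- 1 - pj
    e <- n * c(qj^2, 2 * pj * qj, pj^2)   # counts of A1 copies 0,1,2
    o <- c(n0[j], n1[j], n2[j])
    x2 <- sum((o - e)^2 / pmax(e, .Machine$double.eps))
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }, numeric(1))
  miss <- 1 - n_obs / nrow(G)
  keep <- maf > maf_min & hwe_p > hwe_p_min & miss < miss_max
  data.frame(id = genotypes$variants$id, freq = p, maf = maf,
             mac = maf * 2 * n_obs,
             mac_smallest = if (is.null(n_smallest)) NA_real_ else maf * 2 * n_smallest,
             hwe_p = hwe_p, missing_rate = miss, keep = keep,
             stringsAsFactors = FALSE)
}

# Residualize columns of M on the column space of X (with intercept).
.residualize <- function(M, X) {
  Q <- qr.Q(qr(X))
  M - Q %*% crossprod(Q, M)
}

.assoc_frame <- function(variants, freq, n, beta, se, p, test) {
  data.frame(chr = variants$chr, pos = variants$pos, id = variants$id,
             A1 = variants$A1, A2 = variants$A2, freq = freq, n = n,
             beta = beta, se = se, p = p, test = test,
             stringsAsFactors = FALSE)
}

#' Additive genome-wide association scan
#'
#' For each variant, the per-allele effect of A1 on the (RINT) phenotype
#' adjusting for covariates. `mode = "ols"` fits each variant by ordinary
#' least squares (equivalent, via Frisch-Waugh, to the full multiple
#' regression coefficient). `mode = "gls"` estimates variance components
#' once on the null model from a (typically bK-sparse) GRM, then runs
#' per-variant generalized least squares with that V fixed — the
#' one-variance-estimate approximation used by sparse-GRM mixed-model GWAS.
#'
#' @param y phenotype vector (RINT upstream).
#' @param genotypes a `genotype_matrix`.
#' @param covariates matrix/data.frame or NULL.
#' @param mode "ols" or "gls".
#' @param grm `grm` for gls mode (sparse/thresholded recommended).
#' @return data.frame of association records (`test = "additive"`).
#' @export
additive_gwas <- function(y, genotypes, covariates = NULL,
                          mode = c("ols", "gls"), grm = NULL) {
  mode <- match.arg(mode)
  G <- genotypes$values
  n <- length(y)
  p_a1 <- colMeans(G, na.rm = TRUE) / 2
  X <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(as.matrix(covariates))[qx$pivot[-seq_len(qx$rank)] - 1]
    stop("collinear covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  Gimp <- G
  if (anyNA(Gimp)) {
    for (j in which(colSums(is.na(Gimp)) > 0))
      Gimp[is.na(Gimp[, j]), j] <- 2 * p_a1[j]
  }
  if (mode == "gls") {
    .assert(!is.null(grm), "gls mode needs a grm")
    fit0 <- reml_two_component(y, covariates, list(grm))
    V <- fit0$varcomp[["sigma2_g"]] * grm$A + diag(fit0$varcomp[["sigma2_e"]], n)
    W <- backsolve(chol(V), diag(n), transpose = TRUE)  # W V W' = I
    y <- drop(W %*% y)
    X <- W %*% X
    Gimp <- W %*% Gimp
  }
  yr <- drop(.residualize(matrix(y), X))
  Gr <- .residualize(Gimp, X)
  gtg <- colSums(Gr^2)
  gty <- drop(crossprod(Gr, yr))
  beta <- gty / gtg
  df <- n - ncol(X) - 1
  rss <- sum(yr^2) - beta^2 * gtg
  se <- sqrt(pmax(rss, 0) / df / gtg)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  .assoc_frame(genotypes$variants, p_a1, colSums(!is.na(G)),
               beta, se, pval, "additive")
}

#' Dominance genome-wide association scan
#'
#' Per variant, fits the joint model with additive (0,1,2) and dominance
#' (0,1,0) codings and reports the dominance term, tested by a 1-df
#' chi-square Wald statistic. The phenotype must already be residualized on
#' confounders and RINT-transformed. Additive coefficients from this
#' non-orthogonal joint fit are computed but not reported as effect
#' estimates.
#'
#' @param y_adj pre-adjusted, RINT phenotype.
#' @param genotypes a `genotype_matrix`.
#' @return data.frame of records (`test = "dominance"`); variants with no
#'   heterozygotes have NA estimates and `flag = "no_heterozygotes"`.
#' @export
dominance_gwas <- function(y_adj, genotypes) {
  G <- genotypes$values
  n <- length(y_adj)
  m <- ncol(G)
  p_a1 <- colMeans(G, na.rm = TRUE) / 2
  beta <- se <- pval <- rep(NA_real_, m)
  flag <- rep("", m)
  for (j in seq_len(m)) {
    x <- G[, j]
    ok <- !is.na(x)
    xa <- x[ok]; yy <- y_adj[ok]
    xd <- as.numeric(xa == 1)
    if (sum(xd) == 0) { flag[j] <- "no_heterozygotes"; next }
    X <- cbind(1, xa, xd)
    if (qr(X)$rank < 3) { flag[j] <- "inestimable"; next }
    XtX <- crossprod(X)
    b <- solve(XtX, crossprod(X, yy))
    res <- yy - X %*% b
    s2 <- sum(res^2) / (length(yy) - 3)
    vb <- s2 * solve(XtX)
    beta[j] <- b[3]
    se[j] <- sqrt(vb[3, 3])
    pval[j] <- stats::pchisq((b[3] / se[j])^2, 1, lower.tail = FALSE)
  }
  out <- .assoc_frame(genotypes$variants, p_a1, colSums(!is.na(G)),
                      beta, se, pval, "dominance")
  out$flag <- flag
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' `beta = sum(w_i b_i) / sum(w_i)` with `w_i = 1/se_i^2`;
#' `se = 1/sqrt(sum(w_i))`; p from the Wald z. Effect alleles are
#' harmonized across strata: a stratum whose A1 equals the first stratum's
#' A2 has its effect negated and frequency reflected.
#'
#' @param records_by_stratum list of association data.frames sharing variant
#'   ids.
#' @return data.frame of meta records (`test = "meta"`, n = sum of stratum
#'   n). Variants with unresolvable allele mismatches are dropped with a
#'   warning.
#' @export
meta_ivw <- function(records_by_stratum) {
  .assert(length(records_by_stratum) >= 1, "no strata supplied")
  base <- records_by_stratum[[1]]
  if (length(records_by_stratum) == 1) {
    out <- base; out$test <- "meta"; return(out)
  }
  ids <- Reduce(intersect, lapply(records_by_stratum, `[[`, "id"))
  aligned <- lapply(records_by_stratum, function(r) r[match(ids, r$id), ])
  b0 <- aligned[[1]]
  drop_ids <- character(0)
  for (k in seq_along(aligned)[-1]) {
    r <- aligned[[k]]
    swap <- r$A1 == b0$A2 & r$A2 == b0$A1
    bad <- !(swap | (r$A1 == b0$A1 & r$A2 == b0$A2))
    if (any(bad)) drop_ids <- c(drop_ids, ids[bad])
    r$beta[swap] <- -r$beta[swap]
    r$freq[swap] <- 1 - r$freq[swap]
    aligned[[k]] <- r
  }
  if (length(drop_ids)) {
    warning("allele mismatch, variants skipped: ",
            paste(unique(drop_ids), collapse = ", "))
    keep <- !(ids %in% drop_ids)
    aligned <- lapply(aligned, function(r) r[keep, , drop = FALSE])
    b0 <- aligned[[1]]
  }
  W <- sapply(aligned, function(r) 1 / r$se^2)
  Bw <- sapply(aligned, function(r) r$beta / r$se^2)
  if (is.null(dim(W))) { W <- matrix(W, nrow = 1); Bw <- matrix(Bw, nrow = 1) }
  sw <- rowSums(W)
  beta <- rowSums(Bw) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  ntot <- Reduce(`+`, lapply(aligned, `[[`, "n"))
  out <- .assoc_frame(b0[c("chr", "pos", "id", "A1", "A2")],
                      b0$freq, ntot, beta, se, 2 * stats::pnorm(-abs(z)), "meta")
  out
}

#' Polygenic score as a weighted allele sum
#'
#' `score_i = sum_j w_j * dosage_ij` of each weight's effect allele;
#' missing genotypes contribute `2p * w` (mean imputation). Weights keyed
#' by variant id; the effect allele may be A1 or A2 of the genotype data
#' (A2 dosages are counted as `2 - g`).
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights data.frame with columns `id`, `effect_allele`, `weight`.
#' @return numeric score per sample.
#' @export
polygenic_score <- function(genotypes, weights) {
  idx <- match(weights$id, genotypes$variants$id)
  use <- !is.na(idx)
  .assert(any(use), "no overlapping variants between weights and genotypes")
  idx <- idx[use]
  w <- weights$weight[use]
  ea <- weights$effect_allele[use]
  G <- genotypes$values[, idx, drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  for (j in seq_along(idx)) G[is.na(G[, j]), j] <- 2 * p[j]
  a1 <- genotypes$variants$A1[idx]
  flip <- ea != a1
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  drop(G %*% w)
}
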