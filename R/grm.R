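#' Genomic relationship matrix from allele counts
#'
#' `A_jk = (1/m) * sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))`
#' with in-sample frequencies; missing genotypes contribute 0 to the sum
#' (mean imputation after centring) and the per-pair SNP count is adjusted.
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return list of class `grm`: `A` (n x n), `nsnp` (per-pair SNP counts),
#'   `ids`.
#' @export
compute_grm <- function(genotypes, maf_min = 0.01) {
  G <- genotypes$values
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_min
  .assert(any(keep), "no variant passes the MAF filter")
  Gk <- G[, keep, drop = FALSE]
  Z <- .std_geno(Gk, p[keep])
  m <- ncol(Z)
  obs <- !is.na(Gk) + 0
  nsnp <- tcrossprod(obs)          # SNPs observed in both members of a pair
  A <- tcrossprod(Z) / pmax(nsnp, 1)
  A <- (A + t(A)) / 2
  structure(list(A = A, nsnp = nsnp, ids = genotypes$samples$id),
            class = "grm")
}

#' Zero out small off-diagonal relationships (the bK split)
#'
#' Off-diagonal entries below `cutoff` are set to 0; the diagonal is kept.
#' Used to separate pedigree-like relatedness (kept) from the SNP-tagged
#' background (zeroed) in the two-component heritability model.
#'
#' @param grm a `grm`.
#' @param cutoff relationship threshold (default 0.05).
#' @return a `grm` with thresholded off-diagonals.
#' @export
threshold_grm <- function(grm, cutoff = 0.05) {
  A <- grm$A
  d <- diag(A)
  A[A < cutoff] <- 0
  diag(A) <- d
  grm$A <- A
  grm
}

#' Two-sided Z-test for the difference of two estimates
#'
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)`, p from the standard normal.
#' Used to compare heritability estimates (and per-SNP effects) between
#' groups under H0: no difference.
#'
#' @param est1,se1,est2,se2 estimates and their standard errors.
#' @return list: `z`, `p`.
#' @export
estimate_difference_test <- function(est1, se1, est2, se2) {
  .assert(all(se1 > 0) && all(se2 > 0), "standard errors must be positive")
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Variance components by average-information REML
#'
#' Fits `V = sum_r sigma2_r K_r + sigma2_e I` for a list of relationship
#' matrices (typically a full GRM and its bK-thresholded copy) under the
#' restricted likelihood, with fixed effects `X` (intercept + covariates).
#' Three EM warm-up iterations precede AI updates; components are clamped to
#' `[1e-6 * Vp, Vp]`. Convergence: log-likelihood change < 1e-6.
#'
#' Heritabilities follow the bK convention: `h2_snp = sigma2_g / Vp` (first
#' GRM) and `h2_ped = (sigma2_g + sigma2_bk) / Vp` when a second,
#' thresholded GRM is present. Standard errors come from the inverse AI
#' matrix, with the delta method for the ratios.
#'
#' @param y phenotype (RINT-transformed upstream).
#' @param covariates matrix/data.frame of covariates, or NULL.
#' @param grms list of `grm` objects (or plain matrices), length 1 or more.
#' @param max_iter maximum iterations (default 100).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return list of class `varcomp_fit`: `varcomp` (named components incl.
#'   residual), `se`, `h2_snp`, `h2_snp_se`, `h2_ped`, `h2_ped_se`,
#'   `loglik`, `converged`, `iterations`.
#' @export
reml_two_component <- function(y, covariates = NULL, grms,
                               max_iter = 100, tol = 1e-6) {
  Ks <- lapply(grms, function(g) if (inherits(g, "grm")) g$A else as.matrix(g))
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qr_x <- qr(X)
  X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  r <- length(Ks)
  Vp <- stats::var(y)
  s2 <- rep(Vp / (r + 1), r + 1)   # components: GRMs ..., residual
  lo <- 1e-6 * Vp

  eval_parts <- function(s2) {
    V <- diag(s2[r + 1], n)
    for (i in seq_len(r)) V <- V + s2[i] * Ks[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViX_i <- solve(XtViX)
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                  sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll))
  }

  parts <- eval_parts(s2)
  .assert(!is.null(parts), "initial V is not positive definite")
  ll_old <- parts$ll
  converged <- FALSE
  it <- 0
  AI <- NULL
  for (it in seq_len(max_iter)) {
    P <- parts$P; Py <- parts$Py
    KPy <- lapply(seq_len(r + 1), function(i)
      if (i <= r) Ks[[i]] %*% Py else Py)
    score <- numeric(r + 1)
    for (i in seq_len(r + 1)) {
      trPK <- if (i <= r) sum(P * Ks[[i]]) else sum(diag(P))
      score[i] <- -0.5 * (trPK - sum(Py * KPy[[i]]))
    }
    if (it <= 3) {
      # EM warm-up: stable but slow updates
      s2_new <- numeric(r + 1)
      for (i in seq_len(r + 1)) {
        trPK <- if (i <= r) sum(P * Ks[[i]]) else sum(diag(P))
        s2_new[i] <- s2[i] + s2[i]^2 * (sum(Py * KPy[[i]]) - trPK) / n
      }
    } else {
      AI <- matrix(0, r + 1, r + 1)
      PKPy <- lapply(KPy, function(v) P %*% v)
      for (i in seq_len(r + 1)) for (j in i:(r + 1)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
      }
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(delta)) delta <- score / diag(AI)
      s2_new <- s2 + delta
      # step-halve if the update leaves the feasible region badly
      step <- 1
      while (any(s2_new > 2 * Vp) && step > 1e-3) {
        step <- step / 2
        s2_new <- s2 + step * delta
      }
    }
    s2_new <- pmin(pmax(s2_new, lo), Vp)
    parts_new <- eval_parts(s2_new)
    if (is.null(parts_new)) { s2_new <- (s2 + s2_new) / 2; parts_new <- eval_parts(s2_new) }
    if (is.null(parts_new)) break
    s2 <- s2_new
    parts <- parts_new
    if (it > 3 && abs(parts$ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- parts$ll
  }
  if (!converged) warning("REML did not converge; returning partial results")

  # information matrix at the solution for standard errors
  P <- parts$P; Py <- parts$Py
  KPy <- lapply(seq_len(r + 1), function(i) if (i <= r) Ks[[i]] %*% Py else Py)
  PKPy <- lapply(KPy, function(v) P %*% v)
  AI <- matrix(0, r + 1, r + 1)
  for (i in seq_len(r + 1)) for (j in i:(r + 1))
    AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
  covm <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, r + 1, r + 1))
  se <- sqrt(pmax(diag(covm), 0))

  tot <- sum(s2)
  # delta method for ratios sigma2_i / sum(sigma2)
  h2_ratio <- function(w) {
    est <- sum(w * s2) / tot
    grad <- (w * tot - sum(w * s2)) / tot^2
    se <- sqrt(max(0, drop(t(grad) %*% covm %*% grad)))
    c(est = est, se = se)
  }
  nm <- c(if (r >= 1) "sigma2_g", if (r >= 2) "sigma2_bk",
          if (r > 2) paste0("sigma2_k", 3:r), "sigma2_e")
  names(s2) <- names(se) <- nm
  h2s <- h2_ratio(c(1, rep(0, r)))
  h2p <- if (r >= 2) h2_ratio(c(1, 1, rep(0, r - 1))) else h2s
  structure(list(varcomp = s2, se = se, vcov = covm,
                 h2_snp = unname(h2s["est"]), h2_snp_se = unname(h2s["se"]),
                 h2_ped = unname(h2p["est"]), h2_ped_se = unname(h2p["se"]),
                 loglik = parts$ll, converged = converged, iterations = it),
            class = "varcomp_fit")
}
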