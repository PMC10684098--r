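#' Reference principal components for ancestry assignment
#'
#' Computes the top-k principal components of a reference panel from
#' genotypes standardized by in-panel allele frequencies (mean `2p`, scale
#' `sqrt(2p(1-p))`); monomorphic variants are dropped. Loadings are the
#' right singular vectors (orthonormal); scores are the projections of the
#' standardized genotypes onto them.
#'
#' @param ref_genotypes a `genotype_matrix` for the reference panel.
#' @param k number of PCs (default 3, the number used for ancestry calls).
#' @return list of class `ancestry_model`: `loadings` (variants x k),
#'   `scores` (reference samples x k), `freq`, `keep` (polymorphic mask),
#'   `variants`, `k`; population parameters are added by
#'   [fit_ancestry_model()].
#' @export
reference_pca <- function(ref_genotypes, k = 3) {
  G <- ref_genotypes$values
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  .assert(any(keep), "all reference variants are monomorphic")
  Z <- .std_geno(G[, keep, drop = FALSE], p[keep])
  n <- nrow(Z); m <- ncol(Z)
  .assert(k <= min(n - 1, m), "k exceeds the rank of the reference matrix")
  if (n <= m) {
    # eigen-decompose the n x n cross-product, recover loadings from scores
    K <- tcrossprod(Z)
    ev <- eigen(K, symmetric = TRUE)
    d <- sqrt(pmax(ev$values[seq_len(k)], 0))
    .assert(all(d > 1e-12), "k exceeds the numerical rank of the reference")
    U <- ev$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(Z, U) %*% diag(1 / d, k)
    scores <- U %*% diag(d, k)
  } else {
    ev <- eigen(crossprod(Z), symmetric = TRUE)
    V <- ev$vectors[, seq_len(k), drop = FALSE]
    scores <- Z %*% V
  }
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  structure(list(loadings = V, scores = scores, freq = p[keep], keep = keep,
                 variants = ref_genotypes$variants[keep, , drop = FALSE],
                 samples = ref_genotypes$samples, k = k),
            class = "ancestry_model")
}

# Match study variants to model variants by (chr, pos, unordered allele pair).
# Returns NULL for ambiguous (A/T, C/G) variants when drop_ambiguous.
.match_variants <- function(model_var, study_var, drop_ambiguous = TRUE) {
  key <- function(v) paste(v$chr, v$pos, sep = ":")
  mk <- key(model_var); sk <- key(study_var)
  idx <- match(mk, sk)
  flip <- rep(FALSE, length(idx))
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (i in which(!is.na(idx))) {
    j <- idx[i]
    a1 <- study_var$A1[j]; a2 <- study_var$A2[j]
    m1 <- model_var$A1[i]; m2 <- model_var$A2[i]
    if (drop_ambiguous && m1 == comp[[m2]]) { idx[i] <- NA; next }
    if (a1 == m1 && a2 == m2) {
      flip[i] <- FALSE
    } else if (a1 == m2 && a2 == m1) {
      flip[i] <- TRUE
    } else if (a1 == comp[[m1]] && a2 == comp[[m2]]) {
      flip[i] <- FALSE          # strand flip, same orientation
    } else if (a1 == comp[[m2]] && a2 == comp[[m1]]) {
      flip[i] <- TRUE
    } else idx[i] <- NA
  }
  list(idx = idx, flip = flip)
}

#' Project study samples onto reference PCs
#'
#' Study variants are intersected with the model's by (chr, pos, unordered
#' allele pair); A1/A2 swaps are handled by counting the other allele.
#' Standardization uses the reference means and scales, so reference samples
#' project exactly onto their own scores.
#'
#' @param model an `ancestry_model` from [reference_pca()].
#' @param genotypes study `genotype_matrix`.
#' @param min_overlap minimum matched variant count (default 10).
#' @return matrix of scores (samples x k).
#' @export
project_samples <- function(model, genotypes, min_overlap = 10) {
  mm <- .match_variants(model$variants, genotypes$variants)
  use <- which(!is.na(mm$idx))
  .assert(length(use) >= min_overlap,
          sprintf("only %d variants overlap the reference (need >= %d)",
                  length(use), min_overlap))
  X <- genotypes$values[, mm$idx[use], drop = FALSE]
  fl <- mm$flip[use]
  if (any(fl)) X[, fl] <- 2 - X[, fl]
  p <- model$freq[use]
  Z <- sweep(X, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  S <- Z %*% model$loadings[use, , drop = FALSE]
  # rescale for partial overlap so projected scale matches the reference
  if (length(use) < nrow(model$loadings))
    S <- S * nrow(model$loadings) / length(use)
  rownames(S) <- genotypes$samples$id
  S
}

#' Fit per-population Gaussian parameters on the reference scores
#'
#' @param model an `ancestry_model` with reference `scores` and sample
#'   ancestry labels.
#' @param priors named prior weights (default equal); must sum to 1 after
#'   normalization.
#' @param eps covariance ridge, as a multiple of the mean diagonal
#'   (default 1e-6).
#' @return the model with `populations` (per-population mean, covariance,
#'   prior) attached.
#' @export
fit_ancestry_model <- function(model, priors = NULL, eps = 1e-6) {
  labs <- model$samples$ancestry
  pops <- sort(unique(labs))
  if (is.null(priors)) priors <- stats::setNames(rep(1 / length(pops), length(pops)), pops)
  priors <- priors / sum(priors)
  fits <- lapply(pops, function(pp) {
    S <- model$scores[labs == pp, , drop = FALSE]
    mu <- colMeans(S)
    Sg <- stats::cov(S)
    Sg <- Sg + diag(eps * mean(diag(Sg)), ncol(Sg))
    .assert(det(Sg) > 0, sprintf("singular covariance for population %s", pp))
    list(mean = mu, cov = Sg, prior = priors[[pp]])
  })
  names(fits) <- pops
  model$populations <- fits
  model
}

# log multivariate normal density
.ldmvn <- function(x, mu, S) {
  k <- length(mu)
  ch <- chol(S)
  d <- x - mu
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Assign samples to ancestry groups by Gaussian posterior
#'
#' Posterior over populations for each sample's PC score under the fitted
#' per-population multivariate Gaussians; the hard label is the argmax, with
#' ties broken by population order and flagged.
#'
#' @param model an `ancestry_model` with fitted `populations`.
#' @param scores matrix of PC scores (samples x k).
#' @return data.frame: IID, PC columns, one `post_<pop>` column per
#'   population, `label`, `tie` flag.
#' @export
assign_ancestry <- function(model, scores) {
  .assert(!is.null(model$populations), "fit_ancestry_model() has not been run")
  pops <- names(model$populations)
  L <- vapply(pops, function(pp) {
    f <- model$populations[[pp]]
    apply(scores, 1, .ldmvn, mu = f$mean, S = f$cov) + log(f$prior)
  }, numeric(nrow(scores)))
  if (is.null(dim(L))) L <- matrix(L, nrow = 1, dimnames = list(NULL, pops))
  mx <- apply(L, 1, max)
  P <- exp(L - mx)
  P <- P / rowSums(P)
  lab_idx <- apply(P, 1, which.max)
  tie <- apply(P, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  out <- data.frame(IID = rownames(scores) %||% seq_len(nrow(scores)),
                    scores, stringsAsFactors = FALSE)
  colnames(P) <- paste0("post_", pops)
  out <- cbind(out, P)
  out$label <- pops[lab_idx]
  out$tie <- tie
  out
}
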