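# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-standardize an allele-count matrix using supplied (or in-sample)
# allele frequencies; missing entries become 0 after centring (mean imputation).
.std_geno <- function(G, p = NULL) {
  if (is.null(p)) p <- colMeans(G, na.rm = TRUE) / 2
  denom <- sqrt(2 * p * (1 - p))
  keep <- denom > 0
  Z <- sweep(G, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, pmax(denom, .Machine$double.eps), "/")
  attr(Z, "poly") <- keep
  Z
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Deterministic per-stage seed derived from a master seed; stays < 2^31.
.substream <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(tag)) * 1009L) %% 2147483562L
}
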