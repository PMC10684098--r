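# Shared fixtures: small genotype containers and cohort simulations built
# in code at test time.

make_geno <- function(values, chr = NULL, pos = NULL, ids = NULL,
                      ancestry = "EUR") {
  values <- as.matrix(values)
  m <- ncol(values); n <- nrow(values)
  structure(list(
    values = values,
    variants = data.frame(
      chr = chr %||% rep(1L, m),
      pos = pos %||% seq_len(m) * 1000L,
      id = ids %||% sprintf("v%03d", seq_len(m)),
      A1 = rep_len(c("A", "C"), m), A2 = rep_len(c("G", "T"), m),
      stringsAsFactors = FALSE),
    samples = data.frame(id = sprintf("s%04d", seq_len(n)),
                         ancestry = rep_len(ancestry, n),
                         stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# association records -> .ma layout
as_ma <- function(rec) {
  data.frame(SNP = rec$id, A1 = rec$A1, A2 = rec$A2, freq = rec$freq,
             b = rec$beta, se = rec$se, p = rec$p, N = rec$n,
             stringsAsFactors = FALSE)
}
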