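#' Effect-size correlation adjusted for estimation error (rb)
#'
#' For aligned effect estimates from two analyses,
#' `rb = cov(bx, by) / sqrt((var(bx) - mean(se_x^2)) * (var(by) - mean(se_y^2)))`:
#' subtracting the mean squared standard errors removes the attenuation
#' that sampling noise induces in the naive Pearson correlation. The
#' standard error is a leave-one-variant-out jackknife.
#'
#' @param panel data.frame with columns `bx`, `sex`, `by`, `sey` (same
#'   effect allele per row; harmonize upstream).
#' @param jackknife compute the leave-one-out standard error (default
#'   TRUE; disable inside replicate loops).
#' @return list of class `rb_result`: `rb`, `se`, `n`, `flag` (set when
#'   |rb| > 1.05).
#' @export
rb <- function(panel, jackknife = TRUE) {
  .assert(all(c("bx", "sex", "by", "sey") %in% names(panel)),
          "panel needs columns bx, sex, by, sey")
  ok <- stats::complete.cases(panel[c("bx", "sex", "by", "sey")])
  d <- panel[ok, , drop = FALSE]
  n <- nrow(d)
  .assert(n >= 3, "need at least 3 variant pairs")
  est <- function(d) {
    vx <- stats::var(d$bx) - mean(d$sex^2)
    vy <- stats::var(d$by) - mean(d$sey^2)
    if (vx <= 0) stop("no detectable effect-size variance on side x", call. = FALSE)
    if (vy <= 0) stop("no detectable effect-size variance on side y", call. = FALSE)
    stats::cov(d$bx, d$by) / sqrt(vx * vy)
  }
  r <- est(d)
  se <- NA_real_
  if (jackknife) {
    jack <- vapply(seq_len(n), function(i)
      tryCatch(est(d[-i, , drop = FALSE]), error = function(e) NA_real_),
      numeric(1))
    jack <- jack[is.finite(jack)]
    se <- sqrt((length(jack) - 1) / length(jack) *
                 sum((jack - mean(jack))^2))
  }
  structure(list(rb = r, se = se, n = n, flag = abs(r) > 1.05),
            class = "rb_result")
}

#' Per-variant effect-size difference test between two analyses
#'
#' `t = (b1 - b2) / sqrt(se1^2 + se2^2)`, two-sided p from the standard
#' normal. Identical algebra to [estimate_difference_test()], kept on the
#' association scale for panel-wise use.
#'
#' @param b1,se1,b2,se2 effect estimates and standard errors (vectors ok).
#' @return data.frame: t, p.
#' @export
effect_difference_test <- function(b1, se1, b2, se2) {
  .assert(all(se1 > 0) && all(se2 > 0), "standard errors must be positive")
  t <- (b1 - b2) / sqrt(se1^2 + se2^2)
  data.frame(t = t, p = 2 * stats::pnorm(-abs(t)))
}

#' Classify loci as shared, new, or lost between two GWAS
#'
#' Each supplied independent locus of analysis A is labelled: `shared`
#' (genome-wide significant in both), `new` (GWS in A only — sub-labelled
#' "no suggestive evidence" when the B p-value exceeds `suggestive`), or
#' `lost` (GWS in B only, sub-labelled "suggestive in A" when A is below
#' `suggestive`). New/lost loci are annotated with the distance and the
#' maximum LD r-squared to the nearest GWS variant of the other analysis
#' within `window_bp` (a radius on the same chromosome).
#'
#' @param gwas_a,gwas_b data.frames of independent loci (columns id, chr,
#'   pos, p at minimum). Loci absent from the other analysis are annotated
#'   `untested`.
#' @param ld_ref an `ld_ref`, or NULL to skip LD annotation.
#' @param gws genome-wide significance threshold (default 5e-8).
#' @param suggestive suggestive threshold (default 1e-6).
#' @param window_bp annotation window radius (default 1 Mb).
#' @return data.frame: id, chr, pos, p_a, p_b, label, sublabel,
#'   nearest_bp, max_ld_r2.
#' @export
classify_loci <- function(gwas_a, gwas_b, ld_ref = NULL,
                          gws = 5e-8, suggestive = 1e-6, window_bp = 1e6) {
  all_ids <- union(gwas_a$id, gwas_b$id)
  pa <- gwas_a$p[match(all_ids, gwas_a$id)]
  pb <- gwas_b$p[match(all_ids, gwas_b$id)]
  chr <- ifelse(all_ids %in% gwas_a$id,
                gwas_a$chr[match(all_ids, gwas_a$id)],
                gwas_b$chr[match(all_ids, gwas_b$id)])
  pos <- ifelse(all_ids %in% gwas_a$id,
                gwas_a$pos[match(all_ids, gwas_a$id)],
                gwas_b$pos[match(all_ids, gwas_b$id)])
  gws_a <- !is.na(pa) & pa < gws
  gws_b <- !is.na(pb) & pb < gws
  label <- ifelse(gws_a & gws_b, "shared",
                  ifelse(gws_a, "new", ifelse(gws_b, "lost", "none")))
  sublabel <- rep("", length(all_ids))
  sublabel[label == "new" & is.na(pb)] <- "untested"
  sublabel[label == "new" & !is.na(pb) & pb > suggestive] <- "no suggestive evidence"
  sublabel[label == "new" & !is.na(pb) & pb <= suggestive] <- "suggestive in other"
  sublabel[label == "lost" & is.na(pa)] <- "untested"
  sublabel[label == "lost" & !is.na(pa) & pa <= suggestive] <- "suggestive in A"
  sublabel[label == "lost" & !is.na(pa) & pa > suggestive] <- "no suggestive evidence"

  nearest_bp <- max_ld <- rep(NA_real_, length(all_ids))
  annotate <- function(i, other) {
    hits <- other[!is.na(other$p) & other$p < gws & other$chr == chr[i] &
                    abs(other$pos - pos[i]) <= window_bp, , drop = FALSE]
    if (!nrow(hits)) return(c(NA_real_, NA_real_))
    dd <- abs(hits$pos - pos[i])
    r2 <- NA_real_
    if (!is.null(ld_ref)) {
      ji <- match(all_ids[i], ld_ref$variants$id)
      jo <- match(hits$id, ld_ref$variants$id)
      use <- !is.na(jo)
      if (!is.na(ji) && any(use)) {
        r <- suppressWarnings(stats::cor(ld_ref$Xc[, ji],
                                         ld_ref$Xc[, jo[use], drop = FALSE]))
        r2 <- max(r^2, na.rm = TRUE)
      }
    }
    c(min(dd), r2)
  }
  for (i in which(label %in% c("new", "lost"))) {
    ann <- annotate(i, if (label[i] == "new") gwas_b else gwas_a)
    nearest_bp[i] <- ann[1]; max_ld[i] <- ann[2]
  }
  out <- data.frame(id = all_ids, chr = chr, pos = pos, p_a = pa, p_b = pb,
                    label = label, sublabel = sublabel,
                    nearest_bp = nearest_bp, max_ld_r2 = max_ld,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$pos), ]
  rownames(out) <- NULL
  out
}
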