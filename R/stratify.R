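#' Assign samples to skin-colour strata with exclusion bookkeeping
#'
#' Default grouping: "very fair" and "fair" form the light stratum;
#' "light olive", "dark olive" and "brown" form the dark stratum; "black"
#' reports within the light-skin ancestry group are excluded, as are
#' samples whose repeated skin reports disagree across visits and samples
#' with unknown categories.
#'
#' @param cohort cohort data.frame with `skin` (and optionally `skin2`, a
#'   second-visit report).
#' @param light,dark character vectors of categories per stratum.
#' @param exclude categories excluded outright (default "black").
#' @param unknown_action "exclude" (default, with warning) or "error".
#' @return list: `assignment` (data.frame IID, stratum; excluded samples
#'   carry NA), `exclusions` (counts by reason).
#' @export
build_strata <- function(cohort,
                         light = c("very fair", "fair"),
                         dark = c("light olive", "dark olive", "brown"),
                         exclude = "black",
                         unknown_action = c("exclude", "error")) {
  unknown_action <- match.arg(unknown_action)
  skin <- as.character(cohort$skin)
  reason <- rep(NA_character_, nrow(cohort))
  if ("skin2" %in% names(cohort)) {
    second <- as.character(cohort$skin2)
    inconsistent <- !is.na(second) & second != skin
    reason[inconsistent] <- "inconsistent"
  }
  known <- c(light, dark, exclude)
  unk <- is.na(reason) & !(skin %in% known)
  if (any(unk)) {
    if (unknown_action == "error") stop("unknown skin categories present")
    warning(sum(unk), " sample(s) with unknown skin category excluded")
    reason[unk] <- "unknown_category"
  }
  excl <- is.na(reason) & skin %in% exclude
  reason[excl] <- "excluded_category"
  stratum <- rep(NA_character_, nrow(cohort))
  ok <- is.na(reason)
  stratum[ok & skin %in% light] <- "light"
  stratum[ok & skin %in% dark] <- "dark"
  exclusions <- table(factor(reason,
    levels = c("inconsistent", "excluded_category", "unknown_category")))
  list(assignment = data.frame(IID = cohort$IID, stratum = stratum,
                               reason = reason, stringsAsFactors = FALSE),
       exclusions = as.data.frame(exclusions, responseName = "n",
                                  stringsAsFactors = FALSE))
}

#' Skin-colour-stratified GWAS with inverse-variance meta-analysis
#'
#' Within each stratum: principal components are recomputed on the
#' stratum's samples, the phenotype is RINT-transformed within stratum,
#' and an additive scan is run with the supplied covariates plus the
#' stratum PCs. Stratum results are combined by fixed-effect IVW
#' meta-analysis, restricted to variants passing the MAF floor in every
#' stratum.
#'
#' @param y raw phenotype vector (nmol/L), aligned with `genotypes`.
#' @param genotypes a `genotype_matrix`.
#' @param strata character/factor stratum label per sample (NA = excluded).
#' @param covariates covariate matrix/data.frame or NULL.
#' @param n_pcs within-stratum PCs to include (default 2; 0 for none).
#' @param maf_min per-stratum MAF floor for the meta (default 0.01).
#' @return list: `meta` (meta association records), `per_stratum` (named
#'   list of stratum records).
#' @export
stratified_gwas_meta <- function(y, genotypes, strata, covariates = NULL,
                                 n_pcs = 2, maf_min = 0.01) {
  labs <- unique(strata[!is.na(strata)])
  .assert(length(labs) >= 1, "no stratum labels supplied")
  per <- list()
  keep_ids <- NULL
  for (s in labs) {
    sel <- which(!is.na(strata) & strata == s)
    sub <- list(values = genotypes$values[sel, , drop = FALSE],
                variants = genotypes$variants,
                samples = genotypes$samples[sel, , drop = FALSE])
    class(sub) <- "genotype_matrix"
    cov_s <- if (!is.null(covariates)) as.matrix(covariates)[sel, , drop = FALSE]
    if (n_pcs > 0) {
      pcs <- tryCatch(reference_pca(sub, k = n_pcs)$scores,
                      error = function(e) NULL)
      if (!is.null(pcs)) cov_s <- cbind(cov_s, pcs)
    }
    ys <- rint(y[sel])
    rec <- additive_gwas(ys, sub, cov_s, mode = "ols")
    p <- rec$freq
    pass <- pmin(p, 1 - p) >= maf_min
    ids_pass <- rec$id[pass]
    keep_ids <- if (is.null(keep_ids)) ids_pass else intersect(keep_ids, ids_pass)
    per[[s]] <- rec
  }
  .assert(length(keep_ids) > 0, "no variant passes the MAF floor in every stratum")
  per_kept <- lapply(per, function(r) r[r$id %in% keep_ids, , drop = FALSE])
  meta <- meta_ivw(per_kept)
  list(meta = meta, per_stratum = per)
}

#' Compare stratified-meta loci against the unstratified analysis
#'
#' Runs conditional-and-joint selection on both summary sets and labels
#' every independent locus shared / new / lost via [classify_loci()].
#'
#' @param meta_records meta association records (or `.ma` data.frame).
#' @param agnostic_records unstratified records.
#' @param ld_ref an `ld_ref` for selection and LD annotation.
#' @param gws,suggestive thresholds passed through.
#' @return list: `loci` (classified locus table), `cojo_meta`,
#'   `cojo_agnostic`.
#' @export
compare_to_agnostic <- function(meta_records, agnostic_records, ld_ref,
                                gws = 5e-8, suggestive = 1e-6) {
  as_ma <- function(r) {
    if ("SNP" %in% names(r)) return(r)
    data.frame(SNP = r$id, A1 = r$A1, A2 = r$A2, freq = r$freq,
               b = r$beta, se = r$se, p = r$p, N = r$n,
               stringsAsFactors = FALSE)
  }
  cm <- cojo_select(as_ma(meta_records), ld_ref, p_threshold = gws)
  ca <- cojo_select(as_ma(agnostic_records), ld_ref, p_threshold = gws)
  lookup <- function(sel, other) {
    # independent loci of one analysis, with the *marginal* p of the same
    # variant in the other analysis
    om <- as_ma(other)
    data.frame(id = sel$SNP, chr = sel$chr, pos = sel$pos,
               p = om$p[match(sel$SNP, om$SNP)], stringsAsFactors = FALSE)
  }
  a_tab <- data.frame(id = cm$selected$SNP, chr = cm$selected$chr,
                      pos = cm$selected$pos, p = cm$selected$p,
                      stringsAsFactors = FALSE)
  b_tab <- lookup(cm$selected, agnostic_records)
  # loci selected only in the agnostic analysis contribute "lost" candidates
  extra <- ca$selected[!(ca$selected$SNP %in% cm$selected$SNP), , drop = FALSE]
  if (nrow(extra)) {
    om <- as_ma(meta_records)
    a_tab <- rbind(a_tab, data.frame(id = extra$SNP, chr = extra$chr,
                                     pos = extra$pos,
                                     p = om$p[match(extra$SNP, om$SNP)]))
    b_tab <- rbind(b_tab, data.frame(id = extra$SNP, chr = extra$chr,
                                     pos = extra$pos, p = extra$p))
  }
  loci <- classify_loci(a_tab, b_tab, ld_ref, gws = gws, suggestive = suggestive)
  list(loci = loci, cojo_meta = cm, cojo_agnostic = ca)
}
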