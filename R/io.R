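#' Write genotypes as PLINK bed/bim/fam
#'
#' Variant-major bed: magic bytes 0x6C 0x1B, mode byte 0x01, then one
#' padded block per variant with 2-bit codes packed 4 samples per byte
#' (low bits first): 00 = homozygous A1 (2 copies), 10 = heterozygous,
#' 11 = homozygous A2, 01 = missing. Padding bits are zero. The .bim is
#' 6-column (chr, id, cM = 0, pos, A1, A2); the .fam uses the sample id
#' for both family and individual id.
#'
#' @param genotypes a `genotype_matrix` (values = counts of A1).
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return the prefix, invisibly.
#' @export
write_bed <- function(genotypes, prefix) {
  G <- genotypes$values
  n <- nrow(G); m <- ncol(G)
  code <- matrix(3L, n, m)                 # hom A2
  code[which(G == 2L)] <- 0L               # hom A1
  code[which(G == 1L)] <- 2L               # het
  code[which(is.na(G))] <- 1L              # missing
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  dim(code) <- c(4, bpv * m)
  bytes <- as.raw(code[1, ] + code[2, ] * 4L + code[3, ] * 16L + code[4, ] * 64L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  v <- genotypes$variants
  utils::write.table(data.frame(v$chr, v$id, 0, v$pos, v$A1, v$A2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- genotypes$samples
  utils::write.table(data.frame(s$id, s$id, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam into a genotype matrix
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return a `genotype_matrix` (ancestry labels NA; the fam format does
#'   not carry them).
#' @export
read_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "id", "cM", "pos", "A1", "A2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  .assert(length(magic) == 3 && identical(magic, as.raw(c(0x6c, 0x1b, 0x01))),
          "bad bed magic bytes or non-variant-major mode")
  bpv <- ceiling(n / 4)
  bytes <- readBin(con, "raw", bpv * m)
  .assert(length(bytes) == bpv * m, "truncated bed genotype block")
  b <- as.integer(bytes)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  dim(codes) <- c(4 * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)        # code 0,1,2,3 -> A1 count
  G <- matrix(lut[codes + 1L], n, m)
  structure(list(values = G,
                 variants = bim[c("chr", "pos", "id", "A1", "A2")],
                 samples = data.frame(id = fam$V2, ancestry = NA_character_,
                                      stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' Read COJO-style `.ma` summary statistics
#'
#' Whitespace-separated with header `SNP A1 A2 freq b se p N`; comment
#' lines starting `#` are skipped. Non-numeric fields raise a row-level
#' error naming the offending line.
#'
#' @param path file path.
#' @return data.frame with typed columns; empty file gives 0 rows.
#' @export
read_ma <- function(path) {
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  first <- tryCatch(utils::read.table(path, header = TRUE, nrows = 1,
                                      comment.char = "#",
                                      stringsAsFactors = FALSE),
                    error = function(e) NULL)
  if (is.null(first))
    return(stats::setNames(data.frame(character(0), character(0), character(0),
                                      numeric(0), numeric(0), numeric(0),
                                      numeric(0), numeric(0),
                                      stringsAsFactors = FALSE), need))
  d <- utils::read.table(path, header = TRUE, comment.char = "#",
                         colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(d))
  .assert(length(missing_cols) == 0,
          paste("missing .ma column(s):", paste(missing_cols, collapse = ", ")))
  d <- d[need]
  for (cc in c("freq", "b", "se", "p", "N")) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- is.na(v) & !(d[[cc]] %in% c("NA", ""))
    if (any(bad))
      stop(sprintf("non-numeric value '%s' in column %s at data line %d",
                   d[[cc]][which(bad)[1]], cc, which(bad)[1]), call. = FALSE)
    d[[cc]] <- v
  }
  d
}

#' Write `.ma` summary statistics
#'
#' @param records data.frame with columns SNP A1 A2 freq b se p N (an
#'   association record frame with id/beta/n columns is converted).
#' @param path output path.
#' @param header_comment optional provenance lines written as `#` comments.
#' @return the path, invisibly.
#' @export
write_ma <- function(records, path, header_comment = NULL) {
  if (!"SNP" %in% names(records))
    records <- data.frame(SNP = records$id, A1 = records$A1, A2 = records$A2,
                          freq = records$freq, b = records$beta,
                          se = records$se, p = records$p, N = records$n,
                          stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(format(records, digits = 15, trim = TRUE,
                            scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
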