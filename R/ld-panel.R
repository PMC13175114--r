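#' Construct a genotype panel object
#'
#' @param dosages n-sample by m-variant numeric matrix of ALT-allele counts
#'   in \[0, 2\] (`NA` allowed before imputation).
#' @param variants Data frame with `chrom`, `pos`, `a1` (counted/ALT allele),
#'   `a2` (other/REF allele).
#' @param samples Sample identifiers (default from rownames).
#' @param missing_rate Optional per-variant fraction of genotypes that were
#'   imputed.
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, samples = rownames(dosages),
                           missing_rate = NULL) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(variants), nrow(variants) == ncol(dosages),
            all(c("chrom", "pos", "a1", "a2") %in% names(variants)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (any(colSums(!is.na(dosages)) == 0L)) {
    stop("variant(s) with 100% missing genotypes")
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(missing_rate)) missing_rate <- colMeans(is.na(dosages))
  variants$chrom <- as.character(variants$chrom)
  colnames(dosages) <- variant_key(variants$chrom, variants$pos,
                                   variants$a1, variants$a2)
  structure(list(dosages = dosages, variants = variants, samples = samples,
                 missing_rate = missing_rate),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (mean missingness %.3g)\n",
              nrow(x$dosages), ncol(x$dosages), mean(x$missing_rate)))
  invisible(x)
}

gt_to_dosage <- function(gt) {
  # GT strings like 0/1, 1|0, ./.; anything not biallelic 0/1 is NA here
  u <- unique(as.vector(gt))
  val <- rep(NA_real_, length(u))
  names(val) <- u
  for (g in u) {
    if (is.na(g)) next
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) == 2L && all(al %in% c("0", "1"))) {
      val[g] <- sum(al == "1")
    }
  }
  matrix(val[as.vector(gt)], nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Load an LD reference panel from a VCF
#'
#' Dosages are ALT-allele counts decoded from GT fields. Multi-allelic sites
#' are skipped (with a logged count) unless `multiallelic = "split"` is later
#' supported by upstream normalization. Missing genotypes are mean-imputed
#' per variant so downstream correlation matrices stay consistent with a
#' complete-data estimate; the imputed fraction is recorded per variant.
#'
#' @param path VCF 4.x file (plain or bgzipped) with GT fields.
#' @param region Optional `"chrom:start-end"` restriction (1-based inclusive).
#' @param multiallelic `"skip"` (default) drops multi-allelic records.
#' @return A `genotype_panel`.
#' @export
load_panel <- function(path, region = NULL, multiallelic = c("skip")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  keep <- rep(TRUE, length(pos))
  multi <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L
  if (any(multi)) {
    pqtlx_log("skipped %d multi-allelic/indel record(s)", sum(multi))
    keep <- keep & !multi
  }
  if (!is.null(region)) {
    mreg <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(mreg) != 4L) stop("malformed region: ", region)
    keep <- keep & chrom == mreg[2] &
      pos >= as.numeric(mreg[3]) & pos <= as.numeric(mreg[4])
  }
  if (!any(keep)) stop("no biallelic variants in region")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  dos <- t(gt_to_dosage(gt))                       # samples x variants
  miss <- colMeans(is.na(dos))
  if (any(miss > 0)) {
    pqtlx_log("mean-imputed missing genotypes at %d variant(s)", sum(miss > 0),
              level = 2L)
    for (j in which(miss > 0)) {
      mu <- mean(dos[, j], na.rm = TRUE)
      if (!is.finite(mu)) stop("variant with all genotypes missing")
      dos[is.na(dos[, j]), j] <- mu
    }
  }
  variants <- data.frame(chrom = chrom[keep], pos = pos[keep],
                         a1 = alt[keep], a2 = ref[keep],
                         stringsAsFactors = FALSE)
  genotype_panel(dos, variants, samples = colnames(gt), missing_rate = miss)
}

#' Load a genotype panel from a plain dosage TSV
#'
#' Fixture-friendly alternative to VCF: first column `sample`, remaining
#' columns named `chrom:pos:a1:a2` (a1 = counted allele) holding dosages in
#' \[0, 2\]. Missing values are mean-imputed per variant.
#'
#' @param path Dosage TSV path.
#' @return A `genotype_panel`.
#' @export
load_panel_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  samples <- as.character(dt[[1]])
  dos <- as.matrix(dt[, -1])
  rownames(dos) <- samples
  parts <- strsplit(colnames(dos), ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("dosage TSV columns must be named chrom:pos:a1:a2")
  }
  variants <- data.frame(chrom = vapply(parts, `[`, "", 1),
                         pos = as.numeric(vapply(parts, `[`, "", 2)),
                         a1 = vapply(parts, `[`, "", 3),
                         a2 = vapply(parts, `[`, "", 4),
                         stringsAsFactors = FALSE)
  miss <- colMeans(is.na(dos))
  for (j in which(miss > 0)) {
    dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
  }
  genotype_panel(dos, variants, samples = samples, missing_rate = miss)
}

#' Compute a variant-variant LD (Pearson r) matrix
#'
#' Correlations are taken over dosage columns. When `effect_alleles` is
#' given, the dosage of any panel variant whose counted (ALT) allele differs
#' from the harmonized effect allele is flipped (`2 - d`) first, fixing the
#' sign convention at LD-construction time so downstream conditional
#' analysis never re-flips. Monomorphic variants are excluded with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param keys Optional data frame (`chrom`, `pos`, `a1`, `a2`) selecting and
#'   ordering variants; defaults to all panel variants.
#' @param effect_alleles Optional character vector (same length as `keys`
#'   rows) of effect alleles to orient to; defaults to `keys$a1`.
#' @return Object of class `ld_matrix`: list with `variants` (data frame) and
#'   `r` (symmetric unit-diagonal matrix).
#' @export
compute_ld <- function(panel, keys = NULL, effect_alleles = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  pv <- panel$variants
  pk <- variant_match_key(pv$chrom, pv$pos, pv$a1, pv$a2)
  if (is.null(keys)) {
    sel <- seq_along(pk)
    keys <- pv
  } else {
    want <- variant_match_key(keys$chrom, keys$pos, keys$a1, keys$a2)
    sel <- match(want, pk)
    if (anyNA(sel)) {
      stop("variant(s) absent from panel: ",
           paste(utils::head(want[is.na(sel)], 5), collapse = ", "))
    }
  }
  dos <- panel$dosages[, sel, drop = FALSE]
  eff <- if (is.null(effect_alleles)) keys$a1 else effect_alleles
  flip <- pv$a1[sel] != eff
  if (any(flip)) dos[, flip] <- 2 - dos[, flip]
  v <- apply(dos, 2, stats::var)
  mono <- v <= 0 | !is.finite(v)
  if (any(mono)) {
    warning(sprintf("excluded %d monomorphic variant(s) from LD matrix", sum(mono)),
            call. = FALSE)
    dos <- dos[, !mono, drop = FALSE]
    keys <- keys[!mono, , drop = FALSE]
    eff <- eff[!mono]
  }
  r <- stats::cor(dos)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  # when orientation flipped, the other allele is the panel's counted allele
  out <- data.frame(chrom = as.character(keys$chrom), pos = keys$pos,
                    a1 = eff,
                    a2 = ifelse(eff == keys$a1, keys$a2, keys$a1),
                    stringsAsFactors = FALSE)
  dimnames(r) <- rep(list(variant_key(out$chrom, out$pos, out$a1, out$a2)), 2)
  structure(list(variants = out, r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d variants\n", nrow(x$r)))
  invisible(x)
}

#' Serialize an LD matrix as TSV (variant-key header row)
#' @param x An `ld_matrix`. @param path Output path.
#' @return `path` invisibly.
#' @export
write_ld <- function(x, path) {
  df <- data.frame(key = rownames(x$r), as.data.frame(x$r, optional = TRUE),
                   check.names = FALSE)
  write_tsv_precise(df, path)
}

#' Read an LD matrix written by [write_ld()]
#' @param path TSV path.
#' @return An `ld_matrix` (variant annotation reparsed from keys).
#' @export
read_ld <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  key <- dt$key
  r <- as.matrix(dt[, -1])
  dimnames(r) <- list(key, key)
  parts <- do.call(rbind, strsplit(key, ":", fixed = TRUE))
  structure(list(variants = data.frame(chrom = parts[, 1],
                                       pos = as.numeric(parts[, 2]),
                                       a1 = parts[, 3], a2 = parts[, 4],
                                       stringsAsFactors = FALSE),
                 r = r),
            class = "ld_matrix")
}
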