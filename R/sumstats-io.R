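VALID_ALLELES <- c("A", "C", "G", "T")

#' Order-free variant match key
#'
#' Variant identity is chromosome, position and the unordered allele pair;
#' rsIDs are carried as annotation only.
#'
#' @param chrom,pos,a1,a2 Vectors describing variants.
#' @return Character keys `chrom:pos:min-max`.
#' @keywords internal
variant_match_key <- function(chrom, pos, a1, a2) {
  paste0(chrom, ":", pos, ":", pmin(a1, a2), "-", pmax(a1, a2))
}

# Oriented key: effect allele order matters.
variant_key <- function(chrom, pos, a1, a2) {
  paste0(chrom, ":", pos, ":", a1, ":", a2)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct a per-protein cis-region summary-statistics set
#'
#' Validates association records for one protein and one chromosome: alleles
#' are upper-cased and must be distinct single bases, `se > 0`, `p` in (0, 1],
#' `eaf` in (0, 1). Rows with missing `beta`, `se` or `eaf` are dropped with a
#' logged count; rows violating hard invariants are rejected with a warning.
#' Duplicate variants (same position and allele pair) are an error. Records
#' whose `|beta/se|` is grossly inconsistent with `p` under the two-sided
#' normal approximation trigger a warning, not a failure.
#'
#' @param records Data frame with columns `chrom`, `pos`, `a1` (effect
#'   allele), `a2`, `eaf`, `beta`, `se`, `p`, `n`, optionally `id` (rsID
#'   annotation).
#' @param protein_id Protein/gene identifier.
#' @param gene_start,gene_end 1-based inclusive gene-body coordinates.
#' @return An object of class `locus_sumstats`: list with `protein_id`,
#'   `chrom`, `gene_start`, `gene_end` and a position-sorted `records` data
#'   frame.
#' @export
locus_sumstats <- function(records, protein_id = NA_character_,
                           gene_start = NA_real_, gene_end = NA_real_) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "pos", "a1", "a2", "eaf", "beta", "se", "p", "n")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"id" %in% names(rec)) rec$id <- rep(NA_character_, nrow(rec))
  rec <- rec[c(need, "id")]
  rec$chrom <- as.character(rec$chrom)
  rec$a1 <- toupper(rec$a1)
  rec$a2 <- toupper(rec$a2)
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    rec[[col]] <- as.numeric(rec[[col]])
  }

  incomplete <- !is.finite(rec$beta) | !is.finite(rec$se) | !is.finite(rec$eaf)
  if (any(incomplete)) {
    pqtlx_log("dropped %d record(s) with missing beta/se/eaf", sum(incomplete))
    rec <- rec[!incomplete, , drop = FALSE]
  }
  # p-values underflow to 0 for very strong associations; clamp to the
  # smallest positive double rather than rejecting the record
  und <- is.finite(rec$p) & rec$p == 0
  if (any(und)) {
    pqtlx_log("clamped %d underflowed p-value(s)", sum(und), level = 2L)
    rec$p[und] <- .Machine$double.xmin
  }
  bad <- !(rec$a1 %in% VALID_ALLELES) | !(rec$a2 %in% VALID_ALLELES) |
    rec$a1 == rec$a2 | rec$pos < 1 | rec$se <= 0 |
    !is.finite(rec$p) | rec$p <= 0 | rec$p > 1 |
    rec$eaf <= 0 | rec$eaf >= 1
  if (any(bad)) {
    warning(sprintf("rejected %d invalid record(s)", sum(bad)), call. = FALSE)
    rec <- rec[!bad, , drop = FALSE]
  }
  if (nrow(rec) > 0 && length(unique(rec$chrom)) > 1L) {
    stop("records span multiple chromosomes: ",
         paste(unique(rec$chrom), collapse = ", "))
  }
  mk <- variant_match_key(rec$chrom, rec$pos, rec$a1, rec$a2)
  if (anyDuplicated(mk)) {
    stop("duplicate variant keys: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "))
  }
  if (nrow(rec) > 0) {
    z <- abs(rec$beta / rec$se)
    p_z <- 2 * stats::pnorm(-z)
    off <- abs(log(pmax(rec$p, 1e-300)) - log(pmax(p_z, 1e-300))) > 1 &
      abs(rec$p - p_z) > 0.01
    if (any(off)) {
      warning(sprintf("%d record(s): p inconsistent with beta/se (normal approx)",
                      sum(off)), call. = FALSE)
    }
  }
  rec <- rec[order(rec$pos, rec$a1, rec$a2), , drop = FALSE]
  rownames(rec) <- NULL
  structure(
    list(protein_id = protein_id,
         chrom = if (nrow(rec)) rec$chrom[1] else NA_character_,
         gene_start = gene_start, gene_end = gene_end, records = rec),
    class = "locus_sumstats")
}

#' @export
print.locus_sumstats <- function(x, ...) {
  cat(sprintf("locus_sumstats: %s (%s), %d variants, gene [%s, %s]\n",
              x$protein_id, x$chrom %||% NA, nrow(x$records),
              format(x$gene_start), format(x$gene_end)))
  invisible(x)
}

default_column_map <- function() {
  c(chrom = "CHR", pos = "POS", a1 = "A1", a2 = "A2", eaf = "EAF",
    beta = "BETA", se = "SE", p = "P", n = "N")
}

#' Read GWAS summary statistics for one cis region
#'
#' @param path Tab-delimited file with a header row.
#' @param column_map Named character vector mapping internal names
#'   (`chrom`, `pos`, `a1`, `a2`, `eaf`, `beta`, `se`, `p`, `n`) to file
#'   column names; defaults to `CHR`/`POS`/`A1`/`A2`/`EAF`/`BETA`/`SE`/`P`/`N`.
#' @param protein_id,gene_start,gene_end Locus annotation (see
#'   [locus_sumstats()]).
#' @return A `locus_sumstats` object.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          protein_id = NA_character_,
                          gene_start = NA_real_, gene_end = NA_real_) {
  if (!file.exists(path)) stop("cannot read summary statistics: ", path)
  cmap <- default_column_map()
  cmap[names(column_map)] <- column_map
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = unname(cmap[c("chrom", "a1", "a2")])))
  missing_cols <- setdiff(unname(cmap), names(dt))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from file: ", paste(missing_cols, collapse = ", "))
  }
  rec <- as.data.frame(dt)[, unname(cmap)]
  names(rec) <- names(cmap)
  if ("ID" %in% names(dt)) rec$id <- as.character(dt$ID)
  locus_sumstats(rec, protein_id = protein_id,
                 gene_start = gene_start, gene_end = gene_end)
}

#' Write summary statistics in the same tab-delimited dialect
#'
#' Numerics are written with 17 significant digits so write/read round trips
#' are exact to better than 1e-12 relative.
#'
#' @param x A `locus_sumstats` object.
#' @param path Output path.
#' @param column_map As in [read_sumstats()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, column_map = default_column_map()) {
  stopifnot(inherits(x, "locus_sumstats"))
  cmap <- default_column_map()
  cmap[names(column_map)] <- column_map
  out <- x$records[names(cmap)]
  names(out) <- unname(cmap)
  if (!all(is.na(x$records$id))) out$ID <- x$records$id
  write_tsv_precise(out, path)
}

#' Read gene coordinates from a BED-like file
#'
#' Four columns (chrom, start, end, gene_id), BED half-open zero-based on
#' disk; converted to 1-based inclusive coordinates.
#'
#' @param path BED file path.
#' @return Data frame with `chrom`, `gene_start`, `gene_end`, `gene_id`
#'   (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "gene_id"))
  data.frame(chrom = as.character(bed$chrom),
             gene_start = bed$start + 1,
             gene_end = bed$end,
             gene_id = as.character(bed$gene_id),
             stringsAsFactors = FALSE)
}

#' Restrict to the cis window around the gene
#'
#' Retains variants with position in `[gene_start - window, gene_end +
#' window]`, boundaries inclusive. With `anchor = "tss"` the window is
#' anchored at the gene start instead of the gene body.
#'
#' @param stats A `locus_sumstats` with gene coordinates set.
#' @param window Cis window in base pairs (default 500000).
#' @param anchor `"gene"` (gene-body, default) or `"tss"`.
#' @return Filtered `locus_sumstats`.
#' @export
filter_cis <- function(stats, window = 500000, anchor = c("gene", "tss")) {
  stopifnot(inherits(stats, "locus_sumstats"))
  anchor <- match.arg(anchor)
  if (!is.finite(stats$gene_start) || !is.finite(stats$gene_end)) {
    stop("gene coordinates not set; cannot apply cis filter")
  }
  lo <- stats$gene_start - window
  hi <- if (anchor == "gene") stats$gene_end + window else stats$gene_start + window
  keep <- stats$records$pos >= lo & stats$records$pos <= hi
  pqtlx_log("cis filter (%s-anchored, %g bp): kept %d / %d", anchor, window,
            sum(keep), length(keep), level = 2L)
  stats$records <- stats$records[keep, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

#' Minor-allele-frequency QC filter
#'
#' Retains records with `min(eaf, 1 - eaf) > maf_min` (strict inequality).
#'
#' @param stats A `locus_sumstats` object.
#' @param maf_min MAF threshold (default 0.05).
#' @return Filtered `locus_sumstats`.
#' @export
apply_qc <- function(stats, maf_min = 0.05) {
  stopifnot(inherits(stats, "locus_sumstats"))
  maf <- pmin(stats$records$eaf, 1 - stats$records$eaf)
  keep <- maf > maf_min
  pqtlx_log("MAF filter (> %g): kept %d / %d", maf_min, sum(keep), length(keep),
            level = 2L)
  stats$records <- stats$records[keep, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

#' Harmonize two summary-statistics sets to one variant universe
#'
#' Intersects on variant identity (position plus unordered allele pair),
#' allowing allele-swap matches: where the second set's alleles are swapped
#' relative to the first, its beta is negated and its effect-allele frequency
#' replaced by `1 - eaf`. Palindromic variants (A/T, C/G) are oriented by
#' allele frequency when the minor-allele frequency is at most
#' `palindrome_maf_max` in both sets, and dropped otherwise (frequency cannot
#' resolve strand near 0.5). Incompatible allele pairs are dropped and logged.
#'
#' @param a,b `locus_sumstats` objects on the same chromosome.
#' @param palindrome_maf_max MAF bound for frequency-based orientation of
#'   palindromic variants (default 0.40).
#' @return List with elements `a` and `b`: index-aligned `locus_sumstats`
#'   sharing identical `chrom`, `pos`, `a1`, `a2` per row.
#' @export
harmonize_pair <- function(a, b, palindrome_maf_max = 0.40) {
  stopifnot(inherits(a, "locus_sumstats"), inherits(b, "locus_sumstats"))
  if (nrow(a$records) && nrow(b$records) && !identical(a$chrom, b$chrom)) {
    stop("cannot harmonize across chromosomes: ", a$chrom, " vs ", b$chrom)
  }
  ra <- a$records; rb <- b$records
  ka <- variant_match_key(ra$chrom, ra$pos, ra$a1, ra$a2)
  kb <- variant_match_key(rb$chrom, rb$pos, rb$a1, rb$a2)
  idx <- match(ka, kb)
  keep <- !is.na(idx)
  n_unmatched <- sum(!keep)
  ra <- ra[keep, , drop = FALSE]
  rb <- rb[idx[keep], , drop = FALSE]

  same <- rb$a1 == ra$a1 & rb$a2 == ra$a2
  swapped <- rb$a1 == ra$a2 & rb$a2 == ra$a1
  pal <- is_palindromic(ra$a1, ra$a2)

  flip <- swapped & !pal
  drop <- !(same | swapped)                       # incompatible allele pair
  if (any(pal)) {
    maf_a <- pmin(ra$eaf, 1 - ra$eaf)
    maf_b <- pmin(rb$eaf, 1 - rb$eaf)
    ambiguous <- pal & (maf_a > palindrome_maf_max | maf_b > palindrome_maf_max)
    drop <- drop | ambiguous
    # Orient resolvable palindromes by frequency proximity: flip when 1 - eaf_b
    # is closer to eaf_a than eaf_b is (ties keep the as-is orientation).
    res <- pal & !ambiguous
    flip[res] <- abs(ra$eaf[res] - rb$eaf[res]) >
      abs(ra$eaf[res] - (1 - rb$eaf[res]))
  }
  if (n_unmatched || any(drop)) {
    pqtlx_log("harmonization: %d unmatched, %d dropped (incompatible or ambiguous palindrome), %d flipped",
              n_unmatched, sum(drop), sum(flip & !drop))
  }
  ra <- ra[!drop, , drop = FALSE]
  rb <- rb[!drop, , drop = FALSE]
  flip <- flip[!drop]
  rb$beta[flip] <- -rb$beta[flip]
  rb$eaf[flip] <- 1 - rb$eaf[flip]
  rb$a1 <- ra$a1
  rb$a2 <- ra$a2
  rownames(ra) <- rownames(rb) <- NULL
  a$records <- ra
  b$records <- rb
  list(a = a, b = b)
}

#' Locus eligibility for colocalization testing
#'
#' A locus is tested only when both traits carry a genome-wide significant
#' association (`min p < p_thresh`, strict), so that absence of
#' colocalization reflects distinct signals rather than lack of power.
#'
#' @param a,b Harmonized `locus_sumstats` objects.
#' @param p_thresh Significance threshold (default 5e-8).
#' @return Logical.
#' @export
locus_eligible <- function(a, b, p_thresh = 5e-8) {
  if (nrow(a$records) == 0L || nrow(b$records) == 0L) return(FALSE)
  min(a$records$p) < p_thresh && min(b$records$p) < p_thresh
}
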