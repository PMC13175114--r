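# Independent oracles and small fixture builders used across tests. These
# deliberately re-derive quantities from first principles (explicit loops,
# direct enumeration) rather than calling the package's own code paths.

# Brute-force single-causal-variant colocalization enumeration from marginal
# statistics: per-variant ABFs on the standardized scale, hypothesis sums by
# explicit (double) loops over variants in log space.
oracle_single_coloc <- function(beta_a, se_a, n_a, beta_b, se_b, n_b,
                                p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.0225) {
  labf <- function(beta, se, n) {
    b <- (beta / se) / sqrt(n)       # standardized effect
    s2 <- 1 / n
    0.5 * log(s2 / (s2 + W)) + (b^2 / s2) / 2 * (W / (s2 + W))
  }
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }
  A <- labf(beta_a, se_a, n_a)
  B <- labf(beta_b, se_b, n_b)
  m <- length(A)
  l1 <- lse(A)
  l2 <- lse(B)
  l12 <- lse(A + B)
  # H3: sum over ordered pairs j != k of A_j * B_k
  cross_terms <- as.vector(outer(A, B, "+"))
  keep <- as.vector(outer(seq_len(m), seq_len(m), "!="))
  lcross <- if (any(keep)) lse(cross_terms[keep]) else -Inf
  lw <- c(0, log(p1) + l1, log(p2) + l2,
          log(p1) + log(p2) + lcross, log(p12) + l12)
  pp <- exp(lw - lse(lw))
  names(pp) <- paste0("PP", 0:4)
  pp
}

# Build a locus_sumstats directly from a record table (bypassing files).
make_stats <- function(pos, beta, se, eaf = 0.3, p = NULL, n = 10000,
                       a1 = "A", a2 = "G", chrom = "1", protein_id = "P",
                       gene_start = if (length(pos)) min(pos) else NA_real_,
                       gene_end = if (length(pos)) max(pos) else NA_real_) {
  m <- length(pos)
  if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
  locus_sumstats(
    data.frame(chrom = rep_len(chrom, m), pos = pos,
               a1 = rep_len(a1, m), a2 = rep_len(a2, m),
               eaf = rep_len(eaf, m), beta = beta, se = se, p = p,
               n = rep_len(n, m), stringsAsFactors = FALSE),
    protein_id = protein_id, gene_start = gene_start, gene_end = gene_end)
}

# Harmonize+QC+LD+colocalize one simulated locus; returns NULL when the
# locus is not eligible for testing.
coloc_one <- function(loc, K = 10, ...) {
  h <- harmonize_pair(apply_qc(filter_cis(loc$a)), apply_qc(filter_cis(loc$b)))
  if (!locus_eligible(h$a, h$b)) return(NULL)
  ld <- compute_ld(loc$panel, keys = h$a$records[c("chrom", "pos", "a1", "a2")])
  list(result = colocalize_locus(h$a, h$b, ld, K = K, ...),
       h = h, ld = ld, panel = loc$panel)
}

# Identity LD matrix for hand-built loci (variants treated as independent).
identity_ld <- function(stats) {
  rec <- stats$records
  m <- nrow(rec)
  r <- diag(m)
  dimnames(r) <- rep(list(paste0(rec$chrom, ":", rec$pos, ":", rec$a1, ":",
                                 rec$a2)), 2)
  structure(list(variants = rec[c("chrom", "pos", "a1", "a2")], r = r),
            class = "ld_matrix")
}
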