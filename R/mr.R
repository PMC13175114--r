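# Two-sample Mendelian randomization using colocalized credible-set lead
# variants as instruments: Wald ratio for a single instrument, fixed-effect
# inverse-variance weighting for two or more.

Z975 <- stats::qnorm(0.975)   # 1.959964

#' Select MR instruments from colocalization results
#'
#' One instrument per colocalized signal pair (PP4 above the colocalization
#' threshold): the pair's lead variant (shared-hypothesis PIP argmax).
#' Variant-to-protein effects are looked up in each tissue's harmonized
#' summary statistics; variant-to-outcome effects in the outcome GWAS, with
#' allele-swap harmonization (beta negated where the outcome's alleles are
#' swapped). Instruments absent from the outcome GWAS are dropped with a
#' logged reason; proteins with no colocalized pair are excluded entirely.
#' When a protein has two or more instruments and an LD panel is supplied,
#' pairwise independence (r-squared below `r2_max`) is asserted — a
#' violation is an error, not a silent prune.
#'
#' @param results Named list of `locus_coloc_result` (one per protein).
#' @param stats_a,stats_b Named lists of harmonized `locus_sumstats` for the
#'   two pQTL tissues (same names as `results`).
#' @param outcome A `locus_sumstats`-like object (or named list, keyed like
#'   `results`) with outcome GWAS records for the loci.
#' @param panel Optional `genotype_panel` for the independence assertion.
#' @param r2_max Maximum pairwise instrument r-squared (default 0.01).
#' @param coloc_threshold PP4 threshold defining colocalized pairs
#'   (default 0.8, strict).
#' @return Data frame of instruments: `protein_id`, `key`, `chrom`, `pos`,
#'   `a1`, `a2`, `beta_a`, `se_a`, `beta_b`, `se_b`, `beta_y`, `se_y`.
#' @export
select_instruments <- function(results, stats_a, stats_b, outcome,
                               panel = NULL, r2_max = 0.01,
                               coloc_threshold = 0.8) {
  rows <- list()
  for (pid in names(results)) {
    res <- results[[pid]]
    if (!isTRUE(res$colocalized)) next
    pairs <- Filter(function(p) p$pp[["PP4"]] > coloc_threshold, res$pairs)
    if (length(pairs) == 0L) next
    sa <- stats_a[[pid]]$records
    sb <- stats_b[[pid]]$records
    out_rec <- if (inherits(outcome, "locus_sumstats")) outcome$records
               else outcome[[pid]]$records
    ka <- variant_match_key(sa$chrom, sa$pos, sa$a1, sa$a2)
    ko <- variant_match_key(out_rec$chrom, out_rec$pos, out_rec$a1, out_rec$a2)
    for (p in pairs) {
      ia <- match(p$lead_key, ka)
      if (is.na(ia)) {
        pqtlx_log("%s: lead %s missing from exposure statistics; instrument dropped",
                  pid, p$lead_key)
        next
      }
      io <- match(ka[ia], ko)
      if (is.na(io)) {
        pqtlx_log("%s: lead %s absent from outcome GWAS; instrument dropped",
                  pid, p$lead_key)
        next
      }
      same <- out_rec$a1[io] == sa$a1[ia] && out_rec$a2[io] == sa$a2[ia]
      swap <- out_rec$a1[io] == sa$a2[ia] && out_rec$a2[io] == sa$a1[ia]
      if (!same && !swap) {
        pqtlx_log("%s: allele mismatch with outcome at %s; instrument dropped",
                  pid, p$lead_key)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, key = p$lead_key,
        chrom = sa$chrom[ia], pos = sa$pos[ia],
        a1 = sa$a1[ia], a2 = sa$a2[ia],
        beta_a = sa$beta[ia], se_a = sa$se[ia],
        beta_b = sb$beta[ia], se_b = sb$se[ia],
        beta_y = if (swap) -out_rec$beta[io] else out_rec$beta[io],
        se_y = out_rec$se[io],
        stringsAsFactors = FALSE)
    }
  }
  inst <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), key = character(),
               chrom = character(), pos = numeric(),
               a1 = character(), a2 = character(),
               beta_a = numeric(), se_a = numeric(),
               beta_b = numeric(), se_b = numeric(),
               beta_y = numeric(), se_y = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(panel) && nrow(inst)) {
    for (pid in unique(inst$protein_id)) {
      sub <- inst[inst$protein_id == pid, , drop = FALSE]
      if (nrow(sub) < 2L) next
      ld <- compute_ld(panel, keys = sub[c("chrom", "pos", "a1", "a2")])
      r2 <- ld$r^2
      diag(r2) <- 0
      if (max(r2) >= r2_max) {
        stop(sprintf("instruments for %s are not independent (max r^2 = %.3g >= %.3g)",
                     pid, max(r2), r2_max))
      }
    }
  }
  inst
}

mr_result_row <- function(protein_id, tissue_source, n_instruments, method,
                          estimate, se, alpha) {
  p <- 2 * stats::pnorm(-abs(estimate / se))
  if (estimate == 0) p <- 1
  data.frame(protein_id = protein_id, tissue_source = tissue_source,
             n_instruments = n_instruments, method = method,
             estimate = estimate, se = se,
             ci95_lo = estimate - Z975 * se, ci95_hi = estimate + Z975 * se,
             p = p, significant = p < alpha, stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single instrument
#'
#' `estimate = beta_y / beta_x`; first-order delta-method standard error
#' `se = se_y / |beta_x|` (the exposure-side uncertainty is ignored, the
#' dominant convention in two-sample MR; a second-order SE including
#' `se_x` is available via `second_order = TRUE`). Two-sided normal p-value.
#'
#' @param beta_x,se_x Variant-to-exposure effect and SE (`beta_x != 0`).
#' @param beta_y,se_y Variant-to-outcome effect and SE.
#' @param alpha Significance threshold (default 1e-5, strict).
#' @param second_order Include the second-order delta term in the SE.
#' @return One-row data frame (see [run_mr()] for columns).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, alpha = 1e-5,
                       second_order = FALSE) {
  if (!is.finite(beta_x) || beta_x == 0) stop("Wald ratio undefined for beta_x = 0")
  if (se_y <= 0) stop("se_y must be positive")
  est <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  mr_result_row(NA_character_, NA_character_, 1L, "wald", est, se, alpha)
}

#' Fixed-effect inverse-variance weighted estimate
#'
#' Combines two or more Wald ratios with weights `w_i = se_i^-2`:
#' `estimate = sum(w theta) / sum(w)`, `se = sum(w)^-0.5`.
#'
#' @param estimates Per-instrument Wald ratio estimates (length >= 2).
#' @param ses Matching standard errors.
#' @param alpha Significance threshold (default 1e-5).
#' @return One-row data frame (see [run_mr()]).
#' @export
ivw <- function(estimates, ses, alpha = 1e-5) {
  if (length(estimates) < 2L) stop("IVW requires at least 2 instruments")
  if (length(ses) != length(estimates)) stop("estimates/ses length mismatch")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_result_row(NA_character_, NA_character_, length(estimates), "ivw",
                est, se, alpha)
}

#' Run MR for every protein and both tissue sources
#'
#' Dispatches by instrument count (1 instrument: Wald ratio; 2 or more:
#' fixed-effect IVW of per-instrument Wald ratios) separately for the two
#' exposure sources (tissue `a` = plasma-like, tissue `b` = brain-like, each
#' using its own `beta_x` at the shared lead variants). A per-protein
#' cross-tissue direction flag records whether the two sources' estimates
#' agree in sign.
#'
#' @param instruments Instrument data frame from [select_instruments()].
#' @param alpha Significance threshold (default 1e-5, strict).
#' @return Data frame with one row per protein and tissue source:
#'   `protein_id`, `tissue_source`, `n_instruments`, `method`, `estimate`,
#'   `se`, `ci95_lo`, `ci95_hi`, `p`, `significant`,
#'   `direction_concordant`.
#' @export
run_mr <- function(instruments, alpha = 1e-5) {
  out <- list()
  for (pid in unique(instruments$protein_id)) {
    sub <- instruments[instruments$protein_id == pid, , drop = FALSE]
    per_source <- lapply(c(a = "a", b = "b"), function(src) {
      bx <- sub[[paste0("beta_", src)]]
      sx <- sub[[paste0("se_", src)]]
      ok <- is.finite(bx) & bx != 0
      if (!any(ok)) return(NULL)
      wr <- mapply(function(b, s, by, sy) {
        r <- wald_ratio(b, s, by, sy, alpha = alpha)
        c(r$estimate, r$se)
      }, bx[ok], sx[ok], sub$beta_y[ok], sub$se_y[ok])
      res <- if (sum(ok) == 1L) {
        wald_ratio(bx[ok], sx[ok], sub$beta_y[ok], sub$se_y[ok], alpha = alpha)
      } else {
        ivw(wr[1, ], wr[2, ], alpha = alpha)
      }
      res$protein_id <- pid
      res$tissue_source <- src
      res
    })
    per_source <- Filter(Negate(is.null), per_source)
    if (length(per_source) == 0L) next
    block <- do.call(rbind, per_source)
    block$direction_concordant <- if (nrow(block) == 2L) {
      sign(block$estimate[1]) == sign(block$estimate[2])
    } else NA
    out[[pid]] <- block
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(), tissue_source = character(),
                      n_instruments = integer(), method = character(),
                      estimate = numeric(), se = numeric(),
                      ci95_lo = numeric(), ci95_hi = numeric(),
                      p = numeric(), significant = logical(),
                      direction_concordant = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
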