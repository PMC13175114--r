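# Dichotomized-Gaussian genotype simulator: block-wise AR(1) latent
# correlation gives exact control of LD structure and MAF at desk scale.

#' Define a locus simulation scenario
#'
#' Encodes the qualitative cross-tissue configurations the pipeline must
#' distinguish: `SHARED_CONCORDANT` (one causal variant shared by both
#' tissues, same effect sign), `SHARED_DISCORDANT` (shared variant, opposite
#' signs), `DISTINCT` (one causal variant per tissue in separate LD blocks,
#' r-squared below 0.1), `A_ONLY` (causal variant in tissue A only), `NULL`
#' (no causal variant). Default sample sizes echo the power asymmetry between
#' a large plasma cohort and a small brain cohort.
#'
#' @param label One of `SHARED_CONCORDANT`, `SHARED_DISCORDANT`, `DISTINCT`,
#'   `A_ONLY`, `NULL`.
#' @param m_variants Number of variants at the locus (default 100).
#' @param n_blocks Number of independent LD blocks (default 5).
#' @param rho Within-block AR(1) latent correlation in \[0, 0.99\]
#'   (default 0.9).
#' @param maf_range Range minor-allele frequencies are drawn from
#'   (default \[0.05, 0.5\]).
#' @param h2_signal Variance in the protein explained per causal signal,
#'   in (0, 0.5) (default 0.05).
#' @param n_a,n_b Per-tissue GWAS sample sizes (defaults 35000 and 1000).
#' @param theta Protein-to-outcome causal effect (default 0).
#' @param n_outcome Outcome GWAS sample size (default 100000).
#' @param n_panel LD reference panel size (default 5000).
#' @param chrom Chromosome label.
#' @param pos_start,pos_spacing Base-pair layout of the variants.
#' @param seed Integer seed; every draw downstream is a pure function of it.
#' @return Object of class `locus_scenario`.
#' @export
locus_scenario <- function(label = c("SHARED_CONCORDANT", "SHARED_DISCORDANT",
                                     "DISTINCT", "A_ONLY", "NULL"),
                           m_variants = 100, n_blocks = 5, rho = 0.9,
                           maf_range = c(0.05, 0.5), h2_signal = 0.05,
                           n_a = 35000, n_b = 1000,
                           theta = 0, n_outcome = 100000, n_panel = 5000,
                           chrom = "1", pos_start = 1e6, pos_spacing = 1000,
                           seed = 1) {
  label <- match.arg(label)
  stopifnot(h2_signal > 0, h2_signal < 0.5, rho >= 0, rho <= 0.99,
            m_variants >= 1, n_blocks >= 1, n_blocks <= m_variants,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(label = label, m_variants = m_variants, n_blocks = n_blocks,
                 rho = rho, maf_range = maf_range, h2_signal = h2_signal,
                 n_a = n_a, n_b = n_b, theta = theta, n_outcome = n_outcome,
                 n_panel = n_panel, chrom = chrom, pos_start = pos_start,
                 pos_spacing = pos_spacing, seed = as.integer(seed)),
            class = "locus_scenario")
}

# Locus blueprint: everything shared across cohorts drawn once from the
# scenario seed — variant layout, alleles, MAFs, block membership, causal
# variant choice and signed effects, gene coordinates.
locus_blueprint <- function(scenario) {
  stopifnot(inherits(scenario, "locus_scenario"))
  sc <- scenario
  with_seed(fork_seed(sc$seed, 1L), {
    m <- sc$m_variants
    pos <- sc$pos_start + (seq_len(m) - 1L) * sc$pos_spacing
    pairs <- t(utils::combn(VALID_ALLELES, 2))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
    a1 <- ifelse(swap, pairs[pick, 2], pairs[pick, 1])
    a2 <- ifelse(swap, pairs[pick, 1], pairs[pick, 2])
    maf <- stats::runif(m, sc$maf_range[1], sc$maf_range[2])
    blocks <- sort(rep_len(seq_len(sc$n_blocks), m))

    h2 <- sc$h2_signal
    eff <- sqrt(h2)
    sgn <- sample(c(-1, 1), 2, replace = TRUE)
    mid_block <- which(blocks == ((sc$n_blocks + 1L) %/% 2L))
    causal_a <- integer(0); causal_b <- integer(0)
    beta_a <- numeric(0); beta_b <- numeric(0)
    if (sc$label %in% c("SHARED_CONCORDANT", "SHARED_DISCORDANT")) {
      cv <- sample(mid_block, 1)
      causal_a <- cv; beta_a <- sgn[1] * eff
      causal_b <- cv
      beta_b <- if (sc$label == "SHARED_CONCORDANT") beta_a else -beta_a
    } else if (sc$label == "DISTINCT") {
      bl <- sample(unique(blocks), 2)
      causal_a <- sample(which(blocks == bl[1]), 1)
      causal_b <- sample(which(blocks == bl[2]), 1)
      beta_a <- sgn[1] * eff
      beta_b <- sgn[2] * eff
    } else if (sc$label == "A_ONLY") {
      causal_a <- sample(mid_block, 1)
      beta_a <- sgn[1] * eff
    }
    gene_mid <- pos[(m + 1L) %/% 2L]
    list(scenario = sc, pos = pos, a1 = a1, a2 = a2, maf = maf,
         blocks = blocks,
         causal_a = causal_a, beta_a = beta_a,
         causal_b = causal_b, beta_b = beta_b,
         gene_start = max(1, gene_mid - 5000), gene_end = gene_mid + 5000)
  })
}

# Core dosage draw: two independent haplotypes from a blockwise AR(1)
# latent Gaussian, dichotomized at the MAF quantile.
draw_dosages <- function(n, maf, blocks, rho, seed) {
  with_seed(seed, {
    m <- length(maf)
    th <- stats::qnorm(maf)
    hap <- function() {
      Z <- matrix(stats::rnorm(n * m), n, m)
      if (rho > 0) {
        sq <- sqrt(1 - rho^2)
        for (blk in split(seq_len(m), blocks)) {
          if (length(blk) < 2L) next
          for (j in blk[-1]) Z[, j] <- rho * Z[, j - 1L] + sq * Z[, j]
        }
      }
      Z < rep(th, each = n)
    }
    d <- hap() + hap()
    storage.mode(d) <- "double"
    d
  })
}

#' Simulate an LD reference genotype panel
#'
#' Dichotomized-Gaussian dosages: a latent Gaussian with within-block AR(1)
#' correlation `rho` is drawn twice (two haplotypes) and thresholded at the
#' MAF quantile; the dosage is the sum. MAFs are drawn uniformly from the
#' scenario's `maf_range`. Fixed seeds give bit-identical panels.
#'
#' @param n Number of samples (defaults to the scenario's `n_panel`).
#' @param scenario A `locus_scenario`.
#' @param blueprint Optional precomputed internal blueprint (shared layout
#'   across cohorts); derived from `scenario` when absent.
#' @param stream Integer RNG stream index separating cohorts.
#' @return A `genotype_panel`.
#' @export
simulate_genotypes <- function(n = NULL, scenario, blueprint = NULL,
                               stream = 2L) {
  bp <- blueprint %||% locus_blueprint(scenario)
  sc <- bp$scenario
  n <- n %||% sc$n_panel
  d <- draw_dosages(n, bp$maf, bp$blocks, sc$rho, fork_seed(sc$seed, stream))
  genotype_panel(d, data.frame(chrom = sc$chrom, pos = bp$pos,
                               a1 = bp$a1, a2 = bp$a2,
                               stringsAsFactors = FALSE))
}

# Marginal OLS of y on each standardized dosage column; returns beta, se, p
# (two-sided normal), eaf, n.
marginal_ols <- function(dos, y) {
  n <- nrow(dos)
  xc <- sweep(dos, 2, colMeans(dos), "-")
  sx <- sqrt(colSums(xc^2) / (n - 1))
  if (any(sx == 0)) stop("monomorphic variant in simulated cohort")
  xs <- sweep(xc, 2, sx, "/")
  yc <- y - mean(y)
  sxx <- n - 1
  bhat <- as.vector(crossprod(xs, yc)) / sxx
  sse <- pmax(sum(yc^2) - bhat^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  z <- bhat / se
  list(beta = bhat, se = se,
       p = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
       eaf = colMeans(dos) / 2, n = n)
}

# Protein value given dosages and the blueprint's causal model for one
# tissue; each signal explains h2_signal of the variance.
protein_value <- function(dos, causal, beta, seed) {
  n <- nrow(dos)
  g <- rep(0, n)
  for (i in seq_along(causal)) {
    x <- dos[, causal[i]]
    g <- g + beta[i] * (x - mean(x)) / stats::sd(x)
  }
  noise_sd <- sqrt(max(1 - sum(beta^2), 1e-6))
  with_seed(seed, g + stats::rnorm(n, sd = noise_sd))
}

sumstats_from_cohort <- function(dos, y, bp, protein_id) {
  sc <- bp$scenario
  ols <- marginal_ols(dos, y)
  locus_sumstats(
    data.frame(chrom = sc$chrom, pos = bp$pos, a1 = bp$a1, a2 = bp$a2,
               eaf = ols$eaf, beta = ols$beta, se = ols$se, p = ols$p,
               n = ols$n, stringsAsFactors = FALSE),
    protein_id = protein_id,
    gene_start = bp$gene_start, gene_end = bp$gene_end)
}

#' Simulate a two-tissue cis-pQTL locus with known truth
#'
#' Draws independent cohorts for tissues A and B plus an LD reference panel
#' from one shared locus blueprint. The protein phenotype in each tissue is
#' the sum of signed causal effects on standardized dosages plus Gaussian
#' noise scaled so each signal explains `h2_signal` of the variance;
#' per-variant marginal OLS yields the summary statistics. For `DISTINCT`
#' loci the two causal variants are redrawn (up to 100 times) until their
#' panel r-squared is below 0.1.
#'
#' @param scenario A `locus_scenario`.
#' @param protein_id Identifier stored on the outputs.
#' @return List with `a`, `b` (`locus_sumstats`), `panel`
#'   (`genotype_panel`), and `truth` (causal variant keys, signed effects,
#'   scenario label, theta).
#' @export
simulate_locus <- function(scenario, protein_id = "protein") {
  bp <- locus_blueprint(scenario)
  sc <- bp$scenario
  panel <- simulate_genotypes(sc$n_panel, scenario, blueprint = bp, stream = 2L)
  if (sc$label == "DISTINCT") {
    tries <- 0L
    repeat {
      r <- stats::cor(panel$dosages[, bp$causal_a], panel$dosages[, bp$causal_b])
      if (r^2 < 0.1) break
      tries <- tries + 1L
      if (tries > 100L) stop("could not place DISTINCT causal pair at r^2 < 0.1")
      idx <- with_seed(fork_seed(sc$seed, 10L, tries), {
        bl <- sample(unique(bp$blocks), 2)
        c(sample(which(bp$blocks == bl[1]), 1),
          sample(which(bp$blocks == bl[2]), 1))
      })
      bp$causal_a <- idx[1]
      bp$causal_b <- idx[2]
    }
  }
  dos_a <- draw_dosages(sc$n_a, bp$maf, bp$blocks, sc$rho, fork_seed(sc$seed, 3L))
  dos_b <- draw_dosages(sc$n_b, bp$maf, bp$blocks, sc$rho, fork_seed(sc$seed, 4L))
  y_a <- protein_value(dos_a, bp$causal_a, bp$beta_a, fork_seed(sc$seed, 5L))
  y_b <- protein_value(dos_b, bp$causal_b, bp$beta_b, fork_seed(sc$seed, 6L))
  a <- sumstats_from_cohort(dos_a, y_a, bp, protein_id)
  b <- sumstats_from_cohort(dos_b, y_b, bp, protein_id)
  keys <- variant_key(sc$chrom, bp$pos, bp$a1, bp$a2)
  truth <- list(protein_id = protein_id, label = sc$label,
                causal_a = keys[bp$causal_a], beta_a = bp$beta_a,
                causal_b = keys[bp$causal_b], beta_b = bp$beta_b,
                causal_a_idx = bp$causal_a, causal_b_idx = bp$causal_b,
                theta = sc$theta, mediating_tissue = "a")
  list(a = a, b = b, panel = panel, truth = truth, blueprint = bp)
}

#' Simulate outcome GWAS summary statistics for a locus
#'
#' An independent cohort of size `n_outcome` receives the mediating tissue's
#' protein model; the outcome is `theta * protein + N(0, 1)` noise, and
#' marginal OLS summary statistics are emitted for all locus variants.
#'
#' @param locus Output of [simulate_locus()].
#' @param mediating `"a"` (default) or `"b"`: which tissue's protein model
#'   mediates the outcome.
#' @return A `locus_sumstats` for the outcome trait.
#' @export
simulate_outcome <- function(locus, mediating = c("a", "b")) {
  mediating <- match.arg(mediating)
  bp <- locus$blueprint
  sc <- bp$scenario
  dos <- draw_dosages(sc$n_outcome, bp$maf, bp$blocks, sc$rho,
                      fork_seed(sc$seed, 7L))
  causal <- if (mediating == "a") bp$causal_a else bp$causal_b
  beta <- if (mediating == "a") bp$beta_a else bp$beta_b
  prot <- protein_value(dos, causal, beta, fork_seed(sc$seed, 8L))
  y <- with_seed(fork_seed(sc$seed, 9L),
                 sc$theta * prot + stats::rnorm(sc$n_outcome))
  sumstats_from_cohort(dos, y, bp, paste0(locus$truth$protein_id, "_outcome"))
}
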