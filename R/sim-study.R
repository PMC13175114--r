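# Full study bundle: every input the pipeline consumes, written to disk
# with a recorded ground-truth file.

# Minimal VCF 4.2 writer for the simulated LD panel (GT only, unphased).
write_panel_vcf <- function(panels, path) {
  samples <- panels[[1]]$samples
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")),
             path)
  gt_code <- c("0/0", "0/1", "1/1")
  for (panel in panels) {
    stopifnot(identical(panel$samples, samples))
    v <- panel$variants
    gt <- matrix(gt_code[round(t(panel$dosages)) + 1L],
                 nrow = ncol(panel$dosages))
    body <- data.table::data.table(
      CHROM = v$chrom, POS = v$pos, ID = ".",
      REF = v$a2, ALT = v$a1, QUAL = ".", FILTER = "PASS", INFO = ".",
      FORMAT = "GT")
    body <- cbind(body, data.table::as.data.table(gt))
    data.table::fwrite(body, path, sep = "\t", quote = FALSE,
                       col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

default_scenario_mix <- function() {
  c(SHARED_CONCORDANT = 0.40, SHARED_DISCORDANT = 0.10,
    DISTINCT = 0.25, A_ONLY = 0.15, "NULL" = 0.10)
}

#' Default study configuration
#'
#' @param n_proteins Number of simulated proteins (default 40).
#' @param mix Named scenario proportions (must sum to 1); counts are
#'   `round(n_proteins * mix)` and must add up exactly.
#' @param theta Protein-to-outcome effect given to every other protein
#'   (alternating with 0), exercising both MR hits and nulls.
#' @param ... Overrides for [locus_scenario()] fields (e.g. `m_variants`,
#'   `n_a`, `n_b`, `h2_signal`) and [simulate_expression()] fields under
#'   `expression = list(...)`.
#' @return Named list of configuration values.
#' @export
study_config <- function(n_proteins = 40, mix = default_scenario_mix(),
                         theta = 0.3, ...) {
  stopifnot(n_proteins >= 1, abs(sum(mix) - 1) < 1e-9)
  counts <- round(n_proteins * mix)
  if (sum(counts) != n_proteins) {
    stop("scenario mix does not divide n_proteins into whole counts")
  }
  utils::modifyList(
    list(n_proteins = n_proteins, mix = mix, scenario_counts = counts,
         theta = theta,
         m_variants = 100, n_blocks = 5, rho = 0.9,
         maf_range = c(0.05, 0.5), h2_signal = 0.05,
         n_a = 35000, n_b = 1000, n_outcome = 100000, n_panel = 5000,
         expression = list(g_genes = 2000, n_tissues = 50,
                           samples_per_tissue = 10,
                           planted_frac = 0.05, fold = 8)),
    list(...))
}

#' Simulate a full study bundle on disk
#'
#' Writes, under `out_dir`: per-protein summary-statistics TSVs for both
#' pQTL tissues and the outcome GWAS (`sumstats_a/`, `sumstats_b/`,
#' `outcome/`), one LD-panel VCF covering all loci (each protein on its own
#' chromosome label), a gene-coordinates BED, the expression counts TSV and
#' tissue map, `truth.json`, and the resolved `config.yaml`. The first
#' `n_proteins` gene identifiers of the expression matrix are the protein
#' ids, linking colocalization status to expression groups downstream.
#'
#' @param config From [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-protein and per-stage seeds are
#'   forked deterministically from it.
#' @return Invisibly, the list of written paths plus the truth list.
#' @export
simulate_study <- function(config = study_config(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("sumstats_a", "sumstats_b", "outcome")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  labels <- rep(names(config$scenario_counts), config$scenario_counts)
  n <- config$n_proteins
  pids <- sprintf("P%03d", seq_len(n))
  thetas <- ifelse(seq_len(n) %% 2L == 1L, config$theta, 0)
  thetas[labels == "NULL"] <- 0            # no instrument exists anyway

  panels <- vector("list", n)
  truth <- vector("list", n)
  bed <- data.frame()
  for (i in seq_len(n)) {
    sc <- locus_scenario(label = labels[i],
                         m_variants = config$m_variants,
                         n_blocks = config$n_blocks, rho = config$rho,
                         maf_range = config$maf_range,
                         h2_signal = config$h2_signal,
                         n_a = config$n_a, n_b = config$n_b,
                         theta = thetas[i], n_outcome = config$n_outcome,
                         n_panel = config$n_panel,
                         chrom = as.character(i),
                         seed = fork_seed(seed, 20L, i))
    loc <- simulate_locus(sc, protein_id = pids[i])
    out <- simulate_outcome(loc)
    write_sumstats(loc$a, file.path(out_dir, "sumstats_a", paste0(pids[i], ".tsv")))
    write_sumstats(loc$b, file.path(out_dir, "sumstats_b", paste0(pids[i], ".tsv")))
    write_sumstats(out, file.path(out_dir, "outcome", paste0(pids[i], ".tsv")))
    panels[[i]] <- loc$panel
    truth[[i]] <- loc$truth
    bed <- rbind(bed, data.frame(chrom = sc$chrom,
                                 start = loc$a$gene_start - 1,  # BED 0-based
                                 end = loc$a$gene_end,
                                 gene_id = pids[i], stringsAsFactors = FALSE))
    pqtlx_log("simulated locus %s (%s)", pids[i], labels[i], level = 2L)
  }
  write_panel_vcf(panels, file.path(out_dir, "panel.vcf"))
  data.table::fwrite(bed, file.path(out_dir, "genes.bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)

  expr_cfg <- config$expression
  expr <- simulate_expression(
    g_genes = expr_cfg$g_genes, n_tissues = expr_cfg$n_tissues,
    samples_per_tissue = expr_cfg$samples_per_tissue,
    planted_frac = expr_cfg$planted_frac, fold = expr_cfg$fold,
    gene_ids = c(pids, sprintf("G%04d", seq_len(expr_cfg$g_genes - n))),
    seed = fork_seed(seed, 21L))
  cts <- data.frame(gene_id = rownames(expr$counts$counts),
                    expr$counts$counts, check.names = FALSE)
  data.table::fwrite(cts, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(data.frame(sample = names(expr$counts$tissue_of),
                                tissue = unname(expr$counts$tissue_of)),
                     file.path(out_dir, "tissues.tsv"), sep = "\t",
                     quote = FALSE)

  truth_out <- list(proteins = truth,
                    scenario_counts = as.list(config$scenario_counts),
                    expression_planted = expr$truth)
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$mix <- as.list(cfg$mix)
  cfg$scenario_counts <- as.list(cfg$scenario_counts)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(list(dir = out_dir, protein_ids = pids, truth = truth_out))
}
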