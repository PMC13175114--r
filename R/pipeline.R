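# Stage orchestration: simulate -> colocalize -> enrich -> MR -> report.
# All randomness lives in the simulate stage; analysis stages are
# deterministic functions of their inputs, so reruns with the same seed and
# config reproduce outputs byte-for-byte.

#' Build a run configuration
#'
#' Collects input paths, analysis thresholds (each defaulting to the printed
#' study values: 500 kb cis window, MAF > 0.05, p < 5e-8 eligibility, K = 10
#' signals, colocalization probability > 0.8, enrichment z > 2, MR
#' alpha = 1e-5), the master seed, and stage toggles.
#'
#' @param input_dir Directory holding the study inputs (layout as written by
#'   [simulate_study()]).
#' @param out_dir Output directory.
#' @param simulate Run the simulation stage first (default TRUE when
#'   `input_dir` lacks a `truth.json`).
#' @param stages Character vector of analysis stages to run, subset of
#'   `c("coloc", "enrich", "mr")`.
#' @param cis_window,maf_min,gwas_p,K,coloc_threshold,z_enrich,mr_alpha
#'   Analysis thresholds.
#' @param seed Master seed (forked per stage by a counter scheme).
#' @param study Study-level simulation settings from [study_config()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       simulate = !file.exists(file.path(input_dir, "truth.json")),
                       stages = c("coloc", "enrich", "mr"),
                       cis_window = 500000, maf_min = 0.05, gwas_p = 5e-8,
                       K = 10, coloc_threshold = 0.8, z_enrich = 2,
                       mr_alpha = 1e-5, seed = 1,
                       study = study_config()) {
  stopifnot(cis_window > 0, maf_min > 0, gwas_p > 0, K >= 1,
            coloc_threshold > 0, z_enrich > 0, mr_alpha > 0)
  stages <- match.arg(stages, c("coloc", "enrich", "mr"), several.ok = TRUE)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 simulate = simulate, stages = stages,
                 cis_window = cis_window, maf_min = maf_min, gwas_p = gwas_p,
                 K = K, coloc_threshold = coloc_threshold,
                 z_enrich = z_enrich, mr_alpha = mr_alpha,
                 seed = as.integer(seed), study = study),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$study)) y$study <- do.call(study_config, y$study)
  do.call(run_config, y)
}

read_study_inputs <- function(dir) {
  genes <- read_gene_bed(file.path(dir, "genes.bed"))
  pids <- genes$gene_id
  stats_for <- function(sub, pid, g) {
    read_sumstats(file.path(dir, sub, paste0(pid, ".tsv")),
                  protein_id = pid, gene_start = g$gene_start,
                  gene_end = g$gene_end)
  }
  a <- b <- outc <- stats::setNames(vector("list", length(pids)), pids)
  for (i in seq_along(pids)) {
    g <- genes[i, ]
    a[[i]] <- stats_for("sumstats_a", pids[i], g)
    b[[i]] <- stats_for("sumstats_b", pids[i], g)
    outc[[i]] <- stats_for("outcome", pids[i], g)
  }
  list(genes = genes, a = a, b = b, outcome = outc,
       panel_vcf = file.path(dir, "panel.vcf"))
}

#' Run the full cross-tissue pQTL pipeline
#'
#' Stages execute in order (simulate, colocalize, enrich, MR); each stage
#' writes its intermediate TSVs under the configured output directory, every
#' filter logs its drop counts, and any stage error aborts with a
#' stage-tagged diagnostic. The run report records every threshold consumed.
#'
#' @param config A `run_config`.
#' @return Invisibly, a `cohort_summary` list: counts and proportions of
#'   colocalized and discordant loci, Spearman rho of lead effects, the
#'   per-tissue contrast table and the MR table.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (isTRUE(config$simulate)) {
    stage("simulate",
          simulate_study(config$study, config$input_dir, seed = config$seed))
  }
  inputs <- stage("read", read_study_inputs(config$input_dir))
  panel <- stage("read", load_panel(inputs$panel_vcf))

  # --- colocalization stage -------------------------------------------------
  results <- list()
  harmonized <- list()
  per_locus <- list()
  pair_rows <- list()
  if ("coloc" %in% config$stages) {
    for (pid in names(inputs$a)) {
      stage(paste0("coloc:", pid), {
        a <- apply_qc(filter_cis(inputs$a[[pid]], config$cis_window),
                      config$maf_min)
        b <- apply_qc(filter_cis(inputs$b[[pid]], config$cis_window),
                      config$maf_min)
        h <- harmonize_pair(a, b)
        eligible <- locus_eligible(h$a, h$b, config$gwas_p)
        res <- if (eligible && nrow(h$a$records) > 0) {
          ld <- compute_ld(panel, keys = h$a$records[c("chrom", "pos", "a1", "a2")])
          colocalize_locus(h$a, h$b, ld, K = config$K,
                           coloc_threshold = config$coloc_threshold)
        } else NULL
        harmonized[[pid]] <- h
        results[[pid]] <- res
        bp <- if (!is.null(res)) res$best_pair else NULL
        per_locus[[pid]] <- data.frame(
          protein_id = pid, eligible = eligible,
          n_signals_a = if (is.null(res)) 0L else res$n_signals_a,
          n_signals_b = if (is.null(res)) 0L else res$n_signals_b,
          coloc_prob = if (is.null(res)) 0 else res$coloc_prob,
          colocalized = if (is.null(res)) FALSE else res$colocalized,
          lead = if (is.null(bp)) NA_character_ else bp$lead_key,
          lead_pip = if (is.null(bp)) NA_real_ else bp$lead_pip,
          beta_a = if (is.null(bp)) NA_real_ else bp$lead_beta_a,
          beta_b = if (is.null(bp)) NA_real_ else bp$lead_beta_b,
          concordant = if (is.null(bp)) NA else bp$concordant,
          stringsAsFactors = FALSE)
        if (!is.null(res)) {
          for (p in res$pairs) {
            pair_rows[[length(pair_rows) + 1L]] <- data.frame(
              protein_id = pid, step_a = p$step_a, step_b = p$step_b,
              PP0 = p$pp[["PP0"]], PP1 = p$pp[["PP1"]], PP2 = p$pp[["PP2"]],
              PP3 = p$pp[["PP3"]], PP4 = p$pp[["PP4"]],
              lead = p$lead_key, lead_pip = p$lead_pip,
              credible_set = paste(p$credible_set, collapse = ","),
              concordant = p$concordant, stringsAsFactors = FALSE)
          }
        }
      })
    }
    per_locus_df <- do.call(rbind, per_locus)
    rownames(per_locus_df) <- NULL
    write_tsv_precise(per_locus_df, file.path(config$out_dir, "per_locus.tsv"))
    pairs_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame()
    if (nrow(pairs_df)) {
      write_tsv_precise(pairs_df, file.path(config$out_dir, "pairs.tsv"))
    }
  } else {
    per_locus_df <- data.frame()
  }

  tested <- Filter(Negate(is.null), results)
  conc <- if (length(tested)) summarize_concordance(unname(tested)) else
    list(n_tested = 0L, n_colocalized = 0L, prop_colocalized = NA_real_,
         n_discordant = 0L, prop_discordant_among_colocalized = NA_real_,
         spearman_rho = NA_real_)

  # --- tissue-enrichment stage ---------------------------------------------
  contrasts <- NULL
  if ("enrich" %in% config$stages) {
    stage("enrich", {
      cm <- read_counts(file.path(config$input_dir, "counts.tsv"),
                        file.path(config$input_dir, "tissues.tsv"))
      cm <- filter_genes(cm)
      f <- tmm_factors(cm)
      e <- enrichment_z(tissue_medians(cm, f), z_threshold = config$z_enrich)
      zdf <- data.frame(gene_id = rownames(e$z), e$z, check.names = FALSE)
      write_tsv_precise(zdf, file.path(config$out_dir, "enrichment_z.tsv"))
      if (length(tested)) {
        grp <- vapply(tested, function(r) isTRUE(r$colocalized), TRUE)
        group_of <- stats::setNames(ifelse(grp, "coloc", "noncoloc"),
                                    names(tested))
        contrasts <- tryCatch(contrast_by_group(e, group_of),
                              error = function(e2) {
                                pqtlx_log("contrast skipped: %s",
                                          conditionMessage(e2))
                                NULL
                              })
        if (!is.null(contrasts)) {
          write_tsv_precise(contrasts,
                            file.path(config$out_dir, "contrasts.tsv"))
        }
      }
    })
  }

  # --- MR stage -------------------------------------------------------------
  mr_table <- NULL
  if ("mr" %in% config$stages && length(tested)) {
    stage("mr", {
      inst <- select_instruments(tested,
                                 lapply(harmonized, `[[`, "a")[names(tested)],
                                 lapply(harmonized, `[[`, "b")[names(tested)],
                                 inputs$outcome, panel = panel,
                                 coloc_threshold = config$coloc_threshold)
      mr_table <- run_mr(inst, alpha = config$mr_alpha)
      write_tsv_precise(mr_table, file.path(config$out_dir, "mr_results.tsv"))
    })
  }

  summary <- structure(
    c(list(n_proteins_tested = conc$n_tested,
           n_colocalized = conc$n_colocalized,
           prop_colocalized = conc$prop_colocalized,
           n_discordant = conc$n_discordant,
           prop_discordant_among_colocalized =
             conc$prop_discordant_among_colocalized,
           spearman_rho = conc$spearman_rho),
      list(contrasts = contrasts, mr = mr_table)),
    class = "cohort_summary")
  scalar_fields <- c("n_proteins_tested", "n_colocalized", "prop_colocalized",
                     "n_discordant", "prop_discordant_among_colocalized",
                     "spearman_rho")
  jsonlite::write_json(summary[scalar_fields],
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_tsv_precise(as.data.frame(summary[scalar_fields]),
                    file.path(config$out_dir, "summary.tsv"))
  report <- list(thresholds = config[c("cis_window", "maf_min", "gwas_p", "K",
                                       "coloc_threshold", "z_enrich",
                                       "mr_alpha")],
                 seed = config$seed, stages = config$stages,
                 n_proteins = length(inputs$a))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0("cohort_summary: %d tested, %d colocalized (%.1f%%), ",
                     "%d discordant among colocalized (%.1f%%), Spearman rho %.2f\n"),
              x$n_proteins_tested, x$n_colocalized,
              100 * (x$prop_colocalized %||% NA),
              x$n_discordant,
              100 * (x$prop_discordant_among_colocalized %||% NA),
              x$spearman_rho %||% NA))
  invisible(x)
}
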