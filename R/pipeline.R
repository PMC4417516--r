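#' Per-module eigengene-age report
#'
#' For every module eigengene: the covariate-adjusted partial correlation
#' with age, its p-value, and a Bonferroni flag at
#' `alpha / n_modules` (six modules at alpha 0.05 give the conventional
#' threshold 0.05/6, printed as 0.008). Also returns the pairwise
#' eigengene correlation matrix (symmetric, unit diagonal).
#'
#' @param eigengenes Result of [module_eigengene()] (or any tibble with
#'   `module`, `sample_id`, `eigengene` columns).
#' @param sample_table Tibble aligned by `sample_id`.
#' @param covariates Character vector of covariate column names.
#' @param alpha Family-wise error target (default 0.05).
#' @return List with `table` (tibble: module, partial_r, p.value,
#'   bonferroni_threshold, significant), and `eigengene_cor` (matrix).
#' @export
eigengene_age_report <- function(eigengenes, sample_table,
                                 covariates = character(0), alpha = 0.05) {
  mods <- sort(unique(eigengenes$module))
  n_modules <- length(mods)
  if (n_modules == 0) stop("no modules in eigengene table")
  threshold <- alpha / n_modules
  wide <- matrix(NA_real_, nrow = nrow(sample_table), ncol = n_modules,
                 dimnames = list(sample_table$sample_id, paste0("ME", mods)))
  tab <- purrr::map_dfr(seq_along(mods), function(i) {
    sub <- eigengenes[eigengenes$module == mods[i], ]
    idx <- match(sample_table$sample_id, sub$sample_id)
    eg <- sub$eigengene[idx]
    wide[, i] <<- eg
    covs <- if (length(covariates)) {
      as.data.frame(sample_table[, covariates, drop = FALSE])
    } else NULL
    fit <- fit_linear_association(eg, sample_table$age, covs)
    tibble::tibble(module = mods[i], partial_r = fit$partial_r,
                   p.value = fit$p.value)
  })
  tab$bonferroni_threshold <- threshold
  tab$significant <- tab$p.value < threshold
  list(table = tab, eigengene_cor = stats::cor(wide))
}

#' Default pipeline configuration
#'
#' Thresholds mirror the study design: a discovery age scan at
#' FDR <= 0.001, a more liberal network pre-selection at FDR <= 0.01,
#' 200 subsamples of 80% with a 0.70 consensus edge threshold, and
#' mediation flagged at indirect p < 0.05.
#'
#' @param ... Named overrides of any default entry.
#' @param file Optional path to a YAML file whose entries override the
#'   defaults (explicit `...` arguments take final precedence).
#' @return Named list of pipeline settings.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    discovery_fdr = 0.001,
    network_fdr = 0.01,
    consensus_fraction = 0.8,
    consensus_reps = 200,
    consensus_threshold = 0.70,
    mediation_p = 0.05,
    cis_window = 1e6,
    cis_fdr = 0.001,
    min_module_size = 10,
    n_boot = 200,
    covariates = c("sex", "race", "site", "chip"),
    stages = list(contamination = TRUE, association = TRUE, network = TRUE,
                  consensus = TRUE, mediation = TRUE, enrichment = TRUE),
    seed = 1L
  )
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    for (nm in names(from_file)) cfg[[nm]] <- from_file[[nm]]
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$discovery_fdr > 0, cfg$discovery_fdr <= 1,
            cfg$network_fdr > 0, cfg$network_fdr <= 1,
            cfg$consensus_threshold > 0, cfg$consensus_threshold <= 1)
  cfg
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the study-level flow on a `synthetic_cohort` (or a directory
#' written by [write_cohort()], or an equivalent list): contamination
#' scoring, covariate-adjusted age scans of expression and methylation,
#' network pre-selection at the liberal FDR, network construction with
#' consensus-stability analysis, cis CpG-gene pairing with mediation of
#' the age effect, and gene-set overrepresentation of the age-associated
#' genes against the planted module memberships (or a supplied
#' collection). Each stage's output lands in `out_dir` along with a JSON
#' summary of counts at every threshold and a plain-text log of all
#' seeds; stage failures halt with the stage name.
#'
#' @param cohort A `synthetic_cohort`, a cohort directory path, or a list
#'   with the same components.
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory; `NULL` skips file output.
#' @param collection Optional named list of gene sets for the enrichment
#'   stage.
#' @return List of stage results plus `summary` (named counts).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         collection = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  log_lines <- c(sprintf("pipeline seed: %d", config$seed),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) readr::write_tsv(df, file.path(out_dir, name))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()
  summary <- list(n_genes = nrow(cohort$expression),
                  n_cpgs = nrow(cohort$methylation),
                  n_samples = ncol(cohort$expression))
  samples <- cohort$samples
  covars <- config$covariates

  ## contamination scoring -> covariates
  if (isTRUE(config$stages$contamination) && !is.null(cohort$profiles)) {
    results$contamination <- stage("contamination", {
      sigs <- select_signature_genes(cohort$profiles, fold = 4)
      sigs <- sigs[vapply(sigs, length, integer(1)) > 0]
      score_cohort(cohort$expression, sigs)
    })
    samples <- dplyr::left_join(samples, results$contamination,
                                by = "sample_id")
    covars <- c(covars, grep("^score_", names(samples), value = TRUE))
    emit(results$contamination, "contamination_scores.tsv")
    log_lines <- c(log_lines, sprintf("contamination: %d cell types scored",
                                      ncol(results$contamination) - 1L))
  }

  ## age scans
  if (isTRUE(config$stages$association)) {
    results$age_expression <- stage("age_expression_scan", {
      scan_associations(cohort$expression, samples, predictor = "age",
                        covariates = covars)
    })
    results$age_methylation <- stage("age_methylation_scan", {
      scan_associations(beta_to_m(cohort$methylation), samples,
                        predictor = "age",
                        covariates = setdiff(covars, "chip"))
    })
    emit(results$age_expression, "age_expression.tsv")
    emit(results$age_methylation, "age_methylation.tsv")
    summary$n_age_genes_discovery <-
      sum(results$age_expression$q.value <= config$discovery_fdr, na.rm = TRUE)
    summary$n_age_genes_network <-
      sum(results$age_expression$q.value <= config$network_fdr, na.rm = TRUE)
    summary$n_age_cpgs <-
      sum(results$age_methylation$q.value <= config$discovery_fdr, na.rm = TRUE)
  }

  ## network + consensus on the pre-selected gene set
  if (isTRUE(config$stages$network) && !is.null(results$age_expression)) {
    pre <- results$age_expression$feature_id[
      !is.na(results$age_expression$q.value) &
        results$age_expression$q.value <= config$network_fdr]
    summary$n_network_genes <- length(pre)
    if (length(pre) >= 3 * config$min_module_size) {
      sub_expr <- cohort$expression[pre, , drop = FALSE]
      results$network <- stage("network", {
        network_pipeline(sub_expr, min_size = config$min_module_size)
      })
      results$eigengenes <- stage("eigengenes", {
        module_eigengene(sub_expr, results$network$partition)
      })
      results$eigengene_report <- stage("eigengene_report", {
        eigengene_age_report(results$eigengenes, samples, covariates = covars)
      })
      emit(results$network$partition, "modules.tsv")
      emit(results$eigengene_report$table, "eigengene_age.tsv")
      summary$n_modules <- max(results$network$partition$module)
      if (isTRUE(config$stages$consensus)) {
        results$stability <- stage("consensus", {
          stability_report(sub_expr, fraction = config$consensus_fraction,
                           reps = config$consensus_reps,
                           threshold = config$consensus_threshold,
                           seed = config$seed,
                           min_size = config$min_module_size)
        })
        summary$n_consensus_modules <-
          max(results$stability$consensus_partition$module)
        summary$mean_replicate_jaccard <- results$stability$mean_jaccard
        emit(results$stability$consensus_partition, "consensus_modules.tsv")
      }
    } else {
      log_lines <- c(log_lines, "network: too few pre-selected genes; skipped")
    }
  }

  ## cis pairing + mediation
  if (isTRUE(config$stages$mediation) && !is.null(results$age_methylation)) {
    results$mediation <- stage("mediation", {
      pairs <- cis_pairs(cohort$cpg_annotation, cohort$gene_annotation,
                         window = config$cis_window)
      age_cpgs <- results$age_methylation$feature_id[
        !is.na(results$age_methylation$q.value) &
          results$age_methylation$q.value <= config$cis_fdr]
      pairs <- pairs[pairs$cpg_id %in% age_cpgs, , drop = FALSE]
      if (nrow(pairs) > 0) {
        # cis expression filter: CpG M-value predicting the paired gene
        mvals <- beta_to_m(cohort$methylation)
        keep <- vapply(seq_len(nrow(pairs)), function(i) {
          f <- fit_linear_association(
            cohort$expression[pairs$gene_id[i], ],
            mvals[pairs$cpg_id[i], ],
            as.data.frame(samples[, setdiff(covars, "position"),
                                  drop = FALSE]))
          f$p.value
        }, numeric(1))
        pairs <- pairs[qvalues(keep) <= config$cis_fdr, , drop = FALSE]
      }
      summary$n_cis_pairs <- nrow(pairs)
      mediation_scan(pairs, cohort$expression, beta_to_m(cohort$methylation),
                     samples, covariates = setdiff(covars, "position"),
                     n_boot = config$n_boot, seed = config$seed,
                     p_cut = config$mediation_p)
    })
    summary$n_genes_mediated <- attr(results$mediation, "summary")$n_genes_mediated
    if (nrow(results$mediation) > 0) emit(results$mediation, "mediation.tsv")
  }

  ## enrichment of discovery genes
  if (isTRUE(config$stages$enrichment) && !is.null(results$age_expression)) {
    if (is.null(collection) && !is.null(cohort$ground_truth)) {
      gt <- cohort$ground_truth$gene
      collection <- split(gt$gene_id, gt$module)
      collection <- collection[names(collection) != "0"]
      names(collection) <- paste0("module_", names(collection))
    }
    if (!is.null(collection) && length(collection) > 0) {
      results$enrichment <- stage("enrichment", {
        query <- results$age_expression$feature_id[
          !is.na(results$age_expression$q.value) &
            results$age_expression$q.value <= config$discovery_fdr]
        enrich_collection(query, collection,
                          background = rownames(cohort$expression))
      })
      emit(results$enrichment, "enrichment.tsv")
      summary$n_enriched_sets <- sum(results$enrichment$fdr < 0.05)
    }
  }

  results$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  results
}
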