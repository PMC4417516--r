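#' Configuration for a synthetic aging cohort
#'
#' Collects and validates the knobs of the synthetic-cohort generator.
#' Defaults describe the reference study conditions used throughout the
#' package's validation suite: 300 participants aged 55-94, 500 genes of
#' which five blocks of 80 form co-expression modules at within-module
#' correlation 0.7, per-gene age effects capped at 10% of baseline per
#' ten-year difference, five CpG-gene mediation triples, and three
#' contaminating cell types.
#'
#' @param n_samples Number of participants.
#' @param n_genes Number of genes on the array.
#' @param n_cpgs Number of CpG probes.
#' @param age_range Length-2 numeric, years; ages drawn uniformly.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of length `n_modules`; their sum must
#'   not exceed `n_genes`.
#' @param within_module_cor Target pairwise correlation of genes within a
#'   module, in (0, 1).
#' @param module_age_cor Correlation between each module's latent factor
#'   and age (recycled to `n_modules`); alternating signs by default so
#'   eigengenes associate with age in both directions.
#' @param frac_age_genes Proportion of background (non-module,
#'   non-mediation, non-signature) genes given a direct age slope.
#' @param max_effect_per_decade Cap on the per-decade expression shift of a
#'   direct age effect, as a proportion of the gene's baseline (default
#'   0.10, i.e. up to 10% per ten-year difference).
#' @param age_slopes Optional numeric vector of exact per-year slopes; if
#'   given, it overrides `frac_age_genes` and is assigned to the first
#'   `length(age_slopes)` background genes.
#' @param n_mediation_triples Number of CpG-gene pairs whose methylation
#'   partially mediates the age effect on expression.
#' @param mediation_props Data frame with columns `a` (age to M-value slope
#'   per year), `b` (M-value to expression slope) and `cprime` (direct age
#'   to expression slope per year), recycled to `n_mediation_triples`.
#' @param n_cell_types Number of contaminating cell types (0 disables the
#'   contamination component).
#' @param n_signature_genes Signature genes reserved per cell type.
#' @param contamination_range Length-2 proportion interval from which each
#'   sample's per-type contamination fraction is drawn.
#' @param contamination_amplitude Log2 expression shift of a signature gene
#'   per unit contamination fraction.
#' @param noise_sd Standard deviation of per-gene expression noise (log2
#'   units).
#' @param covariate_effects If `TRUE` (default), small additive chip, site
#'   and sex shifts are applied to expression; set `FALSE` for cohorts
#'   whose only structure should be the planted signal.
#' @param meth_noise_sd Standard deviation of CpG M-value noise.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L,
                          n_genes = 500L,
                          n_cpgs = 300L,
                          age_range = c(55, 94),
                          n_modules = 5L,
                          module_sizes = rep(80L, n_modules),
                          within_module_cor = 0.7,
                          module_age_cor = 0.3 * (-1)^(seq_len(n_modules) + 1),
                          frac_age_genes = 0.25,
                          max_effect_per_decade = 0.10,
                          age_slopes = NULL,
                          n_mediation_triples = 5L,
                          mediation_props = data.frame(a = 0.04, b = 1.5, cprime = 0.03),
                          n_cell_types = 3L,
                          n_signature_genes = 10L,
                          contamination_range = c(0, 0.2),
                          contamination_amplitude = 5,
                          noise_sd = 1,
                          meth_noise_sd = 0.5,
                          covariate_effects = TRUE,
                          seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_cpgs = as.integer(n_cpgs), age_range = as.numeric(age_range),
    n_modules = as.integer(n_modules), module_sizes = as.integer(module_sizes),
    within_module_cor = within_module_cor,
    module_age_cor = rep_len(module_age_cor, n_modules),
    frac_age_genes = frac_age_genes,
    max_effect_per_decade = max_effect_per_decade,
    age_slopes = age_slopes,
    n_mediation_triples = as.integer(n_mediation_triples),
    mediation_props = mediation_props[rep_len(seq_len(nrow(mediation_props)),
                                              max(n_mediation_triples, 1L)), , drop = FALSE],
    n_cell_types = as.integer(n_cell_types),
    n_signature_genes = as.integer(n_signature_genes),
    contamination_range = as.numeric(contamination_range),
    contamination_amplitude = contamination_amplitude,
    noise_sd = noise_sd, meth_noise_sd = meth_noise_sd,
    covariate_effects = isTRUE(covariate_effects),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid `", field, "`: ", msg, call. = FALSE)
  if (cfg$n_samples < 2) fail("n_samples", "need at least 2 samples")
  if (cfg$n_genes < 1) fail("n_genes", "need at least 1 gene")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    fail("age_range", "must be (low, high) with low < high")
  if (length(cfg$module_sizes) != cfg$n_modules)
    fail("module_sizes", "length must equal n_modules")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    fail("module_sizes", "sum exceeds n_genes")
  if (cfg$n_modules > 0 &&
      (cfg$within_module_cor <= 0 || cfg$within_module_cor >= 1))
    fail("within_module_cor", "must lie in (0, 1)")
  for (f in c("frac_age_genes", "max_effect_per_decade")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  if (any(cfg$contamination_range < 0) || any(cfg$contamination_range > 1) ||
      cfg$contamination_range[1] > cfg$contamination_range[2])
    fail("contamination_range", "must be an interval within [0, 1]")
  if (cfg$n_mediation_triples > cfg$n_cpgs)
    fail("n_mediation_triples", "cannot exceed n_cpgs")
  reserved <- sum(cfg$module_sizes) + cfg$n_mediation_triples +
    cfg$n_cell_types * cfg$n_signature_genes
  if (reserved > cfg$n_genes)
    fail("n_genes", sprintf(
      "too small: modules + mediation + signature genes reserve %d of %d",
      reserved, cfg$n_genes))
  if (cfg$noise_sd < 0) fail("noise_sd", "must be non-negative")
  invisible(cfg)
}

# sd of Uniform(a, b): used to scale module-factor age loadings
uniform_sd <- function(range) diff(range) / sqrt(12)

make_profiles <- function(gene_ids, designated) {
  n_types <- length(designated)
  base <- stats::runif(length(gene_ids), 4, 8)
  prof <- matrix(rep(base, each = n_types), nrow = n_types,
                 dimnames = list(paste0("celltype", seq_len(n_types)), gene_ids))
  # mild type-specific jitter on non-designated genes, clamped so no
  # accidental gene clears the 4-fold (2 log2) signature margin
  jitter <- matrix(pmin(pmax(stats::rnorm(length(prof), 0, 0.2), -0.5), 0.5),
                   nrow = n_types)
  desig_idx <- match(unlist(designated), gene_ids)
  jitter[, desig_idx] <- 0
  prof <- prof + jitter
  for (t in seq_len(n_types)) {
    idx <- match(designated[[t]], gene_ids)
    prof[t, idx] <- prof[t, idx] + 2 + stats::runif(length(idx), 0, 2)
  }
  prof
}

#' Generate cell-type reference expression profiles
#'
#' Builds a cell-type-by-gene matrix of mean log2 expression in which each
#' cell type has a designated block of signature genes elevated at least
#' four-fold (2 log2 units) over every other type. Used to exercise
#' signature selection and contamination scoring.
#'
#' @param n_cell_types Number of cell types (>= 1).
#' @param n_genes Number of genes (>= `n_cell_types * n_signature_genes`).
#' @param seed Integer seed.
#' @param n_signature_genes Designated signature genes per type.
#' @return Numeric matrix (cell types x genes) with attribute
#'   `planted_signatures`, a named list of the designated gene ids.
#' @export
generate_reference_profiles <- function(n_cell_types, n_genes, seed = 1L,
                                        n_signature_genes = 10L) {
  stopifnot(n_cell_types >= 1, n_genes >= n_cell_types * n_signature_genes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  designated <- lapply(seq_len(n_cell_types), function(t) {
    gene_ids[((t - 1) * n_signature_genes + 1):(t * n_signature_genes)]
  })
  names(designated) <- paste0("celltype", seq_len(n_cell_types))
  prof <- withr::with_seed(seed, make_profiles(gene_ids, designated))
  attr(prof, "planted_signatures") <- designated
  prof
}

#' Generate a synthetic aging cohort with planted ground truth
#'
#' Simulates an expression matrix, a methylation matrix and a sample table
#' with the statistical structure the downstream analyses assume:
#'
#' * co-expression modules via one latent factor per module — gene =
#'   baseline + `sqrt(rho)` factor + `sqrt(1-rho)` noise, so the pairwise
#'   within-module correlation targets `within_module_cor`; the factor
#'   itself carries a module-level age loading so eigengenes associate
#'   with age;
#' * direct per-gene age slopes on a subset of background genes, capped at
#'   `max_effect_per_decade` of baseline per ten years;
#' * mediation triples in which a CpG's M-value follows
#'   `M = a * age + noise` and the paired gene adds `b * M + cprime * age`,
#'   making the marginal age slope `a*b + cprime`;
#' * per-sample cell-type contamination that elevates planted signature
#'   genes in proportion to the contamination fraction;
#' * categorical nuisance covariates (sex, race, site, chip, position)
#'   with small additive shifts, and three blood-pressure readings per
#'   participant from which pulse pressure derives.
#'
#' Methylation is generated on the M-value scale and returned as
#' beta-values through the exact inverse-logit transform, so
#' [beta_to_m()] recovers the generating scale. All genes and CpGs sit on
#' a uniform grid of one synthetic chromosome; each mediating CpG lies
#' 50 kb from its gene so cis-window logic is exercised.
#'
#' @param config A [cohort_config()] object.
#' @return A `synthetic_cohort` list: `expression` (genes x samples, log2),
#'   `methylation` (CpGs x samples, beta scale), `samples` (tibble),
#'   `gene_annotation`, `cpg_annotation` (tibbles with grid coordinates),
#'   `profiles` (cell type x gene reference means), `ground_truth` (planted
#'   slopes, module labels, mediation triples, contamination fractions,
#'   signature lists) and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  G <- cfg$n_genes
  sample_ids <- sprintf("s%04d", seq_len(n))
  gene_ids <- sprintf("g%04d", seq_len(G))

  ## ---- gene layout: modules, mediation, signatures, background --------
  module_of <- integer(G)
  pos <- 1L
  for (m in seq_len(cfg$n_modules)) {
    module_of[pos:(pos + cfg$module_sizes[m] - 1L)] <- m
    pos <- pos + cfg$module_sizes[m]
  }
  med_gene_idx <- if (cfg$n_mediation_triples > 0)
    pos:(pos + cfg$n_mediation_triples - 1L) else integer(0)
  pos <- pos + cfg$n_mediation_triples
  sig_idx <- list()
  if (cfg$n_cell_types > 0) {
    for (t in seq_len(cfg$n_cell_types)) {
      sig_idx[[t]] <- pos:(pos + cfg$n_signature_genes - 1L)
      pos <- pos + cfg$n_signature_genes
    }
    names(sig_idx) <- paste0("celltype", seq_len(cfg$n_cell_types))
  }
  background_idx <- if (pos <= G) pos:G else integer(0)

  ## ---- samples ---------------------------------------------------------
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  age_c <- age - mean(cfg$age_range)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  race <- sample(c("white", "black", "hispanic"), n, replace = TRUE,
                 prob = c(0.4, 0.35, 0.25))
  site <- sample(paste0("site", 1:4), n, replace = TRUE)
  n_chips <- max(1L, ceiling(n / 12))
  chip <- sample(rep(sprintf("chip%02d", seq_len(n_chips)), length.out = n))
  position <- sprintf("pos%02d", (match(sample_ids, sample_ids) - 1L) %% 12L + 1L)
  position <- sample(position)

  ## ---- expression ------------------------------------------------------
  baseline <- stats::runif(G, 6, 12)
  true_slope <- numeric(G)
  expr <- matrix(rep(baseline, times = n), nrow = G,
                 dimnames = list(gene_ids, sample_ids))

  sd_age <- uniform_sd(cfg$age_range)
  rho <- cfg$within_module_cor
  if (cfg$n_modules > 0) {
    for (m in seq_len(cfg$n_modules)) {
      gamma <- cfg$module_age_cor[m]
      w <- gamma / sd_age
      factor_m <- w * age_c + sqrt(max(0, 1 - gamma^2)) * stats::rnorm(n)
      idx <- which(module_of == m)
      load <- cfg$noise_sd * sqrt(rho)
      expr[idx, ] <- expr[idx, ] +
        matrix(rep(load * factor_m, each = length(idx)), nrow = length(idx)) +
        cfg$noise_sd * sqrt(1 - rho) * matrix(stats::rnorm(length(idx) * n),
                                              nrow = length(idx))
      true_slope[idx] <- load * w
    }
  }

  # direct age slopes on background genes
  if (!is.null(cfg$age_slopes)) {
    n_age <- min(length(cfg$age_slopes), length(background_idx))
    age_gene_idx <- background_idx[seq_len(n_age)]
    slopes <- cfg$age_slopes[seq_len(n_age)]
  } else {
    n_age <- round(cfg$frac_age_genes * length(background_idx))
    age_gene_idx <- background_idx[seq_len(n_age)]
    u <- stats::runif(n_age, 0.3, 1) * sample(c(-1, 1), n_age, replace = TRUE)
    slopes <- u * cfg$max_effect_per_decade * baseline[age_gene_idx] / 10
  }
  if (n_age > 0) {
    true_slope[age_gene_idx] <- true_slope[age_gene_idx] + slopes
    expr[age_gene_idx, ] <- expr[age_gene_idx, ] + outer(slopes, age_c)
  }

  # expression noise for all non-module genes
  nonmod <- which(module_of == 0L)
  if (length(nonmod) > 0 && cfg$noise_sd > 0) {
    expr[nonmod, ] <- expr[nonmod, ] +
      cfg$noise_sd * matrix(stats::rnorm(length(nonmod) * n), nrow = length(nonmod))
  }

  ## ---- methylation + mediation ----------------------------------------
  C <- cfg$n_cpgs
  cpg_ids <- sprintf("cg%04d", seq_len(C))
  mu_c <- stats::rnorm(C, 0, 1.5)
  mvals <- matrix(rep(mu_c, times = n), nrow = C,
                  dimnames = list(cpg_ids, sample_ids)) +
    cfg$meth_noise_sd * matrix(stats::rnorm(C * n), nrow = C)

  mediation <- tibble::tibble(cpg_id = character(0), gene_id = character(0),
                              a = numeric(0), b = numeric(0), cprime = numeric(0))
  if (cfg$n_mediation_triples > 0) {
    props <- cfg$mediation_props
    for (k in seq_len(cfg$n_mediation_triples)) {
      a <- props$a[k]; b <- props$b[k]; cp <- props$cprime[k]
      mvals[k, ] <- mvals[k, ] + a * age_c
      g <- med_gene_idx[k]
      expr[g, ] <- expr[g, ] + b * (mvals[k, ] - mu_c[k]) + cp * age_c
      true_slope[g] <- a * b + cp
      mediation <- dplyr::bind_rows(mediation, tibble::tibble(
        cpg_id = cpg_ids[k], gene_id = gene_ids[g], a = a, b = b, cprime = cp))
    }
  }
  # a slice of background CpGs carries small age slopes of its own
  bg_cpg <- setdiff(seq_len(C), seq_len(cfg$n_mediation_triples))
  n_age_cpg <- round(0.2 * length(bg_cpg))
  if (n_age_cpg > 0) {
    idx <- bg_cpg[seq_len(n_age_cpg)]
    sl <- stats::runif(n_age_cpg, 0.01, 0.04) *
      sample(c(-1, 1), n_age_cpg, replace = TRUE)
    mvals[idx, ] <- mvals[idx, ] + outer(sl, age_c)
  }

  ## ---- contamination ---------------------------------------------------
  profiles <- NULL
  contamination <- NULL
  signatures <- list()
  if (cfg$n_cell_types > 0) {
    signatures <- lapply(sig_idx, function(i) gene_ids[i])
    profiles <- make_profiles(gene_ids, signatures)
    fr <- matrix(stats::runif(n * cfg$n_cell_types,
                              cfg$contamination_range[1],
                              cfg$contamination_range[2]),
                 nrow = n,
                 dimnames = list(sample_ids, names(signatures)))
    for (t in seq_along(signatures)) {
      idx <- sig_idx[[t]]
      expr[idx, ] <- expr[idx, ] +
        matrix(rep(cfg$contamination_amplitude * fr[, t], each = length(idx)),
               nrow = length(idx))
    }
    contamination <- tibble::as_tibble(fr, rownames = "sample_id")
  }

  ## ---- covariate shifts ------------------------------------------------
  if (cfg$covariate_effects) {
    chip_shift <- stats::rnorm(n_chips, 0, 0.1)
    names(chip_shift) <- sprintf("chip%02d", seq_len(n_chips))
    site_shift <- stats::rnorm(4, 0, 0.05)
    names(site_shift) <- paste0("site", 1:4)
    expr <- expr + matrix(rep(chip_shift[chip] + site_shift[site], each = G),
                          nrow = G)
    sex_genes <- sample(seq_len(G), max(0L, round(0.1 * G)))
    if (length(sex_genes) > 0) {
      sex_eff <- stats::rnorm(length(sex_genes), 0, 0.3)
      expr[sex_genes, sex == "M"] <- expr[sex_genes, sex == "M"] + sex_eff
    }
  }

  ## ---- blood pressure / pulse pressure ---------------------------------
  sbp_base <- 110 + 0.5 * (age - cfg$age_range[1]) + stats::rnorm(n, 0, 8)
  dbp_base <- 75 + stats::rnorm(n, 0, 6)
  readings <- lapply(1:3, function(r) {
    cbind(sbp = sbp_base + stats::rnorm(n, 0, 3),
          dbp = dbp_base + stats::rnorm(n, 0, 2))
  })
  pp <- vapply(seq_len(n), function(i) {
    pulse_pressure_from_readings(lapply(readings, function(r) r[i, ]))
  }, numeric(1))

  samples <- tibble::tibble(
    sample_id = sample_ids, age = age, sex = sex, race = race, site = site,
    chip = chip, position = position,
    sbp1 = readings[[1]][, "sbp"], dbp1 = readings[[1]][, "dbp"],
    sbp2 = readings[[2]][, "sbp"], dbp2 = readings[[2]][, "dbp"],
    sbp3 = readings[[3]][, "sbp"], dbp3 = readings[[3]][, "dbp"],
    pulse_pressure = pp
  )

  ## ---- annotations: one synthetic chromosome, uniform grids ------------
  gene_annotation <- tibble::tibble(
    gene_id = gene_ids, chrom = "chr1",
    start = (seq_len(G) - 1L) * 100000L,
    end = (seq_len(G) - 1L) * 100000L + 1000L,
    strand = "+"
  )
  spacing <- max(1L, as.integer(floor(G * 100000 / max(C, 1))))
  cpg_pos <- (seq_len(C) - 1L) * spacing
  if (cfg$n_mediation_triples > 0) {
    cpg_pos[seq_len(cfg$n_mediation_triples)] <-
      gene_annotation$start[med_gene_idx] + 50000L
  }
  cpg_annotation <- tibble::tibble(cpg_id = cpg_ids, chrom = "chr1", pos = cpg_pos)

  ground_truth <- list(
    gene = tibble::tibble(
      gene_id = gene_ids, true_slope = true_slope, module = module_of,
      baseline = baseline),
    mediation = mediation,
    contamination = contamination,
    signatures = signatures
  )

  structure(list(
    expression = expr,
    methylation = m_to_beta(mvals),
    samples = samples,
    gene_annotation = gene_annotation,
    cpg_annotation = cpg_annotation,
    profiles = profiles,
    ground_truth = ground_truth,
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic aging cohort\n")
  cat(sprintf("  %d genes x %d samples; %d CpGs\n",
              nrow(x$expression), ncol(x$expression), nrow(x$methylation)))
  cat(sprintf("  ages %.0f-%.0f; %d planted modules; %d mediation triples; %d cell types\n",
              min(x$samples$age), max(x$samples$age), x$config$n_modules,
              x$config$n_mediation_triples, x$config$n_cell_types))
  invisible(x)
}

write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "feature_id")
  readr::write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Matrices go out as TSV (features in rows, header = sample ids),
#' annotations as BED-like TSV (0-based half-open intervals), planted
#' signatures as GMT and the ground truth as JSON. [read_cohort()] reads
#' the set back; matrices round-trip within float formatting.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  p <- function(f) file.path(directory, f)
  write_matrix_tsv(cohort$expression, p("expression.tsv"))
  write_matrix_tsv(cohort$methylation, p("methylation.tsv"))
  readr::write_tsv(cohort$samples, p("samples.tsv"))
  genes_bed <- tibble::tibble(
    chrom = cohort$gene_annotation$chrom,
    start = cohort$gene_annotation$start,
    end = cohort$gene_annotation$end,
    name = cohort$gene_annotation$gene_id,
    score = 0L,
    strand = cohort$gene_annotation$strand
  )
  readr::write_tsv(genes_bed, p("genes.bed"), col_names = FALSE)
  cpgs_bed <- tibble::tibble(
    chrom = cohort$cpg_annotation$chrom,
    start = cohort$cpg_annotation$pos,
    end = cohort$cpg_annotation$pos + 2L,
    name = cohort$cpg_annotation$cpg_id
  )
  readr::write_tsv(cpgs_bed, p("cpgs.bed"), col_names = FALSE)
  files <- c(p("expression.tsv"), p("methylation.tsv"), p("samples.tsv"),
             p("genes.bed"), p("cpgs.bed"))
  if (length(cohort$ground_truth$signatures) > 0) {
    write_gmt(cohort$ground_truth$signatures, p("signatures.gmt"))
    files <- c(files, p("signatures.gmt"))
  }
  gt <- cohort$ground_truth
  gt_json <- list(
    gene = gt$gene,
    mediation = gt$mediation,
    contamination = gt$contamination,
    signatures = gt$signatures
  )
  jsonlite::write_json(gt_json, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- c(files, p("ground_truth.json"))
  invisible(files)
}

#' Read back a cohort directory written by [write_cohort()]
#'
#' @param directory Directory produced by [write_cohort()].
#' @return A list with `expression`, `methylation`, `samples`,
#'   `gene_annotation`, `cpg_annotation`, `signatures` (if present) and
#'   `ground_truth`.
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("expression.tsv", "methylation.tsv", "samples.tsv")) {
    if (!file.exists(p(f))) stop("missing cohort file: ", p(f))
  }
  genes_bed <- readr::read_tsv(p("genes.bed"),
                               col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                               show_col_types = FALSE, progress = FALSE)
  cpgs_bed <- readr::read_tsv(p("cpgs.bed"),
                              col_names = c("chrom", "start", "end", "name"),
                              show_col_types = FALSE, progress = FALSE)
  out <- list(
    expression = read_matrix_tsv(p("expression.tsv")),
    methylation = read_matrix_tsv(p("methylation.tsv")),
    samples = readr::read_tsv(p("samples.tsv"), show_col_types = FALSE,
                              progress = FALSE),
    gene_annotation = tibble::tibble(
      gene_id = genes_bed$name, chrom = genes_bed$chrom,
      start = genes_bed$start, end = genes_bed$end, strand = genes_bed$strand),
    cpg_annotation = tibble::tibble(
      cpg_id = cpgs_bed$name, chrom = cpgs_bed$chrom, pos = cpgs_bed$start)
  )
  if (file.exists(p("signatures.gmt"))) out$signatures <- read_gmt(p("signatures.gmt"))
  if (file.exists(p("ground_truth.json"))) {
    out$ground_truth <- jsonlite::read_json(p("ground_truth.json"),
                                            simplifyVector = TRUE)
  }
  out
}
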