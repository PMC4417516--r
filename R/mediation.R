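#' Point estimates of a single-mediator linear mediation model
#'
#' Product-of-coefficients decomposition via two least-squares fits:
#' `mediator ~ exposure + covariates` gives the path `a`, and
#' `outcome ~ mediator + exposure + covariates` gives `b` (mediator
#' effect) and the direct effect `cprime`. The indirect effect is `a * b`
#' and the total effect `cprime + a * b`. For one continuous mediator
#' with Gaussian errors these point estimates coincide with the
#' maximum-likelihood structural-equation decomposition, and the total
#' equals the exposure coefficient of the reduced model
#' `outcome ~ exposure + covariates` (collapsibility of linear
#' mediation).
#'
#' @param exposure Numeric vector (e.g. age in years).
#' @param mediator Numeric vector (e.g. CpG M-values).
#' @param outcome Numeric vector (e.g. log2 expression).
#' @param covariates Optional data frame of covariates.
#' @return One-row tibble: `a`, `b`, `direct`, `indirect`, `total`.
#' @export
fit_mediation <- function(exposure, mediator, outcome, covariates = NULL) {
  n <- length(exposure)
  stopifnot(length(mediator) == n, length(outcome) == n)
  if (stats::sd(mediator) == 0) stop("constant mediator")
  if (stats::sd(outcome) == 0) stop("constant outcome")
  C <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    build_design(covariates, names(covariates), intercept = TRUE)
  }
  X1 <- cbind(C[, 1, drop = FALSE], exposure = exposure, C[, -1, drop = FALSE])
  X2 <- cbind(C[, 1, drop = FALSE], mediator = mediator, exposure = exposure,
              C[, -1, drop = FALSE])
  if (n <= ncol(X2) + 2) stop("too few observations for the mediation model")
  f1 <- ols_with_se(X1, mediator)
  f2 <- ols_with_se(X2, outcome)
  a <- unname(f1$coef["exposure"])
  b <- unname(f2$coef["mediator"])
  cprime <- unname(f2$coef["exposure"])
  tibble::tibble(a = a, b = b, direct = cprime, indirect = a * b,
                 total = cprime + a * b)
}

#' Bootstrap inference for the indirect (mediated) effect
#'
#' Nonparametric case resampling: samples are drawn with replacement,
#' the two mediation regressions are refit, and the bootstrap
#' distribution of the indirect effect `a * b` is collected. The standard
#' error is the bootstrap standard deviation and the two-sided p-value is
#' the percentile-of-zero rule
#' `p = min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))`. Resamples
#' with a constant mediator or outcome are skipped and counted.
#'
#' @inheritParams fit_mediation
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; fixed seeds reproduce results exactly.
#' @return Object of class `mediation_result`: one-row tibble with `a`,
#'   `b`, `direct`, `indirect`, `total`, `boot_se`, `p_indirect`,
#'   `ci_lower`, `ci_upper` (percentile 95%), `n_boot`, `n_skipped`, `n`,
#'   `seed`.
#' @export
bootstrap_mediation <- function(exposure, mediator, outcome, covariates = NULL,
                                n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  est <- fit_mediation(exposure, mediator, outcome, covariates)
  n <- length(exposure)

  # pre-build the fixed design parts once; refits use .lm.fit on the
  # resampled rows for speed
  C <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    build_design(covariates, names(covariates), intercept = TRUE)
  }
  X1 <- cbind(C[, 1, drop = FALSE], exposure, C[, -1, drop = FALSE])

  boot <- withr::with_seed(seed, {
    vals <- numeric(n_boot)
    skipped <- 0L
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      m_r <- mediator[idx]
      y_r <- outcome[idx]
      if (stats::sd(m_r) == 0 || stats::sd(y_r) == 0) {
        vals[r] <- NA_real_
        skipped <- skipped + 1L
        next
      }
      X1r <- X1[idx, , drop = FALSE]
      a_r <- stats::.lm.fit(X1r, m_r)$coefficients[2]
      X2r <- cbind(X1r[, 1, drop = FALSE], m_r, X1r[, -1, drop = FALSE])
      b_r <- stats::.lm.fit(X2r, y_r)$coefficients[2]
      vals[r] <- a_r * b_r
    }
    list(vals = vals[!is.na(vals)], skipped = skipped)
  })
  bv <- boot$vals
  p <- min(1, 2 * min(mean(bv <= 0), mean(bv >= 0)))
  ci <- stats::quantile(bv, c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    est,
    boot_se = stats::sd(bv), p_indirect = p,
    ci_lower = ci[1], ci_upper = ci[2],
    n_boot = length(bv), n_skipped = boot$skipped,
    n = n, seed = as.integer(seed)
  )
  structure(out, class = c("mediation_result", class(out)))
}

#' Mediation scan over pre-filtered cis CpG-gene pairs
#'
#' Runs [bootstrap_mediation()] for every supplied pair (the pairs are
#' expected to be pre-filtered to CpGs associated with both age and
#' cis-gene expression at the caller's FDR thresholds), flags per gene the
#' pair with the smallest indirect p-value, and summarizes how many genes
#' have any significantly mediating CpG.
#'
#' @param pairs Tibble with `cpg_id` and `gene_id` columns.
#' @param expr Expression matrix (genes x samples).
#' @param meth Methylation matrix on the M-value scale (CpGs x samples);
#'   beta-scale input should pass through [beta_to_m()] first.
#' @param sample_table Tibble containing the exposure column.
#' @param exposure Name of the exposure column (default "age").
#' @param covariates Character vector of covariate column names.
#' @param n_boot,seed Passed to [bootstrap_mediation()]; each pair gets an
#'   independent sub-seed drawn from `seed`.
#' @param p_cut Indirect-effect significance threshold for the summary
#'   (default 0.05).
#' @return Tibble of class `mediation_scan`, one row per pair with the
#'   mediation columns plus `best_for_gene`; summary counts in attribute
#'   `summary`.
#' @export
mediation_scan <- function(pairs, expr, meth, sample_table, exposure = "age",
                           covariates = character(0), n_boot = 1000,
                           seed = 1L, p_cut = 0.05) {
  if (nrow(pairs) == 0) {
    out <- tibble::tibble(cpg_id = character(0), gene_id = character(0))
    attr(out, "summary") <- list(n_pairs = 0L, n_genes = 0L,
                                 n_genes_mediated = 0L)
    return(out)
  }
  missing_g <- setdiff(pairs$gene_id, rownames(expr))
  missing_c <- setdiff(pairs$cpg_id, rownames(meth))
  if (length(missing_g) || length(missing_c)) {
    stop("pairs reference unknown features: ",
         paste(utils::head(c(missing_g, missing_c), 5), collapse = ", "))
  }
  x <- sample_table[[exposure]]
  covs <- if (length(covariates)) {
    as.data.frame(sample_table[, covariates, drop = FALSE])
  } else NULL
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, nrow(pairs)))
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    r <- bootstrap_mediation(
      exposure = x,
      mediator = meth[pairs$cpg_id[i], ],
      outcome = expr[pairs$gene_id[i], ],
      covariates = covs, n_boot = n_boot, seed = sub_seeds[i])
    dplyr::bind_cols(pairs[i, c("cpg_id", "gene_id")], r)
  })
  # deterministic best-pair flag: smallest p, first row on ties
  res$best_for_gene <- FALSE
  for (g in unique(res$gene_id)) {
    idx <- which(res$gene_id == g)
    res$best_for_gene[idx[which.min(res$p_indirect[idx])]] <- TRUE
  }
  attr(res, "summary") <- list(
    n_pairs = nrow(res),
    n_genes = length(unique(res$gene_id)),
    n_genes_mediated = length(unique(res$gene_id[res$p_indirect < p_cut]))
  )
  structure(res, class = c("mediation_scan", class(res)))
}
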