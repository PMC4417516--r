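#' Convert methylation beta-values to M-values
#'
#' The M-value is the log2 ratio of methylated to unmethylated intensity,
#' i.e. `M = log2(beta / (1 - beta))` — the base-2 logit of the beta-value.
#' Beta-values at or beyond the open interval (0, 1) are clamped to
#' `[eps, 1 - eps]` before the transform so degenerate inputs stay finite.
#'
#' @param beta Numeric vector of beta-values in `[0, 1]`.
#' @param eps Clamping epsilon; betas are pushed inside `[eps, 1 - eps]`.
#' @return Numeric vector of M-values.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(is.numeric(beta), is.numeric(eps), eps > 0, eps < 0.5)
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("beta values outside [0, 1]: ", paste(utils::head(beta[bad], 5), collapse = ", "))
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert methylation M-values to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`, always in (0, 1).
#'
#' @param m Numeric vector of finite M-values.
#' @return Numeric vector of beta-values in (0, 1).
#' @examples
#' m_to_beta(c(0, 2, -2)) # 0.5, 0.8, 0.2
#' @export
m_to_beta <- function(m) {
  stopifnot(is.numeric(m))
  # computed via plogis for numerical stability at large |m|
  stats::plogis(m * log(2))
}

#' Quantile-normalize a feature-by-sample matrix
#'
#' Forces every column (sample) to share the same empirical distribution:
#' the mean of the column order statistics. Within-column ranks are
#' preserved exactly; tied values receive the average of the target
#' quantiles over the tied ranks, which makes the result deterministic.
#'
#' @param x Numeric matrix, features in rows, samples in columns; no
#'   missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("quantile_normalize does not accept missing values")
  if (ncol(x) == 1L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(x)
  }
  if (nrow(x) == 0L) return(x)
  target <- rowMeans(apply(x, 2, sort, method = "quick"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    sorted <- x[o, j]
    # average target quantiles across runs of tied values
    runs <- rle(sorted)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    vals <- vapply(seq_along(ends), function(k) {
      mean(target[starts[k]:ends[k]])
    }, numeric(1))
    out[o, j] <- rep(vals, runs$lengths)
  }
  out
}

check_alignment <- function(x, detection, annotation) {
  stopifnot(is.matrix(x), is.matrix(detection))
  if (!identical(dim(x), dim(detection)) ||
      !identical(rownames(x), rownames(detection))) {
    off <- union(
      setdiff(rownames(x), rownames(detection)),
      setdiff(rownames(detection), rownames(x))
    )
    stop("detection table not aligned to matrix; offending probes: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  missing_ann <- setdiff(rownames(x), annotation$probe_id)
  if (length(missing_ann)) {
    stop("probes missing from annotation: ",
         paste(utils::head(missing_ann, 10), collapse = ", "))
  }
  invisible(TRUE)
}

#' Filter expression probes by detection, annotation flags and variance
#'
#' Applies the standard expression QC cascade: drop probes detected
#' (detection p below `detect_p`) in fewer than `detect_frac` of samples;
#' drop probes flagged as overlapping repetitive elements; drop probes
#' whose gene symbol starts with one of the uninformative-name prefixes
#' (KIAA, FLJ, HS, MGC, LOC; case-sensitive); finally drop probes in the
#' lowest `var_quantile` of variance, computed over the probes surviving
#' the earlier rules so that the percentile reflects the analyzable set.
#'
#' @param x Expression matrix (probes x samples, log2 scale).
#' @param detection Matrix of detection p-values aligned to `x`.
#' @param annotation Data frame with columns `probe_id`, `gene_symbol`,
#'   `repeat_overlap` (logical).
#' @param detect_p Detection p-value cut-off (default `1e-4`).
#' @param detect_frac Minimum fraction of samples in which a probe must be
#'   detected (default 0.10).
#' @param var_quantile Variance percentile below which probes are removed
#'   (default 0.10); strictly-below convention.
#' @param name_prefixes Character vector of gene-name prefixes to drop.
#' @return List with `matrix` (surviving probes) and `removed`, a tibble of
#'   per-rule removal counts.
#' @export
filter_expression_probes <- function(x, detection, annotation,
                                     detect_p = 1e-4, detect_frac = 0.10,
                                     var_quantile = 0.10,
                                     name_prefixes = c("KIAA", "FLJ", "HS", "MGC", "LOC")) {
  if (nrow(x) == 0L) {
    return(list(
      matrix = x,
      removed = tibble::tibble(
        rule = c("undetected", "repeat_overlap", "name_prefix", "low_variance"),
        n_removed = 0L
      )
    ))
  }
  check_alignment(x, detection, annotation)
  ann <- annotation[match(rownames(x), annotation$probe_id), , drop = FALSE]

  detected_frac <- rowMeans(detection < detect_p)
  rm_detect <- detected_frac < detect_frac
  rm_repeat <- as.logical(ann$repeat_overlap)
  prefix_re <- paste0("^(", paste(name_prefixes, collapse = "|"), ")")
  rm_name <- grepl(prefix_re, ann$gene_symbol)

  keep1 <- !(rm_detect | rm_repeat | rm_name)
  x1 <- x[keep1, , drop = FALSE]
  if (nrow(x1) > 0L) {
    v <- apply(x1, 1, stats::var)
    cut <- stats::quantile(v, var_quantile)
    rm_var <- v < cut
  } else {
    rm_var <- logical(0)
  }
  list(
    matrix = x1[!rm_var, , drop = FALSE],
    removed = tibble::tibble(
      rule = c("undetected", "repeat_overlap", "name_prefix", "low_variance"),
      n_removed = c(sum(rm_detect), sum(rm_repeat & !rm_detect),
                    sum(rm_name & !rm_detect & !rm_repeat), sum(rm_var))
    )
  )
}

#' Filter methylation probes by detection and annotation flags
#'
#' Drops CpGs detected (p below `detect_p`) in fewer than `detect_frac` of
#' samples, CpGs with a SNP within 10 bp of the targeted site, and CpGs
#' overlapping repetitive elements. A CpG detected in exactly
#' `detect_frac` of samples is retained (the rule removes strictly-below).
#'
#' @param x Methylation matrix (CpGs x samples).
#' @param detection Matrix of detection p-values aligned to `x`.
#' @param annotation Data frame with columns `probe_id`,
#'   `snp_within_10bp`, `repeat_overlap` (logical).
#' @param detect_p Detection p-value cut-off (default 0.05).
#' @param detect_frac Minimum detected fraction (default 0.90).
#' @return List with `matrix` and `removed` as in
#'   [filter_expression_probes()].
#' @export
filter_methylation_probes <- function(x, detection, annotation,
                                      detect_p = 0.05, detect_frac = 0.90) {
  if (nrow(x) == 0L) {
    return(list(
      matrix = x,
      removed = tibble::tibble(
        rule = c("undetected", "snp_within_10bp", "repeat_overlap"),
        n_removed = 0L
      )
    ))
  }
  check_alignment(x, detection, annotation)
  ann <- annotation[match(rownames(x), annotation$probe_id), , drop = FALSE]

  detected_frac <- rowMeans(detection < detect_p)
  rm_detect <- detected_frac < detect_frac
  rm_snp <- as.logical(ann$snp_within_10bp)
  rm_repeat <- as.logical(ann$repeat_overlap)
  keep <- !(rm_detect | rm_snp | rm_repeat)
  list(
    matrix = x[keep, , drop = FALSE],
    removed = tibble::tibble(
      rule = c("undetected", "snp_within_10bp", "repeat_overlap"),
      n_removed = c(sum(rm_detect), sum(rm_snp & !rm_detect),
                    sum(rm_repeat & !rm_detect & !rm_snp))
    )
  )
}
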