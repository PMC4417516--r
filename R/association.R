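#' @importFrom rlang .data
NULL

# Build a full-rank design matrix from a sample table. Categorical columns
# become treatment contrasts with the lexicographically first level as
# reference, so the encoding is deterministic regardless of input order.
build_design <- function(sample_table, columns, intercept = TRUE) {
  if (length(columns) == 0) {
    X <- matrix(1, nrow = nrow(sample_table), ncol = 1,
                dimnames = list(NULL, "(Intercept)"))
    return(if (intercept) X else X[, 0, drop = FALSE])
  }
  missing_cols <- setdiff(columns, names(sample_table))
  if (length(missing_cols)) {
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(sample_table[, columns, drop = FALSE])
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]], levels = sort(unique(as.character(df[[nm]]))))
    } else if (is.factor(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]], levels = sort(levels(df[[nm]])))
    }
    if (anyNA(df[[nm]])) stop("missing values in modeled column `", nm, "`")
  }
  # single-level factors carry no information; drop them rather than
  # letting model.matrix error
  keep <- vapply(df, function(v) !is.factor(v) || nlevels(droplevels(v)) > 1,
                 logical(1))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0) return(build_design(sample_table, character(0), intercept))
  fm <- stats::as.formula(paste("~", paste(names(df), collapse = " + ")))
  X <- stats::model.matrix(fm, df)
  if (!intercept) X <- X[, -1, drop = FALSE]
  X
}

ols_with_se <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - qr_x$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  list(coef = fit$coefficients, se = se, df = df, residuals = fit$residuals)
}

#' Covariate-adjusted linear association of one outcome with one predictor
#'
#' Ordinary least squares of `y` on `x` plus covariates, with a two-sided
#' t-test on the coefficient of `x` and the partial correlation obtained
#' by residualizing both `y` and `x` on the covariates (it collapses to
#' the Pearson correlation when there are none). Categorical covariates
#' are one-hot encoded against the lexicographically first level.
#'
#' @param y Numeric outcome vector.
#' @param x Numeric predictor vector.
#' @param covariates Optional data frame of covariate columns aligned with
#'   `y` and `x`.
#' @return One-row tibble: `estimate`, `se`, `statistic`, `p.value`,
#'   `partial_r`, `n`.
#' @export
fit_linear_association <- function(y, x, covariates = NULL) {
  stopifnot(is.numeric(y), is.numeric(x), length(y) == length(x))
  n <- length(y)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  C <- build_design(covariates, names(covariates), intercept = TRUE)
  X <- cbind(C[, 1, drop = FALSE], x = x, C[, -1, drop = FALSE])
  if (n <= ncol(X)) stop("fewer observations than model parameters")
  fit <- ols_with_se(X, y)
  est <- unname(fit$coef["x"])
  se <- unname(fit$se[which(colnames(X) == "x")])
  tval <- if (se > 0) est / se else sign(est) * Inf
  p <- if (is.finite(tval)) 2 * stats::pt(-abs(tval), fit$df) else
    (if (est == 0) 1 else 0)
  ry <- stats::lm.fit(C, y)$residuals
  rx <- stats::lm.fit(C, x)$residuals
  pr <- if (stats::sd(ry) > 0 && stats::sd(rx) > 0) stats::cor(ry, rx) else NA_real_
  tibble::tibble(estimate = est, se = se, statistic = tval, p.value = p,
                 partial_r = pr, n = n)
}

#' Genome-wide association scan of a matrix against a predictor
#'
#' Fits one covariate-adjusted linear model per feature (row), with the
#' named `predictor` column of the sample table as the exposure, and
#' appends Storey q-values over the whole scan. Zero-variance features
#' yield an `NA` row with a warning and are excluded from the FDR
#' computation. With `strata`, the scan is rerun within each subgroup and
#' results are stacked with a `stratum` column.
#'
#' @param features Numeric matrix, features x samples; column names must
#'   match `sample_table$sample_id` order.
#' @param sample_table Tibble of per-sample data.
#' @param predictor Name of the numeric predictor column (default "age").
#' @param covariates Character vector of covariate column names.
#' @param strata Optional name of a categorical column to stratify by.
#' @param pi0 Optional fixed null proportion passed to [qvalues()].
#' @return Tibble of class `association_scan`: `feature_id`, `estimate`,
#'   `se`, `statistic`, `p.value`, `q.value`, `partial_r`, `n`.
#' @export
scan_associations <- function(features, sample_table, predictor = "age",
                              covariates = character(0), strata = NULL,
                              pi0 = NULL) {
  stopifnot(is.matrix(features))
  if (!is.null(colnames(features)) && "sample_id" %in% names(sample_table)) {
    if (!identical(colnames(features), sample_table$sample_id)) {
      stop("feature matrix columns do not match sample table order")
    }
  }
  if (ncol(features) != nrow(sample_table)) {
    stop("feature matrix and sample table disagree on sample count")
  }
  if (!is.null(strata)) {
    levs <- sort(unique(as.character(sample_table[[strata]])))
    out <- purrr::map_dfr(levs, function(l) {
      sel <- sample_table[[strata]] == l
      res <- scan_associations(features[, sel, drop = FALSE],
                               sample_table[sel, , drop = FALSE],
                               predictor = predictor,
                               covariates = setdiff(covariates, strata),
                               pi0 = pi0)
      dplyr::mutate(res, stratum = l, .before = 1)
    })
    return(structure(out, class = c("association_scan", class(out))))
  }

  x <- sample_table[[predictor]]
  if (is.null(x)) stop("predictor column `", predictor, "` not found")
  C <- build_design(sample_table, covariates, intercept = TRUE)
  X <- cbind(C[, 1, drop = FALSE], x = x, C[, -1, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  n <- nrow(X)
  df <- n - qr_x$rank
  if (df <= 0) stop("fewer observations than model parameters")

  feat_var <- apply(features, 1, stats::var)
  ok <- is.finite(feat_var) & feat_var > 0
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance feature(s) returned as NA and excluded from FDR")
  }
  Y <- t(features[ok, , drop = FALSE])
  fit <- stats::lm.fit(X, Y)
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  x_pos <- which(colnames(X) == "x")
  se <- sqrt(pmax(sigma2 * xtx_inv[x_pos, x_pos], 0))
  est <- as.numeric(coefs[x_pos, ])
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- ifelse(is.finite(tval), 2 * stats::pt(-abs(tval), df),
              ifelse(est == 0, 1, 0))
  partial_r <- ifelse(is.finite(tval), tval / sqrt(tval^2 + df), sign(est))

  out <- tibble::tibble(
    feature_id = rownames(features),
    estimate = NA_real_, se = NA_real_, statistic = NA_real_,
    p.value = NA_real_, q.value = NA_real_, partial_r = NA_real_,
    n = as.integer(n)
  )
  out$estimate[ok] <- est
  out$se[ok] <- se
  out$statistic[ok] <- tval
  out$p.value[ok] <- p
  out$partial_r[ok] <- partial_r
  out$q.value[ok] <- qvalues(p, pi0 = pi0)
  structure(out, class = c("association_scan", class(out)))
}

#' Storey q-values from a p-value vector
#'
#' Estimates the null proportion pi0 from the p-value histogram — by
#' default `mean(p > lambda) / (1 - lambda)` at a fixed `lambda = 0.5`,
#' optionally by the smoother over a lambda grid — and converts p-values
#' to q-values by the step-up rule `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`.
#' The estimate is clamped to `[1/m, 1]`; with `pi0 = 1` the result equals
#' Benjamini-Hochberg adjusted p-values exactly. Output is monotone
#' non-decreasing in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter for the fixed-lambda pi0 estimate.
#' @param pi0 Optional fixed null proportion overriding estimation.
#' @param smoother If `TRUE`, estimate pi0 by a cubic-spline smoother over
#'   `lambda = 0.05, 0.10, ..., 0.95` evaluated at the right end.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
qvalues <- function(p, lambda = 0.5, pi0 = NULL, smoother = FALSE) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (smoother && m >= 20) {
      grid <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(grid, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(grid, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(grid))$y
    } else {
      pi0 <- mean(p > lambda) / (1 - lambda)
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[ro]
}

#' Enumerate cis CpG-gene pairs within a distance window
#'
#' A CpG is paired with every gene on the same chromosome whose anchor
#' (transcription start: `start` on the + strand, `end` on the -) lies
#' within `window` base pairs, boundary inclusive. Coordinates are
#' 0-based.
#'
#' @param cpg_annotation Tibble with `cpg_id`, `chrom`, `pos`.
#' @param gene_annotation Tibble with `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand`.
#' @param window Window size in bp (default 1 Mb).
#' @return Tibble: `cpg_id`, `gene_id`, `distance`.
#' @export
cis_pairs <- function(cpg_annotation, gene_annotation, window = 1e6) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(cpg_annotation)),
            all(c("gene_id", "chrom", "start", "end") %in% names(gene_annotation)))
  bad <- setdiff(unique(cpg_annotation$chrom), unique(gene_annotation$chrom))
  if (length(bad) > 0 || anyNA(cpg_annotation$chrom) || anyNA(gene_annotation$chrom)) {
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "))
  }
  genes <- gene_annotation
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$anchor <- ifelse(genes$strand == "-", genes$end, genes$start)
  dplyr::inner_join(
    cpg_annotation[, c("cpg_id", "chrom", "pos")],
    genes[, c("gene_id", "chrom", "anchor")],
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = abs(.data$anchor - .data$pos)) |>
    dplyr::filter(.data$distance <= window) |>
    dplyr::select("cpg_id", "gene_id", "distance")
}

#' Pulse pressure from repeated blood-pressure readings
#'
#' Blood pressure is defined as the average of the second and third
#' readings; pulse pressure is the averaged systolic minus the averaged
#' diastolic. The first reading is discarded by definition.
#'
#' @param readings List of at least three numeric length-2 vectors
#'   `(systolic, diastolic)` in mmHg, in measurement order.
#' @return Pulse pressure in mmHg.
#' @examples
#' pulse_pressure_from_readings(list(c(130, 80), c(128, 78), c(126, 76))) # 50
#' @export
pulse_pressure_from_readings <- function(readings) {
  if (!is.list(readings) || length(readings) < 3) {
    stop("need at least 3 (systolic, diastolic) readings")
  }
  r2 <- readings[[2]]; r3 <- readings[[3]]
  stopifnot(length(r2) >= 2, length(r3) >= 2)
  mean(c(r2[1], r3[1])) - mean(c(r2[2], r3[2]))
}

#' Scan expression as a predictor of a sample-level phenotype
#'
#' One linear model per gene with that gene's expression predicting the
#' phenotype, adjusted for covariates (age included by default so
#' phenotype associations are not mere age proxies); genome-wide Storey
#' q-values appended. Computed by the Frisch-Waugh-Lovell residualization,
#' so each per-gene fit matches a full OLS with the covariates.
#'
#' @param expr Expression matrix, genes x samples.
#' @param sample_table Tibble with the phenotype and covariate columns.
#' @param phenotype Name of the phenotype column (default
#'   "pulse_pressure").
#' @param covariates Character vector of covariate column names.
#' @param pi0 Optional fixed null proportion for [qvalues()].
#' @return `association_scan` tibble as in [scan_associations()].
#' @export
phenotype_scan <- function(expr, sample_table, phenotype = "pulse_pressure",
                           covariates = "age", pi0 = NULL) {
  stopifnot(is.matrix(expr))
  y <- sample_table[[phenotype]]
  if (is.null(y)) stop("phenotype column `", phenotype, "` not found")
  if (stats::var(y) == 0) stop("zero-variance phenotype `", phenotype, "`")
  C <- build_design(sample_table, covariates, intercept = TRUE)
  qc <- qr(C)
  ry <- stats::lm.fit(C, y)$residuals
  RX <- stats::lm.fit(C, t(expr))$residuals
  RX <- as.matrix(RX)
  sxx <- colSums(RX^2)
  ok <- sxx > 0
  if (any(!ok)) warning(sum(!ok), " zero-variance feature(s) returned as NA")
  df <- length(y) - qc$rank - 1L
  beta <- colSums(RX * ry) / sxx
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(pmax(rss / df, 0) / sxx)
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- ifelse(is.finite(tval), 2 * stats::pt(-abs(tval), df),
              ifelse(beta == 0, 1, 0))
  out <- tibble::tibble(
    feature_id = rownames(expr),
    estimate = ifelse(ok, beta, NA_real_),
    se = ifelse(ok, se, NA_real_),
    statistic = ifelse(ok, tval, NA_real_),
    p.value = ifelse(ok, p, NA_real_),
    q.value = NA_real_,
    partial_r = ifelse(ok, ifelse(is.finite(tval), tval / sqrt(tval^2 + df),
                                  sign(beta)), NA_real_),
    n = length(y)
  )
  out$q.value[ok] <- qvalues(out$p.value[ok], pi0 = pi0)
  structure(out, class = c("association_scan", class(out)))
}
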