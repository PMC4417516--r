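#' Biweight midcorrelation
#'
#' Robust correlation built from Tukey biweights around the median:
#' `u = (x - median(x)) / (9 * mad(x))`, weight `(1 - u^2)^2` for
#' `|u| < 1` and zero beyond, applied to median-centered values. Falls
#' back to the Pearson correlation (with a warning) for a vector whose
#' MAD is zero, where the biweight is undefined.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  m <- bicor_matrix(cbind(x = x, y = y))
  m["x", "y"]
}

# weights and centered values for one column of the biweight scheme;
# returns NULL when the MAD is zero (caller falls back to Pearson)
biweight_prepare <- function(v) {
  med <- stats::median(v)
  mad_v <- stats::mad(v, constant = 1)
  if (mad_v == 0) return(NULL)
  u <- (v - med) / (9 * mad_v)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xw <- (v - med) * w
  xw / sqrt(sum(xw^2))
}

#' Biweight midcorrelation matrix of the columns of a matrix
#'
#' Column-wise [bicor()]; columns with zero MAD are Pearson-standardized
#' instead, with one warning naming how many fell back.
#'
#' @param mat Numeric matrix, observations in rows, variables in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 4)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(utils::head(colnames(mat)[sds == 0], 5),
                                       collapse = ", "))
  }
  Z <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  fallback <- 0L
  for (j in seq_len(ncol(mat))) {
    zj <- biweight_prepare(mat[, j])
    if (is.null(zj)) {
      fallback <- fallback + 1L
      v <- mat[, j] - mean(mat[, j])
      zj <- v / sqrt(sum(v^2))
    }
    Z[, j] <- zj
  }
  if (fallback > 0) {
    warning(fallback, " column(s) had zero MAD; Pearson fallback used")
  }
  r <- crossprod(Z)
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

#' Choose a soft-thresholding power for approximate scale-free topology
#'
#' For each candidate power, connectivities `k_i = sum_j |cor_ij|^beta`
#' are binned on the log10 scale and `log10 p(k)` is regressed on
#' `log10 k`; the scale-free fit is the R-squared of that regression.
#' The smallest power whose fit reaches `rsq_cut` with a negative slope is
#' selected; if none qualifies — which happens whenever a few large,
#' equally connected modules dominate the degree distribution — the
#' conventional default power for unsigned networks at moderate sample
#' sizes (`fallback_power`, default 6) is used with a warning.
#'
#' @param cor_mat Gene-gene correlation matrix.
#' @param powers Integer grid of candidate powers (default 1:20).
#' @param rsq_cut Minimum scale-free fit R-squared (default 0.8).
#' @param n_bins Histogram bins for the degree distribution (default 10).
#' @param fallback_power Power used when no candidate qualifies.
#' @param min_mean_k Minimum mean connectivity for a power to qualify
#'   (default 1): unstructured data can reach high apparent scale-free
#'   fits at powers that leave the network essentially empty, and this
#'   floor excludes those degenerate solutions.
#' @return List with `power` (selected) and `fit` (tibble: power,
#'   rsq, slope, mean_k).
#' @export
pick_soft_threshold <- function(cor_mat, powers = 1:20, rsq_cut = 0.8,
                                n_bins = 10, fallback_power = 6,
                                min_mean_k = 1) {
  stopifnot(is.matrix(cor_mat), nrow(cor_mat) == ncol(cor_mat))
  ac <- abs(cor_mat)
  diag(ac) <- 0
  fit <- purrr::map_dfr(powers, function(beta) {
    k_all <- colSums(ac^beta)
    k <- k_all[k_all > 0]
    if (length(unique(k)) < 3) {
      return(tibble::tibble(power = beta, rsq = NA_real_, slope = NA_real_,
                            mean_k = mean(k_all)))
    }
    # bins on the linear connectivity scale (the canonical convention);
    # p(k) is the fraction of genes per occupied bin
    bin <- cut(k, n_bins)
    counts <- tapply(k, bin, length)
    centers <- tapply(k, bin, mean)
    keep <- !is.na(counts) & counts > 0
    if (sum(keep) < 3) {
      stop("fewer than 3 occupied connectivity bins at power ", beta)
    }
    lk <- log10(centers[keep])
    lp <- log10(counts[keep] / sum(counts[keep]))
    reg <- stats::lm(lp ~ lk)
    tibble::tibble(power = beta,
                   rsq = summary(reg)$r.squared,
                   slope = unname(stats::coef(reg)[2]),
                   mean_k = mean(colSums(ac^beta)))
  })
  good <- which(!is.na(fit$rsq) & fit$rsq >= rsq_cut & fit$slope < 0 &
                  fit$mean_k >= min_mean_k)
  if (length(good) > 0) {
    power <- fit$power[good[1]]
  } else {
    power <- fallback_power
    warning("no power reached scale-free fit R^2 >= ", rsq_cut,
            "; using the unsigned-network convention (power ", power, ")")
  }
  list(power = power, fit = fit)
}

#' Soft-thresholded (unsigned) adjacency matrix
#'
#' `a_ij = |cor_ij|^power` with unit diagonal.
#'
#' @param cor_mat Correlation matrix.
#' @param power Soft-thresholding power (>= 1).
#' @return Adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency <- function(cor_mat, power) {
  stopifnot(power >= 1)
  a <- abs(cor_mat)^power
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM: for `i != j`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1. Two genes overlap strongly when they are directly
#' connected and share neighbors.
#'
#' @param a Adjacency matrix from [adjacency()].
#' @return TOM matrix in `[0, 1]`, symmetric, unit diagonal.
#' @export
tom_similarity <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0            # L_ij includes u = i and u = j terms only via
  k <- colSums(a0)          # zeroed diagonal, so the sum skips them
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (L + a0) / denom
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  tom
}

# Recursive static-height tree cut: cut the subtree at the given quantile
# of its own merge heights; any branch big enough to host two clusters is
# re-examined with its own height distribution. Returns integer labels.
cut_tree_recursive <- function(hc, labels_in, d_mat, min_size, cut_quantile) {
  n <- length(labels_in)
  if (n < 2 * min_size) return(rep(1L, n))
  h_cut <- stats::quantile(hc$height, cut_quantile)
  cl <- stats::cutree(hc, h = h_cut)
  if (length(unique(cl)) == 1L) {
    # degenerate: cut above all merges; step down to the highest merge
    cl <- stats::cutree(hc, k = 2)
  }
  out <- integer(n)
  next_label <- 1L
  for (g in sort(unique(cl))) {
    idx <- which(cl == g)
    if (length(idx) >= 2 * min_size) {
      sub_d <- stats::as.dist(d_mat[idx, idx, drop = FALSE])
      sub_hc <- stats::hclust(sub_d, method = "average")
      sub <- cut_tree_recursive(sub_hc, labels_in[idx], d_mat[idx, idx, drop = FALSE],
                                min_size, cut_quantile)
      # only accept the sub-split if it found real substructure
      sub_sizes <- table(sub)
      if (sum(sub_sizes >= min_size) >= 2) {
        for (s in sort(unique(sub))) {
          out[idx[sub == s]] <- next_label
          next_label <- next_label + 1L
        }
        next
      }
    }
    out[idx] <- next_label
    next_label <- next_label + 1L
  }
  out
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut by a
#' deterministic static-height rule: the tree is cut at the `cut_quantile`
#' quantile of its merge heights, and every resulting branch large enough
#' to contain two modules is recursively re-cut against its own height
#' distribution until no further split yields two clusters of at least
#' `min_size` genes. Clusters below `min_size` become unassigned
#' (label 0); surviving modules are renumbered by decreasing size and
#' given conventional color names.
#'
#' After cutting, a cohesion cleanup pass expels weakly attached members:
#' a gene whose mean TOM similarity to the rest of its module falls below
#' half the module's median member similarity is moved to unassigned, and
#' the pass repeats until stable. This keeps loosely co-clustered
#' background genes from being absorbed into real modules while leaving
#' homogeneous modules untouched.
#'
#' @param dissim Dissimilarity matrix, typically `1 - tom_similarity(a)`.
#' @param min_size Minimum module size (default 10).
#' @param cut_quantile Quantile of merge heights at which to cut
#'   (default 0.99).
#' @return A `module_partition`: tibble with `gene_id`, `module` (integer,
#'   0 = unassigned) and `color`.
#' @export
detect_modules <- function(dissim, min_size = 10, cut_quantile = 0.99) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  genes <- rownames(dissim)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(dissim)))
  n <- nrow(dissim)
  if (n < min_size) {
    warning("fewer genes than min_size; all genes unassigned")
    return(new_module_partition(genes, rep(0L, n)))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  raw <- cut_tree_recursive(hc, seq_len(n), dissim, min_size, cut_quantile)
  raw <- cohesion_cleanup(raw, dissim)
  sizes <- table(raw[raw != 0L])
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(n)
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[as.character(keep)], keep)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  new_module_partition(genes, labels)
}

# expel module members whose mean within-module TOM similarity is under
# half the module's median member similarity; iterate to stability
cohesion_cleanup <- function(labels, dissim, max_iter = 10L) {
  sim <- 1 - dissim
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (m in setdiff(unique(labels), 0L)) {
      idx <- which(labels == m)
      if (length(idx) < 3) next
      sub <- sim[idx, idx, drop = FALSE]
      diag(sub) <- NA
      mg <- rowMeans(sub, na.rm = TRUE)
      drop <- mg < 0.5 * stats::median(mg)
      if (any(drop)) {
        labels[idx[drop]] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "black",
                   "red", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan")

new_module_partition <- function(genes, labels) {
  color <- ifelse(labels == 0L, "grey",
                  module_colors[((labels - 1L) %% length(module_colors)) + 1L])
  structure(
    tibble::tibble(gene_id = genes, module = as.integer(labels), color = color),
    class = c("module_partition", class(tibble::tibble()))
  )
}

#' Module eigengenes
#'
#' Per module: each gene is standardized to mean 0, sd 1 across samples;
#' the eigengene is the first right-singular vector of the standardized
#' genes-by-samples matrix (unit norm over samples), sign-oriented so that
#' it correlates non-negatively with the module's average standardized
#' expression. Variance explained is the first squared singular value over
#' the total.
#'
#' @param expr Expression matrix, genes x samples.
#' @param partition A `module_partition` from [detect_modules()].
#' @return Tibble with one row per (module, sample): `module`, `color`,
#'   `sample_id`, `eigengene`, `variance_explained`; also carries the
#'   sample-by-module score matrix in attribute `matrix`.
#' @export
module_eigengene <- function(expr, partition) {
  stopifnot(is.matrix(expr))
  mods <- sort(setdiff(unique(partition$module), 0L))
  samples <- colnames(expr)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(expr)))
  rows <- list()
  score_mat <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
                      dimnames = list(samples, paste0("ME", mods)))
  for (i in seq_along(mods)) {
    m <- mods[i]
    genes <- partition$gene_id[partition$module == m]
    genes <- intersect(genes, rownames(expr))
    if (length(genes) == 0) {
      warning("module ", m, " has no genes in the expression matrix; skipped")
      next
    }
    Z <- expr[genes, , drop = FALSE]
    Z <- (Z - rowMeans(Z)) / apply(Z, 1, stats::sd)
    sv <- svd(Z)
    eg <- sv$v[, 1]
    if (stats::cor(eg, colMeans(Z)) < 0) eg <- -eg
    ve <- sv$d[1]^2 / sum(sv$d^2)
    score_mat[, i] <- eg
    color <- partition$color[match(genes[1], partition$gene_id)]
    rows[[length(rows) + 1]] <- tibble::tibble(
      module = m, color = color, sample_id = samples,
      eigengene = eg, variance_explained = ve)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrix") <- score_mat
  out
}

#' Run the full network pipeline on an expression matrix
#'
#' Convenience chain: biweight midcorrelation, soft-threshold selection,
#' adjacency, TOM, module detection. Used by the consensus subsampling
#' machinery so every replicate runs the identical pipeline.
#'
#' @param expr Expression matrix, genes x samples.
#' @param min_size Minimum module size.
#' @param powers Candidate soft powers.
#' @param power Fixed soft power; if `NULL` (default) it is selected by
#'   [pick_soft_threshold()].
#' @param cut_quantile Tree-cut quantile for [detect_modules()].
#' @return List: `partition`, `power`, `fit` (NULL if `power` fixed).
#' @export
network_pipeline <- function(expr, min_size = 10, powers = 1:20, power = NULL,
                             cut_quantile = 0.99) {
  cor_mat <- suppressWarnings(bicor_matrix(t(expr)))
  fit <- NULL
  if (is.null(power)) {
    sel <- suppressWarnings(pick_soft_threshold(cor_mat, powers))
    power <- sel$power
    fit <- sel$fit
  }
  a <- adjacency(cor_mat, power)
  tom <- tom_similarity(a)
  partition <- detect_modules(1 - tom, min_size = min_size,
                              cut_quantile = cut_quantile)
  list(partition = partition, power = power, fit = fit)
}
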