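#' Select cell-type signature genes from reference profiles
#'
#' A gene belongs to a cell type's signature when its mean log2 expression
#' in that type exceeds the maximum over all other types by at least
#' `log2(fold)` (boundary inclusive: "at least four-fold") and itself
#' reaches `floor`. The max-over-others rule is the strictest reading of
#' "more highly expressed than in other cell populations".
#'
#' @param profiles Numeric matrix, cell types in rows, genes in columns,
#'   mean log2 expression.
#' @param fold Minimum fold difference over every other type (default 4).
#' @param floor Minimum log2 expression in the targeted type (default 0).
#' @return Named list, one character vector of gene ids per cell type.
#' @export
select_signature_genes <- function(profiles, fold = 4, floor = 0) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  if (fold <= 1) stop("`fold` must exceed 1")
  margin <- log2(fold)
  types <- rownames(profiles)
  if (is.null(types)) types <- paste0("celltype", seq_len(nrow(profiles)))
  out <- lapply(seq_len(nrow(profiles)), function(t) {
    others <- profiles[-t, , drop = FALSE]
    max_other <- apply(others, 2, max)
    sel <- (profiles[t, ] - max_other >= margin) & (profiles[t, ] >= floor)
    colnames(profiles)[sel]
  })
  names(out) <- types
  out
}

#' Running-sum enrichment score of a signature in one ranked list
#'
#' The classic unweighted (rank-only) statistic: walk the ranking from
#' most- to least-expressed, stepping up by `1/|signature|` at signature
#' genes and down by `1/(N - |signature|)` elsewhere; the score is the
#' signed maximum deviation of the running sum from zero. It lies in
#' `[-1, 1]`, equals 1 exactly when the signature occupies the top
#' `|signature|` positions, and depends only on ranks, so any strictly
#' monotone transform of the expression values leaves it unchanged.
#'
#' @param ranking Character vector, gene ids ordered from most to least
#'   expressed.
#' @param signature Character vector of signature gene ids, a non-empty
#'   proper subset of `ranking`.
#' @return Single numeric score in `[-1, 1]`.
#' @export
sample_enrichment_score <- function(ranking, signature) {
  n <- length(ranking)
  hits <- ranking %in% signature
  n_hit <- sum(hits)
  if (n_hit == 0L || n_hit == n) {
    stop("signature must be a non-empty proper subset of the ranking universe")
  }
  steps <- ifelse(hits, 1 / n_hit, -1 / (n - n_hit))
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Score every sample of a cohort against every cell-type signature
#'
#' For each sample, genes are ranked by decreasing expression (ties broken
#' lexicographically by gene id, so reruns are bit-identical) and the
#' running-sum score of each signature is computed. Signature genes absent
#' from the matrix are dropped with a warning; a signature with empty
#' intersection is an error.
#'
#' @param expr Expression matrix, genes x samples, log2 scale.
#' @param signatures Named list of gene-id vectors (e.g. from
#'   [select_signature_genes()] or [read_gmt()]).
#' @return Tibble with `sample_id` and one numeric score column per cell
#'   type, prefixed `score_`.
#' @export
score_cohort <- function(expr, signatures) {
  stopifnot(is.matrix(expr), is.list(signatures), length(signatures) > 0)
  universe <- rownames(expr)
  sigs <- lapply(names(signatures), function(nm) {
    s <- intersect(signatures[[nm]], universe)
    if (length(s) == 0L) {
      stop("signature `", nm, "` has no genes in the expression matrix")
    }
    dropped <- setdiff(signatures[[nm]], universe)
    if (length(dropped) > 0) {
      warning("signature `", nm, "`: dropped ", length(dropped),
              " gene(s) absent from the matrix")
    }
    s
  })
  names(sigs) <- names(signatures)
  scores <- matrix(NA_real_, nrow = ncol(expr), ncol = length(sigs),
                   dimnames = list(colnames(expr), names(sigs)))
  for (j in seq_len(ncol(expr))) {
    ranking <- universe[order(-expr[, j], universe, method = "radix")]
    for (t in seq_along(sigs)) {
      scores[j, t] <- sample_enrichment_score(ranking, sigs[[t]])
    }
  }
  out <- tibble::as_tibble(scores, rownames = "sample_id")
  names(out)[-1] <- paste0("score_", names(sigs))
  out
}
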