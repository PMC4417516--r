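#' Read a GMT gene-set file
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`. Duplicate
#' genes within a set are deduplicated with a warning; a line with fewer
#' than three fields is an error naming the line.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; set descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    nm <- fields[1]
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("set `", nm, "`: duplicate genes deduplicated")
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
    descs[nm] <- fields[2]
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT file")
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric overrepresentation test
#'
#' With `k` query genes in the target set, query size `n`, target size `K`
#' (after intersection with the background) and background size `N`:
#' fold enrichment is `(k/n) / (K/N)` and the p-value is the
#' hypergeometric upper tail `P[X >= k]`. With `ease = TRUE` the
#' DAVID-style EASE variant is used instead, penalizing the overlap by one
#' (`P[X >= k]` computed at `k - 1`).
#'
#' @param query Character vector of query genes (must lie in the
#'   background).
#' @param target Character vector, the gene set under test.
#' @param background Character vector, the gene universe.
#' @param ease Use the EASE score variant (default `FALSE`).
#' @return One-row tibble: `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p.value`.
#' @export
overrepresentation_test <- function(query, target, background, ease = FALSE) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    stop("query genes outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  target <- intersect(unique(target), background)
  k <- length(intersect(query, target))
  n <- length(query)
  K <- length(target)
  N <- length(background)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  k_eff <- if (ease) max(k - 1L, 0L) else k
  p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(k = k, n = n, K = K, N = N, fold_enrichment = fold,
                 p.value = p)
}

#' Overrepresentation of a query list across a gene-set collection
#'
#' One hypergeometric test per set with Benjamini-Hochberg FDR across the
#' collection, sorted by p-value.
#'
#' @param query Character vector of query genes.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector, the gene universe (all genes
#'   expressed and passing QC).
#' @param ease Use the EASE variant per test (default `FALSE`).
#' @return Tibble of class `enrichment_result`: `set`, `k`, `n`, `K`,
#'   `N`, `fold_enrichment`, `p.value`, `fdr`.
#' @export
enrich_collection <- function(query, collection, background, ease = FALSE) {
  stopifnot(is.list(collection), length(collection) > 0)
  res <- purrr::map_dfr(names(collection), function(nm) {
    dplyr::bind_cols(
      tibble::tibble(set = nm),
      overrepresentation_test(query, collection[[nm]], background, ease = ease))
  })
  res$fdr <- stats::p.adjust(res$p.value, method = "BH")
  res <- dplyr::arrange(res, .data$p.value)
  structure(res, class = c("enrichment_result", class(res)))
}
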