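#' Co-membership network of a module partition
#'
#' The unweighted graph in which two genes are joined by an edge exactly
#' when they carry the same non-zero module label; unassigned genes
#' (label 0) contribute no edges. Edges are stored as integer codes over
#' the fixed, ordered gene universe so that set operations across many
#' networks stay cheap.
#'
#' @param partition A `module_partition` (tibble with `gene_id`,
#'   `module`), or any data frame with those columns.
#' @param universe Optional character vector fixing the gene universe and
#'   its order; defaults to `partition$gene_id`.
#' @return Object of class `co_membership`: list with `universe` and
#'   sorted integer `edges`.
#' @export
co_membership_network <- function(partition, universe = NULL) {
  if (is.null(universe)) universe <- partition$gene_id
  idx <- match(partition$gene_id, universe)
  if (anyNA(idx)) stop("partition contains genes outside the universe")
  labels <- partition$module
  edges <- integer(0)
  for (m in setdiff(unique(labels), 0L)) {
    members <- sort(idx[labels == m])
    k <- length(members)
    if (k < 2) next
    pairs <- utils::combn(members, 2)
    edges <- c(edges, encode_edges(pairs[1, ], pairs[2, ], length(universe)))
  }
  new_co_membership(universe, sort(edges))
}

encode_edges <- function(i, j, n) (i - 1) * n + j  # requires i < j

decode_edges <- function(edges, universe) {
  n <- length(universe)
  i <- (edges - 1) %/% n + 1
  j <- edges - (i - 1) * n
  tibble::tibble(gene_a = universe[i], gene_b = universe[j])
}

new_co_membership <- function(universe, edges) {
  structure(list(universe = universe, edges = edges), class = "co_membership")
}

#' @export
print.co_membership <- function(x, ...) {
  cat(sprintf("Co-membership network: %d genes, %d edges\n",
              length(x$universe), length(x$edges)))
  invisible(x)
}

#' Jaccard index between two co-membership networks
#'
#' Shared edges divided by the union of edges. Both networks must be over
#' the same gene universe. Two empty networks are identical structures, so
#' their Jaccard index is 1 by convention.
#'
#' @param a,b `co_membership` networks over the same universe.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "co_membership"), inherits(b, "co_membership"))
  if (!identical(a$universe, b$universe)) {
    stop("networks are defined over different gene universes")
  }
  n_union <- length(union(a$edges, b$edges))
  if (n_union == 0) return(1)
  length(intersect(a$edges, b$edges)) / n_union
}

#' Module partitions from repeated subsampling of the cohort
#'
#' Each replicate draws `floor(fraction * n)` samples without replacement
#' and runs the complete network pipeline on the subset — biweight
#' midcorrelation, per-replicate soft-power selection, TOM, module
#' detection — mirroring a full re-analysis of the reduced cohort.
#' Replicate sub-seeds are drawn once from the master seed and recorded,
#' so the whole list is reproducible bit-for-bit.
#'
#' @param expr Expression matrix, genes x samples.
#' @param fraction Subsample fraction in (0, 1]; 1 disables subsampling.
#' @param reps Number of replicates.
#' @param seed Master integer seed.
#' @param min_n Minimum viable subsample size (default 30).
#' @param min_size,powers,power,cut_quantile Passed to
#'   [network_pipeline()]; set `power` to freeze the soft power across
#'   replicates instead of re-selecting it.
#' @return List of `module_partition` objects with attribute `sub_seeds`.
#' @export
subsample_partitions <- function(expr, fraction = 0.8, reps = 200, seed = 1L,
                                 min_n = 30, min_size = 10, powers = 1:20,
                                 power = NULL, cut_quantile = 0.99) {
  stopifnot(is.matrix(expr), fraction > 0, fraction <= 1, reps >= 1)
  n <- ncol(expr)
  n_sub <- floor(fraction * n)
  if (n_sub < min_n) {
    stop("subsample size ", n_sub, " below minimum viable n (", min_n, ")")
  }
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, reps))
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    out[[r]] <- withr::with_seed(sub_seeds[r], {
      cols <- if (fraction < 1) sort(sample.int(n, n_sub)) else seq_len(n)
      network_pipeline(expr[, cols, drop = FALSE], min_size = min_size,
                       powers = powers, power = power,
                       cut_quantile = cut_quantile)$partition
    })
  }
  attr(out, "sub_seeds") <- sub_seeds
  out
}

#' Consensus network from a list of co-membership networks
#'
#' Keeps an edge when it occurs in at least `ceiling(threshold * R)` of
#' the `R` input networks, the boundary inclusive ("at least 70%" keeps
#' an edge present in exactly 140 of 200 networks).
#'
#' @param networks Non-empty list of `co_membership` networks over one
#'   universe.
#' @param threshold Required fraction of networks, in (0, 1].
#' @return A `co_membership` consensus network.
#' @export
consensus_network <- function(networks, threshold = 0.70) {
  if (length(networks) == 0) stop("empty network list")
  stopifnot(threshold > 0, threshold <= 1)
  universe <- networks[[1]]$universe
  for (nw in networks) {
    if (!identical(nw$universe, universe)) {
      stop("networks are defined over different gene universes")
    }
  }
  all_edges <- unlist(lapply(networks, `[[`, "edges"))
  if (length(all_edges) == 0) return(new_co_membership(universe, integer(0)))
  counts <- table(all_edges)
  need <- ceiling(threshold * length(networks))
  keep <- as.numeric(names(counts)[counts >= need])
  new_co_membership(universe, sort(keep))
}

#' Modules from a consensus network's connected components
#'
#' Every connected component with at least two genes becomes a module;
#' isolated genes are unassigned. No minimum module size is applied —
#' consensus modules may legitimately be as small as a pair. Labels are
#' assigned by decreasing component size.
#'
#' @param network A `co_membership` network.
#' @return A `module_partition` tibble.
#' @export
consensus_modules <- function(network) {
  stopifnot(inherits(network, "co_membership"))
  universe <- network$universe
  if (length(network$edges) == 0) {
    return(new_module_partition(universe, rep(0L, length(universe))))
  }
  el <- decode_edges(network$edges, universe)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = universe))
  comp <- igraph::components(g)
  labels <- integer(length(universe))
  sizes <- comp$csize
  real <- which(sizes >= 2)
  ord <- real[order(-sizes[real], real)]
  membership <- comp$membership[match(universe, igraph::V(g)$name)]
  for (i in seq_along(ord)) labels[membership == ord[i]] <- i
  new_module_partition(universe, labels)
}

#' Full stability analysis of module detection under subsampling
#'
#' Runs the network pipeline on the complete data, builds `reps`
#' subsampled replicate partitions, computes the Jaccard index of each
#' replicate's co-membership network against the full-data network, forms
#' the consensus network at `threshold`, and extracts consensus modules.
#' With `consensus_reps > 1` the entire procedure is repeated that many
#' times with independent seeds and the pairwise Jaccard indices between
#' consensus networks are reported — the stability contrast between
#' individual replicate networks (typically low) and consensus networks
#' (typically high).
#'
#' @param expr Expression matrix, genes x samples.
#' @param fraction Subsample fraction (default 0.8).
#' @param reps Replicates per consensus (default 200).
#' @param threshold Consensus edge-retention fraction (default 0.70).
#' @param seed Master seed.
#' @param consensus_reps Number of independent consensus networks
#'   (default 1).
#' @param ... Passed to [subsample_partitions()].
#' @return Object of class `stability_report`: list with `replicate_jaccard`
#'   (tibble), `mean_jaccard`, `consensus` network, `consensus_partition`,
#'   `consensus_pairwise_jaccard` (tibble, when `consensus_reps > 1`),
#'   `full_partition`, and the configuration used.
#' @export
stability_report <- function(expr, fraction = 0.8, reps = 200,
                             threshold = 0.70, seed = 1L,
                             consensus_reps = 1L, ...) {
  full <- network_pipeline(expr, ...)
  universe <- rownames(expr)
  full_net <- co_membership_network(full$partition, universe)

  master_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max, consensus_reps))
  cons_nets <- vector("list", consensus_reps)
  rep_jaccard <- NULL
  for (cr in seq_len(consensus_reps)) {
    parts <- subsample_partitions(expr, fraction = fraction, reps = reps,
                                  seed = master_seeds[cr], ...)
    nets <- lapply(parts, co_membership_network, universe = universe)
    jac <- vapply(nets, jaccard_index, numeric(1), b = full_net)
    if (cr == 1L) {
      rep_jaccard <- tibble::tibble(replicate = seq_len(reps), jaccard = jac,
                                    sub_seed = attr(parts, "sub_seeds"))
    }
    cons_nets[[cr]] <- consensus_network(nets, threshold)
  }
  pairwise <- NULL
  if (consensus_reps > 1) {
    combs <- utils::combn(consensus_reps, 2)
    pairwise <- tibble::tibble(
      consensus_a = combs[1, ], consensus_b = combs[2, ],
      jaccard = apply(combs, 2, function(ij) {
        jaccard_index(cons_nets[[ij[1]]], cons_nets[[ij[2]]])
      })
    )
  }
  structure(list(
    replicate_jaccard = rep_jaccard,
    mean_jaccard = mean(rep_jaccard$jaccard),
    consensus = cons_nets[[1]],
    consensus_networks = cons_nets,
    consensus_partition = consensus_modules(cons_nets[[1]]),
    consensus_pairwise_jaccard = pairwise,
    full_partition = full$partition,
    config = list(fraction = fraction, reps = reps, threshold = threshold,
                  seed = seed, consensus_reps = consensus_reps)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Module-stability report\n")
  cat(sprintf("  %d replicates at %.0f%% subsampling, consensus threshold %.2f\n",
              x$config$reps, 100 * x$config$fraction, x$config$threshold))
  cat(sprintf("  mean replicate-vs-full Jaccard: %.3f\n", x$mean_jaccard))
  cat(sprintf("  consensus network: %d edges, %d modules\n",
              length(x$consensus$edges),
              max(x$consensus_partition$module)))
  if (!is.null(x$consensus_pairwise_jaccard)) {
    cat(sprintf("  mean consensus-vs-consensus Jaccard: %.3f\n",
                mean(x$consensus_pairwise_jaccard$jaccard)))
  }
  invisible(x)
}
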