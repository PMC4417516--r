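make_partition <- function(universe, assignment) {
  tibble::tibble(gene_id = universe,
                 module = assignment[universe],
                 color = "grey")
}

test_that("co-membership networks enumerate within-module pairs", {
  uni <- c("a", "b", "c", "d", "e")
  part <- make_partition(uni, c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L))
  nw <- co_membership_network(part)
  expect_equal(length(nw$edges), 4) # C(3,2) + C(2,2)
  # all unassigned -> no edges
  none <- make_partition(uni, setNames(rep(0L, 5), uni))
  expect_equal(length(co_membership_network(none)$edges), 0)
  # one module of k genes -> k(k-1)/2 edges
  k <- 7
  unik <- paste0("g", 1:k)
  allone <- tibble::tibble(gene_id = unik, module = 1L, color = "grey")
  expect_equal(length(co_membership_network(allone)$edges), k * (k - 1) / 2)
})

test_that("Jaccard index covers identity, disjointness and mixed overlap", {
  uni <- c("a", "b", "c", "d")
  nA <- co_membership_network(make_partition(uni, c(a = 1L, b = 1L, c = 1L, d = 0L)))
  expect_equal(jaccard_index(nA, nA), 1)

  # disjoint edge sets
  n1 <- co_membership_network(make_partition(uni, c(a = 1L, b = 1L, c = 0L, d = 0L)))
  n2 <- co_membership_network(make_partition(uni, c(a = 0L, b = 0L, c = 1L, d = 1L)))
  expect_equal(jaccard_index(n1, n2), 0)

  # E_A = {ab, bc}, E_B = {ab, cd} -> 1/3
  eA <- agingtx:::new_co_membership(uni, sort(c(
    agingtx:::encode_edges(1, 2, 4), agingtx:::encode_edges(2, 3, 4))))
  eB <- agingtx:::new_co_membership(uni, sort(c(
    agingtx:::encode_edges(1, 2, 4), agingtx:::encode_edges(3, 4, 4))))
  expect_equal(jaccard_index(eA, eB), 1 / 3)

  # both empty -> 1 by convention
  e0 <- agingtx:::new_co_membership(uni, integer(0))
  expect_equal(jaccard_index(e0, e0), 1)

  # symmetry on random partitions
  withr::with_seed(41, {
    for (i in 1:10) {
      pa <- random_partition(uni, 2, seed = i)
      pb <- random_partition(uni, 2, seed = i + 100)
      na <- co_membership_network(pa)
      nb <- co_membership_network(pb)
      expect_equal(jaccard_index(na, nb), jaccard_index(nb, na))
    }
  })

  expect_error(jaccard_index(nA, agingtx:::new_co_membership(uni[1:3], integer(0))),
               "universes")
})

test_that("consensus edge retention uses the inclusive ceiling boundary", {
  uni <- c("a", "b", "c")
  edge_ab <- agingtx:::encode_edges(1, 2, 3)
  with_edge <- agingtx:::new_co_membership(uni, edge_ab)
  without <- agingtx:::new_co_membership(uni, integer(0))

  nets_140 <- c(rep(list(with_edge), 140), rep(list(without), 60))
  expect_equal(consensus_network(nets_140, 0.70)$edges, edge_ab)
  nets_139 <- c(rep(list(with_edge), 139), rep(list(without), 61))
  expect_equal(length(consensus_network(nets_139, 0.70)$edges), 0)

  # identical inputs -> consensus equals each input
  expect_equal(consensus_network(rep(list(with_edge), 10), 0.70)$edges,
               with_edge$edges)
  # monotone: raising the threshold never adds edges
  withr::with_seed(43, {
    nets <- lapply(1:20, function(i) {
      co_membership_network(random_partition(paste0("g", 1:12), 3, seed = i))
    })
  })
  e_strict <- consensus_network(nets, 1.0)$edges
  e_loose <- consensus_network(nets, 0.7)$edges
  expect_true(all(e_strict %in% e_loose))
  expect_error(consensus_network(list(), 0.7), "empty")
})

test_that("consensus modules are connected components with no minimum size", {
  uni <- c("a", "b", "c", "d", "e")
  n <- agingtx:::new_co_membership(uni, sort(c(
    agingtx:::encode_edges(1, 2, 5), agingtx:::encode_edges(2, 3, 5))))
  part <- consensus_modules(n)
  expect_equal(part$module[match(c("a", "b", "c"), part$gene_id)], rep(1L, 3))
  expect_equal(part$module[match(c("d", "e"), part$gene_id)], rep(0L, 2))

  # two size-2 components allowed
  n2 <- agingtx:::new_co_membership(uni, sort(c(
    agingtx:::encode_edges(1, 2, 5), agingtx:::encode_edges(3, 4, 5))))
  p2 <- consensus_modules(n2)
  expect_equal(sort(table(p2$module[p2$module > 0])), sort(table(c(1, 1, 2, 2))))

  # empty network -> all unassigned
  p0 <- consensus_modules(agingtx:::new_co_membership(uni, integer(0)))
  expect_true(all(p0$module == 0L))
})

test_that("subsampling with fraction 1 reproduces the full-data partition", {
  co <- two_block_cohort()
  expr <- co$expression[, 1:60]
  full <- suppressWarnings(network_pipeline(expr))
  parts <- suppressWarnings(
    subsample_partitions(expr, fraction = 1, reps = 3, seed = 50))
  for (p in parts) expect_identical(p, full$partition)
  # reruns with the same master seed are bit-identical
  parts2 <- suppressWarnings(
    subsample_partitions(expr, fraction = 1, reps = 3, seed = 50))
  expect_identical(parts, parts2)
  expect_error(subsample_partitions(expr, fraction = 0.1, reps = 2, seed = 1),
               "minimum viable")
})

test_that("stability report contrasts replicate and consensus stability", {
  co <- two_block_cohort()
  expr <- co$expression
  rep <- suppressWarnings(
    stability_report(expr, fraction = 0.8, reps = 12, threshold = 0.70,
                     seed = 60, consensus_reps = 2))
  expect_equal(nrow(rep$replicate_jaccard), 12)
  expect_true(all(rep$replicate_jaccard$jaccard >= 0 &
                    rep$replicate_jaccard$jaccard <= 1))
  expect_gte(rep$mean_jaccard, min(rep$replicate_jaccard$jaccard))
  expect_lte(rep$mean_jaccard, max(rep$replicate_jaccard$jaccard))
  expect_equal(nrow(rep$consensus_pairwise_jaccard), 1)
  # strong two-block structure: replicates agree with the full network
  expect_gte(rep$mean_jaccard, 0.8)
  # consensus partition recovers the planted blocks at least as well as a
  # typical replicate
  truth <- co$ground_truth$gene$module
  cons_ari <- ari(rep$consensus_partition$module, truth)
  expect_gte(cons_ari, 0.9)
  # tidy/glance interface
  expect_equal(nrow(tidy(rep)), 12)
  expect_equal(glance(rep)$reps, 12)
})
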