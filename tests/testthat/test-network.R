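test_that("bicor has correlation fixed points and matches Pearson on clean data", {
  withr::with_seed(30, x <- rnorm(100))
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  withr::with_seed(31, {
    z <- matrix(rnorm(2000 * 2), ncol = 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
  })
  expect_lt(abs(bicor(z[, 1], z[, 2]) - cor(z[, 1], z[, 2])), 0.03)
  # robust to a gross outlier where Pearson is not
  withr::with_seed(32, {
    a <- rnorm(100); b <- 0.8 * a + 0.6 * rnorm(100)
  })
  a_out <- c(a, 50); b_out <- c(b, -50)
  expect_lt(abs(bicor(a_out, b_out) - 0.8), 0.15)
  expect_lt(cor(a_out, b_out), 0)
  # zero MAD falls back to Pearson with a warning
  spiky <- c(rep(0, 96), 1, 2, 3, 4)
  expect_warning(r <- bicor(spiky, rnorm(100)), "MAD")
  expect_true(is.finite(r))
})

test_that("adjacency is the power of absolute correlation", {
  withr::with_seed(33, m <- matrix(rnorm(200), ncol = 5))
  cm <- cor(m)
  expect_equal(unname(adjacency(cm, 1) - diag(5)),
               unname(abs(cm) - diag(5) * 1), tolerance = 1e-12)
  a6 <- adjacency(cm, 6)
  expect_true(all(a6 <= abs(cm) + 1e-12))
  expect_equal(unname(diag(a6)), rep(1, 5))
  cm0 <- cm; cm0[1, 2] <- cm0[2, 1] <- 0
  expect_equal(adjacency(cm0, 3)[1, 2], 0)
})

test_that("TOM matches closed-form values on canonical small graphs", {
  # fully connected 3-node graph
  a <- matrix(1, 3, 3)
  expect_equal(unname(tom_similarity(a)), matrix(1, 3, 3))
  # empty off-diagonal
  a0 <- diag(3)
  expect_equal(unname(tom_similarity(a0) - diag(3)), matrix(0, 3, 3))
  # 3-node chain: a12 = a23 = 0.5, a13 = 0 -> TOM12 = 0.5
  ch <- diag(3)
  ch[1, 2] <- ch[2, 1] <- 0.5
  ch[2, 3] <- ch[3, 2] <- 0.5
  tom <- tom_similarity(ch)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(tom[1, 3], (0.25 + 0) / (0.5 + 1 - 0))
})

test_that("TOM equals the brute-force triple-loop oracle on random inputs", {
  withr::with_seed(34, {
    for (trial in 1:50) {
      n <- sample(3:10, 1)
      a <- matrix(runif(n * n), n, n)
      a <- (a + t(a)) / 2
      diag(a) <- 1
      expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-10)
    }
  })
})

test_that("adjacency and TOM are symmetric to machine precision", {
  co <- two_block_cohort()
  cm <- suppressWarnings(bicor_matrix(t(co$expression[1:40, ])))
  a <- adjacency(cm, 6)
  tom <- tom_similarity(a)
  expect_lt(max(abs(a - t(a))), 1e-12)
  expect_lt(max(abs(tom - t(tom))), 1e-12)
  expect_true(all(tom >= 0 & tom <= 1))
})

test_that("soft threshold selection prefers scale-free fits and falls back sanely", {
  # hub-hierarchy structure: loadings decay within modules, sizes decay
  withr::with_seed(42, {
    n <- 300
    sizes <- c(120, 80, 55, 38, 26, 18, 12, 8, 6, 4)
    G <- sum(sizes) + 130
    X <- matrix(rnorm(n * G), nrow = n)
    g0 <- 0
    for (m in seq_along(sizes)) {
      f <- rnorm(n)
      l <- sqrt(seq(0.9, 0.15, length.out = sizes[m]))
      for (j in seq_len(sizes[m])) {
        X[, g0 + j] <- l[j] * f + sqrt(1 - l[j]^2) * rnorm(n)
      }
      g0 <- g0 + sizes[m]
    }
    colnames(X) <- paste0("g", seq_len(G))
  })
  sel <- pick_soft_threshold(suppressWarnings(bicor_matrix(X)))
  chosen <- sel$fit[sel$fit$power == sel$power, ]
  expect_gte(chosen$rsq, 0.8)
  expect_lt(chosen$slope, 0)
  # mean connectivity strictly decreasing in power
  expect_true(all(diff(sel$fit$mean_k) < 0))

  # independent noise takes the warning path
  withr::with_seed(5, {
    Xn <- matrix(rnorm(200 * 150), nrow = 200)
    colnames(Xn) <- paste0("g", 1:150)
  })
  expect_warning(pick_soft_threshold(suppressWarnings(bicor_matrix(Xn))),
                 "no power reached")
})

test_that("two planted blocks are recovered exactly", {
  co <- two_block_cohort()
  cm <- suppressWarnings(bicor_matrix(t(co$expression)))
  part <- detect_modules(1 - tom_similarity(adjacency(cm, 6)))
  expect_equal(ari(part$module, co$ground_truth$gene$module), 1)
  # deterministic rerun
  part2 <- detect_modules(1 - tom_similarity(adjacency(cm, 6)))
  expect_identical(part, part2)
})

test_that("blocks below min_size stay unassigned", {
  cfg <- cohort_config(n_samples = 300, n_genes = 40, n_cpgs = 5, n_modules = 1,
                       module_sizes = 5L, within_module_cor = 0.9,
                       frac_age_genes = 0, n_mediation_triples = 0,
                       n_cell_types = 0, covariate_effects = FALSE, seed = 6)
  co <- generate_cohort(cfg)
  cm <- suppressWarnings(bicor_matrix(t(co$expression)))
  part <- detect_modules(1 - tom_similarity(adjacency(cm, 6)), min_size = 10)
  planted <- co$ground_truth$gene$module == 1
  expect_true(all(part$module[planted] == 0))
  # fewer genes than min_size
  expect_warning(p2 <- detect_modules(matrix(0.5, 3, 3) + 0.5 * diag(3),
                                      min_size = 10),
                 "unassigned")
  expect_true(all(p2$module == 0))
})

test_that("module labels are ordered by size and colored conventionally", {
  co <- default_cohort()
  net <- suppressWarnings(network_pipeline(co$expression))
  part <- net$partition
  sizes <- table(part$module[part$module > 0])
  expect_true(all(diff(as.numeric(sizes)) <= 0))
  expect_identical(unique(part$color[part$module == 1]), "turquoise")
  expect_identical(unique(part$color[part$module == 0]), "grey")
})

test_that("eigengenes match a dense SVD oracle and explain variance sensibly", {
  co <- two_block_cohort()
  expr <- co$expression
  part <- tibble::tibble(
    gene_id = rownames(expr)[1:20], module = 1L, color = "turquoise")
  eg <- module_eigengene(expr, part)
  # oracle: dense SVD of the standardized matrix
  Z <- expr[1:20, ]
  Z <- (Z - rowMeans(Z)) / apply(Z, 1, sd)
  sv <- svd(Z)
  v1 <- sv$v[, 1]
  if (cor(v1, colMeans(Z)) < 0) v1 <- -v1
  expect_lt(max(abs(eg$eigengene - v1)), 1e-8)
  expect_equal(unique(eg$variance_explained), sv$d[1]^2 / sum(sv$d^2))
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-10)

  # single-gene module: eigengene is the standardized profile / sqrt(n)
  p1 <- tibble::tibble(gene_id = rownames(expr)[1], module = 1L,
                       color = "turquoise")
  eg1 <- module_eigengene(expr, p1)
  z <- unname(scale(expr[1, ])[, 1])
  expect_equal(eg1$eigengene, z / sqrt(sum(z^2)), tolerance = 1e-10)
  expect_equal(unique(eg1$variance_explained), 1)

  # two perfectly correlated genes
  dup <- rbind(g1 = expr[1, ], g2 = 2 * expr[1, ] + 3)
  p2 <- tibble::tibble(gene_id = c("g1", "g2"), module = 1L, color = "blue")
  eg2 <- module_eigengene(dup, p2)
  expect_equal(unique(eg2$variance_explained), 1, tolerance = 1e-12)
})

test_that("eigengene-age association recovers the planted module-age signs", {
  co <- default_cohort()
  net <- suppressWarnings(network_pipeline(co$expression))
  truth <- co$ground_truth$gene
  eg <- module_eigengene(co$expression, net$partition)
  rep <- eigengene_age_report(eg, co$samples,
                              covariates = c("sex", "race", "site"))
  # map detected modules to planted ones by overlap, then compare signs
  gamma <- c(0.3, -0.3, 0.3, -0.3, 0.3)
  n_checked <- 0
  for (m in sort(unique(net$partition$module[net$partition$module > 0]))) {
    genes <- net$partition$gene_id[net$partition$module == m]
    planted <- truth$module[match(genes, truth$gene_id)]
    main <- as.integer(names(which.max(table(planted[planted > 0]))))
    if (length(main) == 0 || mean(planted == main) < 0.8) next
    got <- rep$table$partial_r[rep$table$module == m]
    expect_equal(sign(got), sign(gamma[main]))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 4)
})
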