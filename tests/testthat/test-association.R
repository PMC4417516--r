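test_that("noiseless fit recovers slope with zero standard error", {
  x <- seq(1, 10, length.out = 50)
  f <- fit_linear_association(0.5 * x, x)
  expect_equal(f$estimate, 0.5, tolerance = 1e-12)
  expect_lt(f$se, 1e-10)
  expect_equal(f$p.value, 0)
})

test_that("partial correlation collapses to Pearson without covariates", {
  withr::with_seed(14, {
    x <- rnorm(80)
    y <- 0.4 * x + rnorm(80)
  })
  f <- fit_linear_association(y, x)
  expect_equal(f$partial_r, cor(x, y), tolerance = 1e-12)
  expect_equal(sign(f$partial_r), sign(f$estimate))
})

test_that("null p-values are uniform across simulated scans", {
  withr::with_seed(15, {
    p <- vapply(1:1000, function(i) {
      x <- rnorm(200)
      y <- rnorm(200)
      fit_linear_association(y, x)$p.value
    }, numeric(1))
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("fit residuals are orthogonal to the design", {
  withr::with_seed(16, {
    n <- 100
    covs <- data.frame(sex = sample(c("F", "M"), n, TRUE), z = rnorm(n))
    x <- rnorm(n)
    y <- 0.3 * x + 0.5 * (covs$sex == "M") + rnorm(n)
  })
  C <- agingtx:::build_design(covs, names(covs))
  X <- cbind(C, x = x)
  res <- stats::lm.fit(X, y)$residuals
  Xs <- scale(X[, -1])
  expect_lt(max(abs(crossprod(Xs, res) / n)), 1e-8)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  x <- rnorm(50)
  covs <- data.frame(dup = 2 * x)
  expect_error(fit_linear_association(rnorm(50), x, covs), "collinear")
})

test_that("scan matches per-feature fits and handles zero-variance rows", {
  co <- generate_cohort(cohort_config(n_samples = 80, n_genes = 30, n_cpgs = 5,
                                      n_modules = 0, module_sizes = integer(0),
                                      frac_age_genes = 0.5,
                                      n_mediation_triples = 0, n_cell_types = 0,
                                      seed = 17))
  covs <- c("sex", "site")
  sc <- scan_associations(co$expression, co$samples, covariates = covs)
  f3 <- fit_linear_association(co$expression[3, ], co$samples$age,
                               as.data.frame(co$samples[, covs]))
  expect_equal(sc$estimate[3], f3$estimate, tolerance = 1e-10)
  expect_equal(sc$se[3], f3$se, tolerance = 1e-10)
  expect_equal(sc$p.value[3], f3$p.value, tolerance = 1e-10)
  expect_equal(sc$partial_r[3], f3$partial_r, tolerance = 1e-10)

  flat <- co$expression
  flat[5, ] <- 2
  expect_warning(sc2 <- scan_associations(flat, co$samples, covariates = covs),
                 "zero-variance")
  expect_true(is.na(sc2$estimate[5]))
  expect_false(anyNA(sc2$q.value[-5]))

  # single-feature scan reduces to the fit with q = pi0 * p
  sc1 <- scan_associations(co$expression[3, , drop = FALSE], co$samples,
                           covariates = covs)
  expect_equal(sc1$q.value, min(1, sc1$p.value * 1))
})

test_that("stratified scans pool to the full-cohort estimate", {
  co <- generate_cohort(cohort_config(n_samples = 400, n_genes = 20, n_cpgs = 5,
                                      n_modules = 0, module_sizes = integer(0),
                                      frac_age_genes = 1,
                                      n_mediation_triples = 0, n_cell_types = 0,
                                      seed = 18))
  full <- scan_associations(co$expression, co$samples)
  strat <- scan_associations(co$expression, co$samples, strata = "sex")
  pooled <- strat |>
    dplyr::group_by(feature_id) |>
    dplyr::summarise(est = sum(estimate / se^2) / sum(1 / se^2),
                     se = sqrt(1 / sum(1 / se^2)))
  m <- match(full$feature_id, pooled$feature_id)
  expect_true(all(abs(full$estimate - pooled$est[m]) < 2 * pooled$se[m]))
  expect_true(all(c("F", "M") %in% strat$stratum))
})

test_that("power at the ten-percent-per-decade cap is high at n = 500", {
  cfg <- cohort_config(n_samples = 500, n_genes = 60, n_cpgs = 5, n_modules = 0,
                       module_sizes = integer(0), n_mediation_triples = 0,
                       n_cell_types = 0, frac_age_genes = 0,
                       age_slopes = rep(0.08, 30), # cap-level slope, baseline ~8
                       seed = 19)
  co <- generate_cohort(cfg)
  sc <- scan_associations(co$expression, co$samples,
                          covariates = c("sex", "race", "site", "chip"))
  truth <- co$ground_truth$gene$true_slope
  hits <- sc$q.value[truth != 0] <= 0.01
  expect_gte(mean(hits), 0.9)
  # null genes stay quiet
  expect_lt(mean(sc$q.value[truth == 0] <= 0.05), 0.1)
})

test_that("qvalues reproduce BH exactly at pi0 = 1 and stay monotone", {
  withr::with_seed(20, p <- c(runif(300), runif(100, 0, 0.01)))
  q_fixed <- qvalues(p, pi0 = 1)
  expect_equal(q_fixed, p.adjust(p, "BH"), tolerance = 1e-12)
  q_est <- qvalues(p)
  o <- order(p)
  expect_true(all(diff(q_est[o]) >= -1e-12))
  expect_true(all(q_est <= q_fixed + 1e-12))
  expect_equal(qvalues(rep(1, 10)), rep(1, 10))
  expect_equal(qvalues(numeric(0)), numeric(0))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
  # smoother variant returns valid q-values
  q_sm <- qvalues(p, smoother = TRUE)
  expect_true(all(q_sm >= 0 & q_sm <= 1))
})

test_that("cis pairing honors the inclusive 1 Mb boundary", {
  cpg <- tibble::tibble(cpg_id = "cg1", chrom = "chr1", pos = 1000000L)
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(2000000L, 2000001L), end = c(2000500L, 2000501L), strand = "+")
  pr <- cis_pairs(cpg, genes)
  expect_identical(pr$gene_id, "gA")
  expect_equal(pr$distance, 1e6)

  # enumeration oracle on a grid of 10 genes around one CpG
  grid <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
    start = seq(0L, 2700000L, by = 300000L),
    end = seq(0L, 2700000L, by = 300000L) + 100L, strand = "+")
  cpg2 <- tibble::tibble(cpg_id = "cg2", chrom = "chr1", pos = 1500000L)
  pr2 <- cis_pairs(cpg2, grid)
  expected <- grid$gene_id[abs(grid$start - 1500000) <= 1e6]
  expect_setequal(pr2$gene_id, expected)

  # minus-strand genes anchor at their end coordinate
  neg <- tibble::tibble(gene_id = "gN", chrom = "chr1",
                        start = 0L, end = 900000L, strand = "-")
  expect_equal(nrow(cis_pairs(cpg, neg)), 1)

  expect_error(cis_pairs(tibble::tibble(cpg_id = "c", chrom = "chrX", pos = 1L),
                         genes), "chromosome")
})

test_that("pulse pressure uses only the second and third readings", {
  expect_equal(pulse_pressure_from_readings(
    list(c(130, 80), c(128, 78), c(126, 76))), 50)
  expect_equal(pulse_pressure_from_readings(
    list(c(120, 70), c(120, 70), c(120, 70))), 50)
  # first reading is ignored entirely
  expect_equal(pulse_pressure_from_readings(
    list(c(999, 1), c(128, 78), c(126, 76))), 50)
  expect_error(pulse_pressure_from_readings(list(c(120, 70), c(121, 71))),
               "at least 3")
})

test_that("phenotype scan separates direct effects from age proxies", {
  withr::with_seed(23, {
    n <- 300
    age <- runif(n, 55, 94)
    direct_gene <- rnorm(n)                      # independent of age
    proxy_gene <- 0.08 * age + rnorm(n, 0, 0.3)  # pure age proxy
    pp <- 40 + 0.4 * age + 3 * direct_gene + rnorm(n, 0, 2)
    expr <- rbind(direct = direct_gene, proxy = proxy_gene,
                  noise = rnorm(n))
    colnames(expr) <- sprintf("s%03d", 1:n)
    st <- tibble::tibble(sample_id = colnames(expr), age = age,
                         pulse_pressure = pp)
  })
  sc <- phenotype_scan(expr, st, covariates = "age")
  expect_lt(sc$q.value[sc$feature_id == "direct"], 0.01)
  expect_gt(sc$p.value[sc$feature_id == "proxy"], 0.05)
  expect_gt(sc$estimate[sc$feature_id == "direct"], 0)
  expect_error(phenotype_scan(expr, dplyr::mutate(st, pulse_pressure = 1)),
               "zero-variance")
})

test_that("significant phenotype calls carry the planted sign", {
  withr::with_seed(24, {
    n <- 250
    signs <- rep(c(1, -1), each = 15)
    expr <- matrix(rnorm(30 * n), nrow = 30,
                   dimnames = list(sprintf("g%02d", 1:30), sprintf("s%03d", 1:n)))
    pp <- 50 + as.numeric(signs %*% expr) * 0.8 + rnorm(n, 0, 3)
    st <- tibble::tibble(sample_id = colnames(expr), age = runif(n, 55, 94),
                         pulse_pressure = pp)
  })
  sc <- phenotype_scan(expr, st, covariates = "age")
  sig <- which(sc$q.value < 0.05)
  agree <- sign(sc$estimate[sig]) == signs[sig]
  expect_gte(mean(agree), 0.95)
})
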