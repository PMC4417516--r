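# Shared fixtures, generated once per test run. Small configurations keep
# the default suite fast; the heavier study-scale cohort is built lazily
# only where a test needs it.

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_cohort <- function() {
  fixture("default_cohort", function() generate_cohort(cohort_config(seed = 7)))
}

# two clean 50-gene blocks at correlation 0.8, no nuisance structure
two_block_cohort <- function() {
  fixture("two_block", function() {
    generate_cohort(cohort_config(
      n_samples = 500, n_genes = 100, n_cpgs = 10, n_modules = 2,
      module_sizes = c(50, 50), within_module_cor = 0.8,
      module_age_cor = c(0, 0), frac_age_genes = 0, n_mediation_triples = 0,
      n_cell_types = 0, covariate_effects = FALSE, seed = 3))
  })
}

# contamination-dominant design: no modules, rich signatures
contamination_cohort <- function() {
  fixture("contamination", function() {
    generate_cohort(cohort_config(
      n_samples = 200, n_genes = 300, n_cpgs = 10, n_modules = 0,
      module_sizes = integer(0), frac_age_genes = 0, n_mediation_triples = 0,
      n_cell_types = 2, n_signature_genes = 25,
      contamination_range = c(0, 0.3), noise_sd = 0.5, seed = 21))
  })
}

# brute-force TOM oracle: explicit triple loop over the definition
tom_oracle <- function(a) {
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + a0[i, u] * a0[u, j]
      }
      k_i <- sum(a0[i, -i])
      k_j <- sum(a0[j, -j])
      out[i, j] <- (l_ij + a0[i, j]) / (min(k_i, k_j) + 1 - a0[i, j])
    }
  }
  out
}

# adjusted Rand index oracle from mclust (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

random_partition <- function(genes, k, seed) {
  withr::with_seed(seed, {
    tibble::tibble(gene_id = genes,
                   module = sample(0:k, length(genes), replace = TRUE),
                   color = "grey")
  })
}
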