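# Synthetic-cohort generator: determinism, planted structure, conservation.

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_preset(seed = 9)
  a <- sample_dmm_counts(cfg)
  b <- sample_dmm_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$labels, b$truth$labels)
  ga <- expand_to_genes(a$counts, cfg, a$truth)
  gb <- expand_to_genes(b$counts, cfg, b$truth)
  expect_identical(ga$gene_counts, gb$gene_counts)
  expect_identical(sample_phenotypes(a$truth, cfg),
                   sample_phenotypes(b$truth, cfg))
  cfg2 <- small_preset(seed = 10)
  expect_false(identical(sample_dmm_counts(cfg2)$counts, a$counts))
})

test_that("mixture draws respect K, weights and depth", {
  cfg1 <- synthetic_config(n_samples = 30, n_taxa = 5, depth = 200, K = 1,
                           alpha = matrix(1, 1, 5), seed = 2)
  s1 <- sample_dmm_counts(cfg1)
  expect_true(all(s1$truth$labels == 1))
  expect_true(all(rowSums(s1$counts) == 200))
  expect_true(all(s1$counts >= 0 & s1$counts == round(s1$counts)))

  cfg3 <- synthetic_config(n_samples = 600, n_taxa = 6, depth = 100, K = 3,
                           seed = 4)
  s3 <- sample_dmm_counts(cfg3)
  freq <- tabulate(s3$truth$labels, 3) / 600
  se <- sqrt((1 / 3) * (2 / 3) / 600)
  expect_true(all(abs(freq - 1 / 3) <= 3 * se))
})

test_that("component composition means converge to alpha/sum(alpha)", {
  cfg <- synthetic_config(n_samples = 400, n_taxa = 8, depth = 2000, K = 2,
                          weights = c(0.5, 0.5), separation = 10,
                          base_alpha = 1, seed = 21)
  s <- sample_dmm_counts(cfg)
  p <- s$counts / rowSums(s$counts)
  for (k in 1:2) {
    target <- cfg$alpha[k, ] / sum(cfg$alpha[k, ])
    rows <- s$truth$labels == k
    est <- colMeans(p[rows, ])
    # per-taxon sampling error of the Dirichlet-compounded mean
    a0 <- sum(cfg$alpha[k, ])
    v <- target * (1 - target) / (a0 + 1)
    se <- sqrt(v / sum(rows))
    expect_true(all(abs(est - target) <= 3 * se + 1e-3))
  }
})

test_that("configuration errors are caught", {
  expect_error(synthetic_config(10, 5, K = 0), "K must be")
  expect_error(synthetic_config(10, 5, depth = 0), "depth")
  expect_error(synthetic_config(10, 5, K = 2, weights = c(0.7, 0.4)),
               "simplex")
  expect_error(synthetic_config(10, 5, K = 1, alpha = matrix(-1, 1, 5)),
               "alpha")
  expect_error(
    synthetic_config(10, 5, K = 1, alpha = matrix(1, 1, 5),
                     correlation_spec = data.frame(taxon_a = 1, taxon_b = 2,
                                                   rho = 1.2)),
    "rho")
  expect_error(
    synthetic_config(10, 5, K = 2, module_spec = list(
      list(module_id = "M1", kos = "KO0001", component = 5, multiplier = 2))),
    "unknown component")
})

test_that("correlated generator plants the requested basis correlation", {
  cs <- data.frame(taxon_a = 1, taxon_b = 2, rho = 0.8)
  cfg <- synthetic_config(n_samples = 200, n_taxa = 50, depth = 5000, K = 1,
                          alpha = matrix(1, 1, 50), correlation_spec = cs,
                          seed = 11)
  sim <- sample_correlated_counts(cfg)
  L <- sim$truth$basis_log
  expect_lt(abs(cor(L[, 1], L[, 2]) - 0.8), 0.1)
  # unspecified pairs have no planted association
  others <- cor(L[, 3:10])
  expect_lt(max(abs(others[upper.tri(others)])), 0.25)
  expect_identical(sim$truth$planted_edges, cfg$correlation_spec)
  expect_identical(sample_correlated_counts(cfg)$counts, sim$counts)
})

test_that("impossible correlation structures are rejected", {
  cs <- data.frame(taxon_a = c(1, 1, 2), taxon_b = c(2, 3, 3),
                   rho = c(-0.9, -0.9, -0.9))
  cfg <- synthetic_config(n_samples = 10, n_taxa = 4, depth = 100, K = 1,
                          alpha = matrix(1, 1, 4), correlation_spec = cs,
                          seed = 1)
  expect_error(sample_correlated_counts(cfg), "positive semi-definite")
})

test_that("gene expansion conserves counts and round-trips abundances", {
  cfg <- synthetic_config(n_samples = 20, n_taxa = 6, genes_per_taxon = 4,
                          depth = 500, K = 1, alpha = matrix(2, 1, 6),
                          unannotated_fraction = 0, ko_fraction = 1,
                          seed = 8)
  sim <- sample_dmm_counts(cfg)
  g <- expand_to_genes(sim$counts, cfg, sim$truth)
  expect_equal(rowSums(g$gene_counts), rowSums(sim$counts))
  # fully annotated: aggregating gene abundances recovers taxa abundances
  agg <- aggregate_abundance(relative_abundance(g$gene_counts),
                             g$annotation, level = "species")
  expect_false("unannotated" %in% colnames(agg))
  taxa_ab <- relative_abundance(sim$counts)
  colnames(taxa_ab) <- sub("^t", "s", colnames(taxa_ab))
  expect_equal(agg[, colnames(taxa_ab)], taxa_ab, tolerance = 1e-12)

  # one gene per taxon, no unannotated: gene table equals taxa table
  cfg1 <- synthetic_config(n_samples = 10, n_taxa = 5, genes_per_taxon = 1,
                           depth = 300, K = 1, alpha = matrix(2, 1, 5),
                           unannotated_fraction = 0, seed = 3)
  s1 <- sample_dmm_counts(cfg1)
  g1 <- expand_to_genes(s1$counts, cfg1, s1$truth)
  expect_equal(unname(g1$gene_counts), unname(s1$counts))
})

test_that("phenotype draws follow component-dependent models", {
  cfg <- synthetic_config(
    n_samples = 50, n_taxa = 5, depth = 100, K = 2, seed = 6,
    phenotype_spec = list(
      list(name = "a", type = "continuous", means = c(1, 5), sd = 0),
      list(name = "grp", type = "categorical", levels = c("x", "y"),
           probs = matrix(c(1, 0, 0, 1), 2, byrow = TRUE))))
  sim <- sample_dmm_counts(cfg)
  ph <- sample_phenotypes(sim$truth, cfg)
  expect_equal(ph$a, c(1, 5)[sim$truth$labels])
  expect_equal(ph$grp, c("x", "y")[sim$truth$labels])
  expect_equal(unname(attr(ph, "types")), c("continuous", "categorical"))

  bad <- cfg
  bad$phenotype_spec <- list(list(name = "z", type = "wibble"))
  expect_error(sample_phenotypes(sim$truth, bad), "unknown covariate type")
})
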