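# Association battery: PERMANOVA, Spearman, group tests, PCA, adjusted
# regression, Box-Cox.

test_that("PERMANOVA reproduces the 1-D worked example", {
  D <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  res <- permanova_single(D, factor(c("A", "A", "B", "B")), n_perm = "exact")
  expect_equal(res$pseudo_F, 20000, tolerance = 1e-8)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_error(permanova_single(D, factor(rep("A", 4))), "constant")
  # default permutation count follows the standard protocol
  expect_equal(eval(formals(permanova_single)$n_perm), 9999L)
})

test_that("1-D PERMANOVA equals classical ANOVA F, P matches enumeration", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 6
    x <- rnorm(n)
    g <- factor(sample(rep(c("A", "B"), each = 3)))
    D <- as.matrix(dist(x))
    res <- permanova_single(D, g, n_perm = "exact")
    f_aov <- summary(aov(x ~ g))[[1]]$`F value`[1]
    expect_equal(res$pseudo_F, f_aov, tolerance = 1e-8)
    # independent enumeration over all label permutations
    Fs <- vapply(perms_of(n), function(p)
      summary(aov(x ~ g[p]))[[1]]$`F value`[1], 0)
    expect_equal(res$p_value, mean(Fs >= f_aov - 1e-10), tolerance = 1e-12)
  }
})

test_that("PERMANOVA agrees with the reference implementation", {
  set.seed(4)
  Y <- matrix(rgamma(30 * 8, 1), 30, 8)
  Y <- Y / rowSums(Y)
  g <- factor(sample(rep(c("A", "B", "C"), each = 10)))
  D <- bray_curtis(Y)
  res <- permanova_single(D, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-8)
})

test_that("null permutation P values are approximately uniform", {
  set.seed(9)
  n <- 24
  pvals <- vapply(1:200, function(i) {
    x <- rnorm(n)
    g <- factor(sample(rep(c("A", "B"), each = n / 2)))
    permanova_single(as.matrix(dist(x)), g, n_perm = 99, seed = i)$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(pvals, "punif")$statistic)
  expect_lt(unname(ks), 0.15)
})

test_that("battery wrapper BH-adjusts across factors", {
  set.seed(2)
  Y <- matrix(rgamma(20 * 6, 1), 20, 6); Y <- Y / rowSums(Y)
  ph <- data.frame(a = rnorm(20), b = rnorm(20))
  out <- permanova_battery(bray_curtis(Y), ph, n_perm = 49, seed = 3)
  expect_equal(out$factor, c("a", "b"))
  expect_equal(out$p_adj, p.adjust(out$p_value, "BH"))
})

test_that("Spearman matrix handles ranks, ties, and families", {
  X <- data.frame(p1 = c(1, 2, 3))
  Y <- data.frame(up = c(10, 20, 30), perm = c(3, 1, 2))
  out <- spearman_matrix(X, Y)
  expect_equal(out$rho[out$feature == "up"], 1)
  expect_equal(out$rho[out$feature == "perm"], -0.5)
  out_neg <- spearman_matrix(X, data.frame(down = -Y$up))
  expect_equal(out_neg$rho, -1)
  # constant vectors reported missing
  out_c <- spearman_matrix(X, data.frame(const = c(1, 1, 1)))
  expect_true(is.na(out_c$rho))
  # per-parameter adjustment families
  set.seed(5)
  X2 <- data.frame(a = rnorm(20), b = rnorm(20))
  Y2 <- data.frame(matrix(rnorm(20 * 4), 20))
  out2 <- spearman_matrix(X2, Y2, adjust_scope = "per_parameter")
  for (p in c("a", "b")) {
    sel <- out2$parameter == p
    expect_equal(out2$p_adj[sel], p.adjust(out2$p_value[sel], "BH"))
  }
})

test_that("group tests match hand-computed statistics", {
  # KW on {1,2},{3,4},{5,6}: rank sums 3,7,11 -> H = 4.571
  gt <- group_tests(1:6, rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(gt$kruskal$statistic), 32 / 7, tolerance = 1e-10)
  expect_equal(nrow(gt$dunn), 3)
  expect_equal(gt$dunn$p_adj, p.adjust(gt$dunn$p_value, "BH"))
  # equal rank sums -> H = 0
  gt0 <- group_tests(c(1, 4, 2, 3), c("a", "a", "b", "b"))
  expect_equal(unname(gt0$kruskal$statistic), 0)
  expect_false(is.null(gt0$ranksum))
  # chi-square without continuity correction on a diagonal 2x2 table
  cs <- group_tests(rep(c("x", "y"), each = 10),
                    rep(c("g1", "g2"), each = 10), type = "categorical")
  expect_equal(unname(cs$chisq$statistic), 20)
  expect_error(group_tests(1:3, rep("a", 3)), "groups")
})

test_that("PCA flags major contributors and returns orthonormal loadings", {
  set.seed(6)
  z <- rnorm(40)
  X <- data.frame(v1 = z, v2 = z)  # perfectly correlated pair
  res <- suppressMessages(pca_factors(X))
  expect_equal(res$variance_fraction[1], 1)
  expect_equal(abs(unname(res$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  expect_true(all(res$contributors$major))
  expect_equal(eval(formals(pca_factors)$loading_threshold), 0.2)
  # orthonormality and zero-variance handling
  X2 <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40), z = 1)
  expect_warning(res2 <- suppressMessages(pca_factors(X2)), "zero-variance")
  L <- res2$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("adjusted regression recovers a planted slope", {
  set.seed(3)
  x <- rnorm(200)
  y <- 2 * x + rnorm(200, sd = 0.1)
  res <- suppressMessages(glm_adjusted(y, x))
  expect_lt(abs(res$beta - 2), 0.05)
  expect_lt(res$p_value, 1e-10)
  # collinear exposure triggers a rank-deficiency error
  expect_error(suppressMessages(
    glm_adjusted(y, x, covars = data.frame(dup = x))), "collinear")
})

test_that("Box-Cox selects sensible lambdas", {
  set.seed(8)
  y <- exp(rnorm(150))
  bc <- boxcox_lambda(y)
  expect_lt(abs(bc$lambda), 0.2 + 1e-9)   # log-normal: lambda near 0
  # the transform is (y^l - 1)/l, log(y) exactly at l = 0
  yt <- if (abs(bc$lambda) < 1e-12) log(y) else (y^bc$lambda - 1) / bc$lambda
  expect_equal(bc$y_transformed, yt, tolerance = 1e-12)
  expect_error(boxcox_lambda(rep(2, 10)), "constant")
  expect_warning(boxcox_lambda(c(-1, 1, 2, 3, 2, 4)), "shifted")
})

test_that("residual repair engages Box-Cox and reports lambda", {
  set.seed(12)
  x <- rnorm(150)
  y <- exp(1 + 0.5 * x + rnorm(150, sd = 0.4))  # multiplicative noise
  res <- suppressMessages(glm_adjusted(y, x))
  expect_false(is.na(res$lambda))
  expect_gt(res$shapiro_p, 0.05)  # normality restored post-transform
})

test_that("enterotype-restricted phenotype effects are recovered in strata", {
  cfg <- preset_config(n_samples = 150, n_taxa = 15, genes_per_taxon = 5,
                       depth = 1500, seed = 23)
  sim <- sample_dmm_counts(cfg)
  ph <- sample_phenotypes(sim$truth, cfg)
  z <- sim$truth$labels
  betas <- pvals <- numeric(3)
  for (k in 1:3) {
    res <- suppressMessages(glm_adjusted(ph$insulin[z == k],
                                         ph$fiber[z == k]))
    betas[k] <- res$beta; pvals[k] <- res$p_value
  }
  expect_true(all(pvals[1:2] < 0.01))   # planted slope -2 in components 1-2
  expect_lt(max(abs(betas[1:2] - (-2))), 0.5)
  expect_gt(pvals[3], 0.05)             # no effect planted in component 3
})

test_that("overweight stratification composes richness and rank-sum", {
  set.seed(10)
  bmi <- c(rnorm(50, 0, 0.5), rnorm(12, 1.6, 0.3))
  rich <- c(rnorm(50, 1000, 50), rnorm(6, 400, 50), rnorm(6, 1000, 50))
  res <- overweight_richness_test(bmi, rich, richness_cutoff = 600)
  expect_equal(dim(res$table), c(2, 2))
  expect_true("overweight" %in% names(res$tests))
  expect_equal(res$bmi_cutoff, 1.04)
})
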