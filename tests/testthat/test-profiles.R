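# Profile construction: rarefaction, aggregation, diversity, distances.

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(1)
  counts <- matrix(rpois(5 * 20, 40), 5, 20,
                   dimnames = list(paste0("s", 1:5), paste0("g", 1:20)))
  r <- rarefy(counts, 300, seed = 2)
  expect_true(all(rowSums(r) == 300))
  expect_true(all(r <= counts))

  # sample already exactly at depth is unchanged
  x <- matrix(c(100L, 200L), 1, 2, dimnames = list("s1", c("g1", "g2")))
  expect_identical(rarefy(x, 300, seed = 1), x)

  # shallow samples are dropped with a warning
  deep <- rbind(x, s2 = c(10L, 20L))
  expect_warning(r2 <- rarefy(deep, 300, seed = 1), "below depth")
  expect_equal(rownames(r2), "s1")

  expect_error(rarefy(x, 0), "positive")
})

test_that("rarefied counts follow the hypergeometric distribution", {
  # one gene holding 50% of 10000 reads, depth 1000: sd = sqrt(k p q (N-k)/(N-1))
  x <- matrix(c(5000L, 5000L), 1, 2, dimnames = list("s1", c("a", "b")))
  sd_hyp <- sqrt(1000 * 0.25 * (10000 - 1000) / (10000 - 1))
  draws <- vapply(1:30, function(i) rarefy(x, 1000, seed = i)[1, "a"], 0)
  expect_true(all(abs(draws - 500) <= 3 * sd_hyp))
})

test_that("aggregation sums gene abundances and reports mapping ratio", {
  ab <- matrix(c(0.3, 0.2, 0.5), 1, 3,
               dimnames = list("s1", c("g1", "g2", "g3")))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    genus = c("A", "A", NA), species = c("A", "A", NA),
                    ko = NA_character_)
  agg <- aggregate_abundance(ab, ann, "species")
  expect_equal(agg[1, "A"], 0.5)
  expect_equal(agg[1, "unannotated"], 0.5)
  expect_equal(unname(attr(agg, "mapping_ratio")["s1"]), 0.5)
  expect_equal(rowSums(agg), c(s1 = 1))

  # all genes of one taxon -> abundance 1
  ann2 <- transform(ann, species = "A")
  expect_equal(aggregate_abundance(ab, ann2, "species")[1, "A"], 1)

  expect_error(aggregate_abundance(ab, ann, "pathway"), "arg")
})

test_that("richness counts nonzero features, order-invariant", {
  m <- rbind(s1 = c(5, 0, 1), s2 = c(0, 0, 0))
  expect_equal(unname(suppressMessages(richness(m))), c(2, 0))
  expect_equal(suppressMessages(richness(m[, c(3, 1, 2)])),
               suppressMessages(richness(m)))
})

test_that("Shannon index uses natural log", {
  expect_equal(unname(shannon_diversity(matrix(c(1, 0, 0), 1))), 0)
  expect_equal(unname(shannon_diversity(matrix(rep(0.25, 4), 1))), log(4))
  expect_equal(unname(shannon_diversity(matrix(c(0.7, 0.2, 0.1), 1))),
               0.8018, tolerance = 1e-4)
  expect_error(shannon_diversity(matrix(c(-0.1, 1.1), 1)), "negative")
})

test_that("Bray-Curtis and root-JSD behave as distances", {
  ab <- rbind(a = c(0.6, 0.4, 0), b = c(0.2, 0.8, 0), c = c(0, 0, 1))
  bc <- bray_curtis(ab)
  expect_equal(bc["a", "b"], 0.4)
  expect_equal(bc["a", "c"], 1)       # disjoint supports
  expect_equal(diag(bc), c(a = 0, b = 0, c = 0))
  expect_equal(bc, t(bc))

  js <- jsd_distance(ab)
  expect_equal(unname(diag(js)), c(0, 0, 0))
  expect_equal(js["a", "c"], sqrt(log(2)), tolerance = 1e-12)
  expect_equal(js, t(js))

  # root-JSD satisfies the triangle inequality on random triples
  set.seed(42)
  P <- matrix(rgamma(100 * 6, 1), 100)
  P <- P / rowSums(P)
  D <- jsd_distance(P)
  for (i in 1:100) {
    tr <- sample(100, 3)
    expect_lte(D[tr[1], tr[3]], D[tr[1], tr[2]] + D[tr[2], tr[3]] + 1e-12)
  }
})

test_that("low-coverage taxa filter respects the gene-count boundary", {
  ann <- data.frame(
    gene_id = paste0("g", 1:199),
    genus = NA_character_,
    species = rep(c("rich", "poor"), c(100, 99)),
    ko = NA_character_)
  expect_equal(filter_low_coverage_taxa(ann, 100), "rich")
  expect_setequal(filter_low_coverage_taxa(ann, 0), c("rich", "poor"))

  # any-group scope counts detected genes within groups
  counts <- matrix(1L, 4, 199, dimnames = list(paste0("s", 1:4),
                                               paste0("g", 1:199)))
  counts[3:4, ] <- 0L  # group B detects nothing
  got <- filter_low_coverage_taxa(ann, 100, scope = "any_group",
                                  gene_counts = counts,
                                  groups = c("A", "A", "B", "B"))
  expect_equal(got, "rich")
})

test_that("intra/inter beta-diversity comparison separates planted groups", {
  # two tight clusters far apart
  x <- c(0, 0.01, 0.02, 5, 5.01, 5.02)
  D <- as.matrix(dist(x))
  g <- rep(c("A", "B"), each = 3)
  res <- beta_group_comparison(D, g)
  expect_equal(length(res$intra$A), 3)   # n(n-1)/2 pairs
  expect_gt(median(res$inter), max(median(res$intra$A),
                                   median(res$intra$B)))
  expect_lt(res$p_value, 0.05)

  # degenerate: all samples identical
  D0 <- matrix(0, 4, 4)
  expect_warning(r0 <- beta_group_comparison(D0, c("A", "A", "B", "B")),
                 "identical")
  expect_true(is.na(r0$p_value))

  # singleton group excluded with warning
  expect_warning(beta_group_comparison(as.matrix(dist(1:4)),
                                       c("A", "A", "A", "B")),
                 "size 1")
})
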