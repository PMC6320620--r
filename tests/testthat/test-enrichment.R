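# Reporter-score enrichment: KO differential tests, module aggregation,
# taxa contribution decomposition.

make_ko_abund <- function(m) {
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- sprintf("KO%04d", seq_len(ncol(m)))
  m
}

test_that("one-tailed rank-sum P matches exact enumeration", {
  # A = {1, 2}, B = {3, 4}: all C(4,2) = 6 rank splits, one as extreme
  ab <- make_ko_abund(matrix(c(1, 2, 3, 4), 4, 1))
  kd <- ko_differential(ab, group_a = 1:2, group_b = 3:4,
                        min_occurrence = 1)
  expect_equal(kd$table$p_less, 1 / 6, tolerance = 1e-12)
  expect_equal(kd$table$p_greater, 1, tolerance = 1e-12)
  # direction: enriched in B, so Z is negative
  expect_lt(kd$table$z, 0)
})

test_that("occurrence filter requires more than six samples", {
  m <- matrix(0, 14, 2)
  m[1:6, 1] <- 1    # KO present in exactly 6 samples: excluded
  m[1:7, 2] <- 1    # present in 7: tested
  ab <- make_ko_abund(m)
  kd <- ko_differential(ab, 1:7, 8:14, min_occurrence = 7)
  expect_equal(kd$table$ko, "KO0002")
  expect_warning(ko_differential(make_ko_abund(matrix(0, 14, 1)), 1:7, 8:14),
                 "occurrence")
  expect_error(ko_differential(ab, 1:7, 5:14), "overlap")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("Z-scores flip sign when the groups are swapped", {
  set.seed(2)
  m <- matrix(runif(20 * 5), 20, 5)
  m[1:10, 1] <- m[1:10, 1] + 2
  ab <- make_ko_abund(m)
  kd_ab <- ko_differential(ab, 1:10, 11:20)
  kd_ba <- ko_differential(ab, 11:20, 1:10)
  expect_equal(kd_ab$table$z, -kd_ba$table$z, tolerance = 1e-9)
})

test_that("reporter aggregation and threshold behave as specified", {
  fake_kd <- function(z) {
    structure(list(table = data.frame(
      ko = sprintf("KO%04d", seq_along(z)), occurrence = 10,
      p_greater = NA, p_less = NA, p_onetail = NA, p_adj = NA, z = z)),
      class = "ko_differential")
  }
  # all-zero member Z: raw aggregate 0
  kd <- fake_kd(rep(0, 8))
  rs <- reporter_scores(kd, list(M1 = sprintf("KO%04d", 1:4)),
                        background_on = FALSE)
  expect_equal(rs$raw_score, 0)
  # m = 4 KOs at Z = 1: raw aggregate 4 / sqrt(4) = 2
  kd <- fake_kd(c(rep(1, 4), rep(0, 4)))
  rs <- reporter_scores(kd, list(M1 = sprintf("KO%04d", 1:4)),
                        background_on = FALSE)
  expect_equal(rs$raw_score, 2)
  # |score| = 1.96 flagged, 1.95 not
  kd <- fake_kd(c(1.96, 1.95))
  rs <- reporter_scores(kd, list(hit = "KO0001", miss = "KO0002"),
                        background_on = FALSE)
  expect_true(rs$significant[rs$module == "hit"])
  expect_false(rs$significant[rs$module == "miss"])
  # module with no tested KO is skipped with a warning
  expect_warning(reporter_scores(kd, list(empty = "KO9999"),
                                 background_on = FALSE),
                 "skipped")
})

test_that("a planted module is detected against flat background", {
  cfg <- preset_config(n_samples = 90, seed = 17)
  sim <- sample_dmm_counts(cfg)
  g <- expand_to_genes(sim$counts, cfg, sim$truth)
  ko_ab <- aggregate_abundance(relative_abundance(g$gene_counts),
                               g$annotation, "ko")
  z <- sim$truth$labels
  kd <- ko_differential(ko_ab, which(z == 1), which(z != 1))
  rs <- reporter_scores(kd, g$module_catalog, seed = 3)
  expect_true(rs$score[rs$module == "M001"] >= 1.96)   # planted in comp 1
  expect_true(all(abs(rs$score[rs$module %in% c("M004", "M005", "M006")]) <
                    1.96))                             # background modules
})

test_that("taxa contributions decompose KO abundance exactly", {
  ab <- matrix(c(0.02, 0.01, 0.97), 1, 3,
               dimnames = list("s1", c("g1", "g2", "g3")))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    genus = c("X", "Y", "X"),
                    species = c("X", "Y", "X"),
                    ko = c("K1", "K1", NA))
  tc <- taxa_contribution(ab, ann, "K1", groups = "all")
  tab <- tc$table
  expect_equal(tab$mean_abundance[tab$species == "X"] /
                 sum(tab$mean_abundance), 2 / 3)
  expect_equal(tab$mean_abundance[tab$species == "Y"] /
                 sum(tab$mean_abundance), 1 / 3)
  # contributions per sample sum to the aggregated KO abundance
  agg <- aggregate_abundance(ab, ann, "ko")
  expect_equal(sum(tc$per_sample$K1["s1", ]), agg["s1", "K1"])
  # single-species KO: 100% share
  ann2 <- transform(ann, species = "X")
  tc2 <- taxa_contribution(ab, ann2, "K1", groups = "all")
  expect_equal(nrow(tc2$table), 1)
  expect_error(taxa_contribution(ab, ann, "K9", "all"), "not in annotation")
})
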