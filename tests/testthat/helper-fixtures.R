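# Shared fixtures: small, quick synthetic configurations built in code.

# scaled-down three-component cohort for fast recovery checks
small_preset <- function(seed = 5, n = 60, taxa = 12, depth = 1000) {
  preset_config(n_samples = n, n_taxa = taxa, genes_per_taxon = 5,
                depth = depth, seed = seed)
}

# independent-taxa compositional null for SparCC
null_counts <- function(n = 100, taxa = 20, depth = 2000, seed = 13) {
  cfg <- synthetic_config(n_samples = n, n_taxa = taxa, depth = depth,
                          K = 1, alpha = matrix(1, 1, taxa), seed = seed)
  sample_correlated_counts(cfg)$counts
}

# independent brute-force BH step-up written from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  vals <- pmin(1, m * p[o] / seq_len(m))
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(vals)))
  adj
}

# exhaustive k-medoids: minimum assignment cost over all medoid sets
pam_brute <- function(D, k) {
  D <- as.matrix(D)
  sets <- utils::combn(nrow(D), k)
  costs <- apply(sets, 2, function(m)
    sum(apply(D[, m, drop = FALSE], 1, min)))
  min(costs)
}

# all permutations of seq_len(n), as a list (n <= 7 in tests)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1))
    for (pos in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  out
}
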