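# Profile construction: rarefaction, relative-abundance aggregation,
# richness/diversity, community dissimilarities, coverage filtering.
# Convention throughout: matrices are samples x features.

#' Rarefy a count table to a fixed depth
#'
#' Per sample, draws `depth` reads without replacement from that sample's
#' read multiset (multivariate hypergeometric subsampling). Samples with
#' fewer than `depth` total reads are dropped with a warning.
#'
#' @param counts samples x features integer matrix.
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return rarefied count matrix; every retained row sums to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  check_counts(counts)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(counts)[!keep], collapse = ", "), call. = FALSE)
  counts <- counts[keep, , drop = FALSE]
  set.seed(split_seed(seed, "rarefy"))
  out <- counts
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    total <- sum(x)
    if (total == depth) next
    remaining <- depth
    left <- total
    for (j in seq_along(x)) {
      if (remaining == 0) { out[i, j:length(x)] <- 0L; break }
      left <- left - x[j]
      # draw this feature's share of the remaining subsample
      d <- stats::rhyper(1, m = x[j], n = left, k = remaining)
      out[i, j] <- d
      remaining <- remaining - d
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to relative abundances
#'
#' @param counts samples x features matrix.
#' @return matrix of the same shape with rows summing to 1.
#' @export
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("sample(s) with zero total reads", call. = FALSE)
  counts / totals
}

#' Aggregate gene abundances to taxa, KOs or categories
#'
#' Feature abundance is the sum of constituent gene abundances; genes without
#' annotation at the requested level fall into an explicit `"unannotated"`
#' feature so each sample still sums to 1. The per-sample annotated-mapping
#' ratio (annotated abundance / total) is attached as attribute
#' `"mapping_ratio"`.
#'
#' @param gene_abund samples x genes relative-abundance matrix.
#' @param annotation data frame with `gene_id` plus annotation columns
#'   (`genus`, `species`, `ko`, optionally others); `NA` means unannotated.
#' @param level annotation column to aggregate by.
#' @return samples x features abundance matrix.
#' @export
aggregate_abundance <- function(gene_abund, annotation,
                                level = c("species", "genus", "ko",
                                          "category")) {
  level <- match.arg(level)
  if (!level %in% names(annotation))
    stop("annotation has no '", level, "' column", call. = FALSE)
  lab <- annotation[[level]][match(colnames(gene_abund), annotation$gene_id)]
  lab[is.na(lab)] <- "unannotated"
  agg <- t(rowsum(t(gene_abund), group = lab))
  # keep "unannotated" last for readability
  ord <- c(setdiff(sort(colnames(agg)), "unannotated"),
           intersect("unannotated", colnames(agg)))
  agg <- agg[, ord, drop = FALSE]
  ratio <- if ("unannotated" %in% colnames(agg))
    1 - agg[, "unannotated"] / rowSums(agg) else rep(1, nrow(agg))
  attr(agg, "mapping_ratio") <- stats::setNames(ratio, rownames(agg))
  agg
}

#' Per-sample feature richness
#'
#' Number of features with a nonzero count per sample. Expects rarefied
#' input; a message is emitted if per-sample totals differ.
#'
#' @param counts samples x features count matrix.
#' @return named integer vector.
#' @export
richness <- function(counts) {
  totals <- rowSums(counts)
  if (length(unique(totals)) > 1L)
    message("richness: per-sample totals differ; input does not look rarefied")
  rowSums(counts > 0)
}

#' Shannon diversity (natural log)
#'
#' @param abund samples x features relative-abundance matrix (rows sum to 1).
#' @return named numeric vector of Shannon indices in nats.
#' @export
shannon_diversity <- function(abund) {
  if (any(abund < 0)) stop("negative abundance", call. = FALSE)
  vegan::diversity(abund, index = "shannon")
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`.
#'
#' @param abund samples x features relative-abundance matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(abund) {
  as.matrix(vegan::vegdist(abund, method = "bray"))
}

#' (Root) Jensen-Shannon divergence distance matrix
#'
#' JSD in nats with exact handling of zero abundances (0 log 0 = 0). By
#' default the square root is returned, which is a metric (standard
#' enterotyping practice); `sqrt = FALSE` gives plain JSD.
#'
#' @param abund samples x features relative-abundance matrix (rows sum to 1).
#' @param sqrt return the square root (metric) form.
#' @return symmetric distance matrix.
#' @export
jsd_distance <- function(abund, sqrt = TRUE) {
  if (any(abund < 0)) stop("negative abundance", call. = FALSE)
  n <- nrow(abund)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h <- apply(abund, 1L, H)
  D <- matrix(0, n, n, dimnames = list(rownames(abund), rownames(abund)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- (abund[i, ] + abund[j, ]) / 2
    d <- H(m) - (h[i] + h[j]) / 2
    D[i, j] <- D[j, i] <- max(d, 0)  # clip tiny negative rounding
  }
  if (sqrt) base::sqrt(D) else D
}

#' Filter taxa with low annotated-gene coverage
#'
#' Retains taxa backed by at least `min_genes` annotated genes. The default
#' scope counts genes cohort-wide; `scope = "any_group"` instead requires at
#' least `min_genes` genes *detected* (nonzero) within some group, given a
#' gene count table and group labels.
#'
#' @param annotation annotation data frame (`gene_id` + taxon column).
#' @param min_genes minimum annotated genes (default 100; taxa with fewer
#'   are removed).
#' @param level taxon column (`"species"` or `"genus"`).
#' @param scope `"cohort"` (default) or `"any_group"`.
#' @param gene_counts,groups required for `scope = "any_group"`: samples x
#'   genes counts and per-sample group labels.
#' @return character vector of retained taxa.
#' @export
filter_low_coverage_taxa <- function(annotation, min_genes = 100,
                                     level = c("species", "genus"),
                                     scope = c("cohort", "any_group"),
                                     gene_counts = NULL, groups = NULL) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  lab <- annotation[[level]]
  if (scope == "cohort") {
    tab <- table(lab[!is.na(lab)])
    return(names(tab)[tab >= min_genes])
  }
  if (is.null(gene_counts) || is.null(groups))
    stop("scope='any_group' needs gene_counts and groups", call. = FALSE)
  taxa <- sort(unique(lab[!is.na(lab)]))
  keep <- logical(length(taxa))
  gl <- lab[match(colnames(gene_counts), annotation$gene_id)]
  for (g in unique(groups)) {
    detected <- colSums(gene_counts[groups == g, , drop = FALSE] > 0) > 0
    tab <- table(gl[detected & !is.na(gl)])
    keep <- keep | (taxa %in% names(tab)[tab >= min_genes])
  }
  taxa[keep]
}

#' Compare within- and between-group community dissimilarity
#'
#' Partitions the pairwise distances into within-group and between-group
#' sets and compares them by a two-sided Wilcoxon rank-sum test. Groups of
#' size 1 have no within pairs and are excluded (with a warning).
#'
#' @param D symmetric distance matrix.
#' @param groups per-sample labels (length `nrow(D)`).
#' @return list with `intra` (named list of within-group distance vectors),
#'   `inter` (between-group distances), and `p_value`.
#' @export
beta_group_comparison <- function(D, groups) {
  stopifnot(nrow(D) == length(groups))
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes == 1L))
    warning("group(s) of size 1 have no intra pairs: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "), call. = FALSE)
  n <- nrow(D)
  pair_i <- rep(seq_len(n), times = n)
  pair_j <- rep(seq_len(n), each = n)
  upper <- pair_i < pair_j
  gi <- groups[pair_i[upper]]; gj <- groups[pair_j[upper]]
  d <- D[cbind(pair_i[upper], pair_j[upper])]
  intra <- lapply(stats::setNames(nm = names(sizes)[sizes > 1L]),
                  function(g) d[gi == g & gj == g])
  inter <- d[gi != gj]
  all_d <- c(unlist(intra), inter)
  if (all(all_d == all_d[1])) {
    warning("all pairwise distances identical; rank-sum P undefined",
            call. = FALSE)
    p <- NA_real_
  } else {
    p <- stats::wilcox.test(unlist(intra), inter, exact = FALSE)$p.value
  }
  list(intra = intra, inter = inter, p_value = p)
}
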