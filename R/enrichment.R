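# Reporter-score functional enrichment: per-KO one-tailed rank-sum tests
# with BH correction, module-level aggregated Z-scores with background
# correction, and per-taxon decomposition of KO abundance.

#' Per-KO differential abundance between two groups
#'
#' KOs present (nonzero) in more than `min_occurrence - 1` samples are tested
#' by one-tailed Wilcoxon rank-sum in both directions; the smaller one-tailed
#' P picks the direction, is BH-adjusted across tested KOs, clamped to
#' `[1e-15, 1 - 1e-15]`, and converted to a signed Z-score
#' `Z = sign * qnorm(1 - P_adj)`, positive when enriched in `group_a`.
#'
#' @param ko_abund samples x KO relative-abundance matrix.
#' @param group_a,group_b disjoint character/integer vectors of sample ids or
#'   indices.
#' @param min_occurrence minimum samples a KO must occur in to be tested
#'   (default 7, i.e. "more than six samples").
#' @return object of class `ko_differential`: data frame `table` with
#'   columns ko, occurrence, p_greater, p_less, p_onetail, p_adj, z.
#' @export
ko_differential <- function(ko_abund, group_a, group_b, min_occurrence = 7L) {
  ia <- if (is.character(group_a)) match(group_a, rownames(ko_abund))
        else as.integer(group_a)
  ib <- if (is.character(group_b)) match(group_b, rownames(ko_abund))
        else as.integer(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample ids", call. = FALSE)
  if (length(intersect(ia, ib))) stop("groups overlap", call. = FALSE)
  if (!length(ia) || !length(ib)) stop("empty group", call. = FALSE)
  kos <- colnames(ko_abund)
  kos <- setdiff(kos, "unannotated")
  occ <- colSums(ko_abund[c(ia, ib), kos, drop = FALSE] > 0)
  tested <- kos[occ >= min_occurrence]
  if (!length(tested)) {
    warning("no KO passes the occurrence filter", call. = FALSE)
    return(structure(list(table = data.frame(
      ko = character(0), occurrence = integer(0), p_greater = numeric(0),
      p_less = numeric(0), p_onetail = numeric(0), p_adj = numeric(0),
      z = numeric(0))), class = "ko_differential"))
  }
  pg <- pl <- numeric(length(tested))
  for (i in seq_along(tested)) {
    a <- ko_abund[ia, tested[i]]
    b <- ko_abund[ib, tested[i]]
    pg[i] <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "greater")$p.value)
    pl[i] <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "less")$p.value)
  }
  direction <- ifelse(pg <= pl, 1, -1)
  p1 <- pmin(pg, pl)
  p_adj <- stats::p.adjust(p1, method = "BH")
  p_adj <- pmin(pmax(p_adj, 1e-15), 1 - 1e-15)
  z <- direction * stats::qnorm(1 - p_adj)
  structure(list(table = data.frame(
    ko = tested, occurrence = occ[tested], p_greater = pg, p_less = pl,
    p_onetail = p1, p_adj = p_adj, z = z, stringsAsFactors = FALSE)),
    class = "ko_differential")
}

#' @export
print.ko_differential <- function(x, ...) {
  cat(sprintf("KO differential: %d KO(s) tested\n", nrow(x$table)))
  cat(sprintf("  |Z| >= 1.96: %d\n", sum(abs(x$table$z) >= 1.96)))
  invisible(x)
}

#' Reporter Z-scores for module enrichment
#'
#' Aggregates per-KO Z-scores over each module's member KOs:
#' `raw = sum(Z) / sqrt(m)`. The background-corrected score subtracts the
#' mean and divides by the standard deviation of the raw aggregate over
#' random size-m draws from all tested KOs. Significance is flagged at
#' `|score| >= threshold` on the corrected score (or raw score when
#' correction is off).
#'
#' @param kd a [ko_differential()] result.
#' @param modules named list: module id -> character vector of member KOs.
#' @param background_sets random draws for the correction (default 1000).
#' @param background_on apply the background correction (default TRUE).
#' @param threshold significance threshold on `|score|`; the default 1.96 is
#'   the standard-normal two-sided 95% quantile.
#' @param seed integer seed.
#' @return data frame (class `reporter_scores`): module, m (member KOs with
#'   a Z), raw_score, score (background-corrected when on), significant.
#' @export
reporter_scores <- function(kd, modules, background_sets = 1000L,
                            background_on = TRUE, threshold = 1.96,
                            seed = 1L) {
  stopifnot(inherits(kd, "ko_differential"))
  z <- stats::setNames(kd$table$z, kd$table$ko)
  set.seed(split_seed(seed, "reporter-background"))
  rows <- lapply(names(modules), function(mod) {
    kos <- intersect(modules[[mod]], names(z))
    m <- length(kos)
    if (m == 0L) {
      warning("module ", mod, " has no tested KO; skipped", call. = FALSE)
      return(NULL)
    }
    raw <- sum(z[kos]) / sqrt(m)
    score <- raw
    if (background_on && length(z) > 1L) {
      bg <- vapply(seq_len(background_sets), function(i)
        sum(sample(z, m, replace = FALSE)) / sqrt(m), 0)
      s <- stats::sd(bg)
      score <- if (s > 0) (raw - mean(bg)) / s else raw
    }
    data.frame(module = mod, m = m, raw_score = raw, score = score,
               significant = abs(score) >= threshold,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), m = integer(0),
               raw_score = numeric(0), score = numeric(0),
               significant = logical(0))
  class(out) <- c("reporter_scores", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Per-species contribution to KO abundance
#'
#' For each requested KO and sample, the contribution of a species is the
#' summed abundance of genes annotated to both; genes without species
#' annotation accumulate to `"unannotated"`. Contributions are averaged
#' within groups; per-sample values are kept in the `per_sample` element.
#'
#' @param gene_abund samples x genes relative-abundance matrix.
#' @param annotation annotation data frame (gene_id, species, ko).
#' @param ko_ids KOs to decompose.
#' @param groups per-sample group labels.
#' @return list with `table` (data frame: ko, species, group,
#'   mean_abundance) and `per_sample` (named list of samples x species
#'   matrices per KO).
#' @export
taxa_contribution <- function(gene_abund, annotation, ko_ids, groups) {
  stopifnot(nrow(gene_abund) == length(groups))
  unknown <- setdiff(ko_ids, annotation$ko)
  if (length(unknown))
    stop("KO(s) not in annotation: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  per_sample <- list()
  rows <- list()
  for (ko in ko_ids) {
    genes <- annotation$gene_id[!is.na(annotation$ko) & annotation$ko == ko]
    genes <- intersect(genes, colnames(gene_abund))
    sp <- annotation$species[match(genes, annotation$gene_id)]
    sp[is.na(sp)] <- "unannotated"
    sub <- gene_abund[, genes, drop = FALSE]
    contrib <- t(rowsum(t(sub), group = sp))
    per_sample[[ko]] <- contrib
    for (g in unique(groups)) {
      mu <- colMeans(contrib[groups == g, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        ko = ko, species = names(mu), group = g, mean_abundance = as.numeric(mu),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), per_sample = per_sample)
}
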