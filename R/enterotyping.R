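# Enterotype discovery: PAM clustering on arbitrary dissimilarities,
# distance-form Calinski-Harabasz, model selection across k, cluster
# matching, and the subsample-resampling stability protocol.

#' Partitioning around medoids (exact for small n, BUILD + SWAP otherwise)
#'
#' Deterministic k-medoids on a dissimilarity matrix. Small instances
#' (at most `exact_limit` candidate medoid sets) are solved by exhaustive
#' search, guaranteeing the global optimum; larger instances use the greedy
#' BUILD phase followed by a SWAP phase that accepts only strictly
#' cost-decreasing medoid/non-medoid exchanges (ties rejected, guaranteeing
#' termination). Samples are assigned to their nearest medoid, ties broken
#' by the lowest medoid index.
#'
#' @param D symmetric dissimilarity matrix (or `dist`).
#' @param k number of clusters (2 <= k <= n).
#' @param exact_limit exhaustive search whenever `choose(n, k)` does not
#'   exceed this (default 3000; covers all n <= 8).
#' @return object of class `pam_clust`: `medoids` (indices, ascending),
#'   `labels` (1..k in medoid order), `total_cost`, `k`.
#' @export
pam_cluster <- function(D, k, exact_limit = 3000) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  cost <- function(meds) sum(do.call(pmin, lapply(meds, function(m) D[, m])))
  if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2L, cost)
    meds <- sets[, which.min(costs)]   # lexicographically first optimum
  } else {
    # BUILD
    meds <- which.min(colSums(D))
    while (length(meds) < k) {
      dmin <- do.call(pmin, lapply(meds, function(m) D[, m]))
      cand <- setdiff(seq_len(n), meds)
      gains <- vapply(cand, function(j) sum(pmin(dmin, D[, j])), 0)
      meds <- c(meds, cand[which.min(gains)])
    }
    # SWAP
    repeat {
      cur <- cost(meds)
      best <- cur; best_meds <- NULL
      for (mi in seq_along(meds)) {
        for (h in setdiff(seq_len(n), meds)) {
          trial <- meds; trial[mi] <- h
          cst <- cost(trial)
          if (cst < best - 1e-12) { best <- cst; best_meds <- trial }
        }
      }
      if (is.null(best_meds)) break
      meds <- best_meds
    }
  }
  meds <- sort(meds)
  nearest <- apply(D[, meds, drop = FALSE], 1L, which.min)  # lowest index ties
  structure(list(medoids = meds, labels = as.integer(nearest),
                 total_cost = cost(meds), k = as.integer(k)),
            class = "pam_clust")
}

#' @export
print.pam_clust <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, total cost %.4f\n", x$k, x$total_cost))
  cat("  medoids:", x$medoids, "\n")
  cat("  sizes:  ", tabulate(x$labels, x$k), "\n")
  invisible(x)
}

#' Calinski-Harabasz index from a distance matrix
#'
#' Distance-only form: total and within-cluster sums of squares are computed
#' from pairwise squared distances (`SS = sum_{i<j} d^2 / n`), and
#' `CH = (SS_between / (k - 1)) / (SS_within / (n - k))`.
#'
#' @param D symmetric distance matrix.
#' @param labels cluster labels (>= 2 nonempty clusters).
#' @return numeric score; `+Inf` with a warning when every cluster is a
#'   singleton (zero within-cluster dispersion).
#' @export
calinski_harabasz <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  k <- length(cl)
  if (k < 2) stop("need >= 2 clusters", call. = FALSE)
  D2 <- D^2
  ss_pairs <- function(idx) {
    if (length(idx) < 2L) return(0)
    sum(D2[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]) /
      length(idx)
  }
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- sum(vapply(cl, function(g) ss_pairs(which(labels == g)), 0))
  ss_between <- ss_total - ss_within
  if (ss_within <= 0) {
    warning("zero within-cluster dispersion; CH is infinite", call. = FALSE)
    return(Inf)
  }
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Select the number of enterotypes
#'
#' Fits every k in `k_range` with the requested protocol and selects the
#' criterion optimum: minimum Laplace negative log evidence for DMM, maximum
#' Calinski-Harabasz for the PAM protocols (on root-JSD or Bray-Curtis
#' dissimilarities of the taxa relative abundances).
#'
#' @param counts samples x taxa integer matrix.
#' @param method `"dmm"`, `"pam_jsd"` or `"pam_bc"`.
#' @param k_range candidate cluster numbers (k >= 1 for DMM, >= 2 for PAM).
#' @param seed integer seed (DMM restarts).
#' @param ... passed to [fit_dmm()] (e.g. `restarts`, `tol`).
#' @return object of class `model_selection`: `method`, `criteria`
#'   (data frame k/criterion), `selected_k`, `fits` (per-k fit objects),
#'   `labels` (assignment at the selected k).
#' @export
select_k <- function(counts, method = c("dmm", "pam_jsd", "pam_bc"),
                     k_range = 1:6, seed = 1L, ...) {
  method <- match.arg(method)
  if (length(k_range) == 0L) stop("k_range is empty", call. = FALSE)
  n <- nrow(counts)
  if (method == "dmm") {
    if (any(k_range < 1) || any(k_range > n - 1))
      stop("DMM k_range must lie in [1, n-1]", call. = FALSE)
    fits <- lapply(k_range, function(k)
      fit_dmm(counts, K = k, seed = split_seed(seed, paste0("selk-", k)), ...))
    crit <- vapply(fits, `[[`, 0, "neg_log_evidence")
    sel <- which.min(crit)
  } else {
    if (any(k_range < 2) || any(k_range > n - 1))
      stop("PAM k_range must lie in [2, n-1]", call. = FALSE)
    abund <- relative_abundance(counts)
    D <- if (method == "pam_jsd") jsd_distance(abund) else bray_curtis(abund)
    fits <- lapply(k_range, function(k) pam_cluster(D, k))
    crit <- vapply(seq_along(fits), function(i)
      calinski_harabasz(D, fits[[i]]$labels), 0)
    sel <- which.max(crit)
  }
  structure(list(method = method,
                 criteria = data.frame(k = k_range, criterion = crit),
                 selected_k = k_range[sel],
                 fits = stats::setNames(fits, paste0("k", k_range)),
                 labels = fits[[sel]]$labels),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  lab <- if (x$method == "dmm") "Laplace neg. log evidence (min is best)"
         else "Calinski-Harabasz (max is best)"
  cat(sprintf("Model selection [%s], criterion: %s\n", x$method, lab))
  print(x$criteria, row.names = FALSE)
  cat("selected k =", x$selected_k, "\n")
  invisible(x)
}

#' Match two cluster labelings and score their agreement
#'
#' Maximum-weight one-to-one matching of cluster ids by overlap count
#' (exhaustive over assignments, exact for the small cluster numbers used
#' in enterotyping); consistency is the matched-agreement fraction.
#'
#' @param labels_a,labels_b label vectors over the same samples.
#' @return list with `mapping` (named integer vector: cluster of `a` ->
#'   cluster of `b`) and `consistency` in `[0, 1]`.
#' @export
match_clusters <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0L)
    stop("labelings must cover the same nonempty sample set", call. = FALSE)
  ua <- sort(unique(labels_a)); ub <- sort(unique(labels_b))
  O <- table(factor(labels_a, ua), factor(labels_b, ub))
  if (length(ua) <= length(ub)) {
    asn <- assignments(seq_along(ua), seq_along(ub))
    scores <- vapply(asn, function(s) sum(O[cbind(seq_along(ua), s)]), 0)
    s <- asn[[which.max(scores)]]
    mapping <- stats::setNames(ub[s], ua)
    agree <- max(scores)
  } else {
    asn <- assignments(seq_along(ub), seq_along(ua))
    scores <- vapply(asn, function(s) sum(O[cbind(s, seq_along(ub))]), 0)
    s <- asn[[which.max(scores)]]
    mapping <- stats::setNames(ub, ua[s])
    agree <- max(scores)
  }
  list(mapping = mapping, consistency = agree / length(labels_a))
}

cluster_once <- function(counts, method, k, seed, ...) {
  if (method == "dmm") {
    fit_dmm(counts, K = k, seed = seed, ...)$labels
  } else {
    abund <- relative_abundance(counts)
    D <- if (method == "pam_jsd") jsd_distance(abund) else bray_curtis(abund)
    pam_cluster(D, k)$labels
  }
}

#' Clustering stability under subsample resampling
#'
#' Clusters the full data once, then for each subsample size and repeat
#' draws a without-replacement subsample, re-clusters it at the full-data k
#' (or re-selects k when `reselect = TRUE`), and records the
#' [match_clusters()] consistency against the full-data labels restricted to
#' the subsample. Default sizes are ~71-100% of n, following the protocol of
#' resampling 200/220/240/260/280 out of 281 samples, scaled to the data at
#' hand.
#'
#' @param counts samples x taxa integer matrix.
#' @param method clustering protocol (see [select_k()]).
#' @param k number of clusters for re-clustering (the full-data choice).
#' @param sizes subsample sizes; default `round(n * c(200,220,240,260,280)/281)`.
#' @param repeats draws per size (default 10).
#' @param reselect re-select k on every subsample instead of fixing it.
#' @param k_range candidate k when `reselect = TRUE`.
#' @param seed integer seed.
#' @param ... passed to the clustering routine (e.g. `restarts` for DMM).
#' @return object of class `stability_report`: `results` (data frame
#'   size/repeat/consistency), `summary` (mean per size), `method`, `k`.
#' @export
clustering_stability <- function(counts, method = c("dmm", "pam_jsd",
                                                    "pam_bc"),
                                 k, sizes = NULL, repeats = 10L,
                                 reselect = FALSE, k_range = 1:6, seed = 1L,
                                 ...) {
  method <- match.arg(method)
  n <- nrow(counts)
  if (is.null(sizes))
    sizes <- unique(pmin(n, round(n * c(200, 220, 240, 260, 280) / 281)))
  if (any(sizes > n)) stop("subsample size exceeds n", call. = FALSE)
  full_labels <- cluster_once(counts, method, k,
                              seed = split_seed(seed, "stab-full"), ...)
  res <- expand.grid(size = sizes, repeat_id = seq_len(repeats))
  res$consistency <- NA_real_
  for (r in seq_len(nrow(res))) {
    s <- res$size[r]; rep_id <- res$repeat_id[r]
    sd_r <- split_seed(seed, paste0("stab-", s, "-", rep_id))
    set.seed(sd_r)
    idx <- sort(sample.int(n, s))
    sub <- counts[idx, , drop = FALSE]
    kk <- if (reselect)
      select_k(sub, method = method,
               k_range = if (method == "dmm") k_range else k_range[k_range >= 2],
               seed = sd_r, ...)$selected_k else k
    sub_labels <- cluster_once(sub, method, kk, seed = sd_r, ...)
    res$consistency[r] <- match_clusters(full_labels[idx],
                                         sub_labels)$consistency
  }
  summ <- stats::aggregate(consistency ~ size, data = res, FUN = mean)
  structure(list(results = res, summary = summ, method = method,
                 k = k, full_labels = full_labels),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Clustering stability [%s, k = %d]: %d consistency values\n",
              x$method, x$k, nrow(x$results)))
  print(x$summary, row.names = FALSE)
  cat(sprintf("overall mean consistency: %.3f\n", mean(x$results$consistency)))
  invisible(x)
}
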