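# SparCC: basis (absolute-abundance) correlations inferred from
# compositional counts via log-ratio variances under a sparsity assumption,
# with permutation-based bootstrap pseudo-P values.

# Solve the sparsity linear system for basis variances given a log-ratio
# variance matrix T, optionally with excluded (strongly correlated) pairs
# removed from the sums. Returns omega and the implied rho.
#' Solve the SparCC basis system for one log-ratio variance matrix
#'
#' Exposed building block: given the observed matrix of log-ratio variances
#' `t_ij = Var(log(f_i / f_j))`, solves the sparsity approximation
#' `sum_{j != i} t_ij ~ (S - 2) * omega_i + sum_j omega_j` for the basis
#' variances and converts to basis correlations
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`.
#'
#' @param Tmat symmetric S x S log-ratio variance matrix (zero diagonal).
#' @param excluded optional logical S x S matrix of pairs to drop from the
#'   sums (the iterative strong-pair exclusion).
#' @return list with `omega` (basis variances, clamped positive; clamped
#'   taxa reported in `flagged`) and `rho` (clamped to `[-1, 1]`, unit
#'   diagonal).
#' @export
sparcc_basis_solve <- function(Tmat, excluded = NULL) {
  S <- nrow(Tmat)
  if (S < 3) stop("need >= 3 taxa to solve the basis system", call. = FALSE)
  M <- matrix(1, S, S)
  diag(M) <- S - 1
  Tuse <- Tmat
  if (!is.null(excluded)) {
    for (i in seq_len(S)) for (j in seq_len(S)) {
      if (i != j && excluded[i, j]) {
        M[i, i] <- M[i, i] - 1
        M[i, j] <- 0
        Tuse[i, j] <- 0
      }
    }
  }
  omega <- solve(M, rowSums(Tuse))
  flagged <- which(omega <= 0)
  if (length(flagged))
    omega[flagged] <- 1e-12
  denom <- 2 * sqrt(omega %o% omega)
  rho <- (outer(omega, rep(1, S)) + outer(rep(1, S), omega) - Tmat) / denom
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  list(omega = omega, rho = rho, flagged = flagged)
}

# One SparCC estimate from a single fraction matrix (n x S): variation
# matrix via the log-fraction covariance, then iterative strong-pair
# exclusion.
sparcc_from_fractions <- function(Fmat, exclusion_threshold, exclusion_iters) {
  L <- log(Fmat)
  V <- stats::cov(L)
  dv <- diag(V)
  Tmat <- outer(dv, rep(1, length(dv))) + outer(rep(1, length(dv)), dv) - 2 * V
  diag(Tmat) <- 0
  S <- nrow(Tmat)
  excluded <- matrix(FALSE, S, S)
  sol <- sparcc_basis_solve(Tmat, excluded)
  iters <- 0L
  while (iters < exclusion_iters) {
    r <- abs(sol$rho)
    diag(r) <- 0
    r[excluded] <- 0
    m <- which.max(r)
    if (r[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(r))
    # drop taxa already reduced to too few partners
    if (sum(!excluded[ij[1], ]) <= 3 || sum(!excluded[ij[2], ]) <= 3) break
    excluded[ij[1], ij[2]] <- excluded[ij[2], ij[1]] <- TRUE
    sol <- sparcc_basis_solve(Tmat, excluded)
    iters <- iters + 1L
  }
  list(rho = sol$rho, omega = sol$omega, Tmat = Tmat, flagged = sol$flagged)
}

#' SparCC basis correlations from compositional counts
#'
#' Per inner draw, sample fractions from a per-sample Dirichlet posterior
#' (counts + 1), compute the log-ratio variance matrix, solve the sparsity
#' system for basis variances, and iteratively exclude the single strongest
#' pair with `|rho|` above the exclusion threshold, re-solving up to
#' `exclusion_iters` times. The reported correlation is the element-wise
#' median over the inner draws, clamped to `[-1, 1]`.
#'
#' @param counts samples x taxa integer matrix (>= 4 taxa).
#' @param inner_draws Dirichlet posterior draws to median over (default 20).
#' @param exclusion_threshold `|rho|` above which the strongest pair is
#'   excluded from the sparsity sums (default 0.1).
#' @param exclusion_iters maximum excluded pairs (default 10).
#' @param seed integer seed.
#' @return object of class `sparcc_fit`: `rho` (S x S, unit diagonal),
#'   `omega` (median basis variances), `t` (mean log-ratio variance matrix),
#'   `pseudo_p` (`NULL` until [sparcc_pseudo_p()] is run), `n_bootstrap`.
#' @export
sparcc <- function(counts, inner_draws = 20L, exclusion_threshold = 0.1,
                   exclusion_iters = 10L, seed = 1L) {
  check_counts(counts)
  n <- nrow(counts); S <- ncol(counts)
  if (S < 4) stop("SparCC needs >= 4 taxa", call. = FALSE)
  set.seed(split_seed(seed, "sparcc"))
  rhos <- array(0, c(S, S, inner_draws))
  omegas <- matrix(0, inner_draws, S)
  Tacc <- matrix(0, S, S)
  flagged <- integer(0)
  for (b in seq_len(inner_draws)) {
    Fmat <- t(apply(counts + 1, 1L, rdirichlet_one))
    est <- sparcc_from_fractions(Fmat, exclusion_threshold, exclusion_iters)
    rhos[, , b] <- est$rho
    omegas[b, ] <- est$omega
    Tacc <- Tacc + est$Tmat
    flagged <- union(flagged, est$flagged)
  }
  if (length(flagged))
    warning("negative basis variance solved for taxa ",
            paste(colnames(counts)[flagged], collapse = ", "),
            "; variances clamped", call. = FALSE)
  rho <- apply(rhos, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  structure(list(rho = rho, omega = apply(omegas, 2L, stats::median),
                 t = Tacc / inner_draws, pseudo_p = NULL,
                 n_bootstrap = 0L, flagged_taxa = flagged,
                 settings = list(inner_draws = inner_draws,
                                 exclusion_threshold = exclusion_threshold,
                                 exclusion_iters = exclusion_iters,
                                 seed = seed)),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  S <- nrow(x$rho)
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("SparCC fit: %d taxa, %d inner draws\n", S,
              x$settings$inner_draws))
  cat(sprintf("  |rho| off-diagonal: median %.3f, max %.3f\n",
              stats::median(abs(off)), max(abs(off))))
  if (!is.null(x$pseudo_p))
    cat(sprintf("  pseudo-P from %d bootstraps; %d pair(s) < 0.01\n",
                x$n_bootstrap,
                sum(x$pseudo_p[upper.tri(x$pseudo_p)] < 0.01)))
  invisible(x)
}

#' Bootstrap pseudo-P values for SparCC correlations
#'
#' Generates `B` null data sets by independently permuting each taxon's
#' counts across samples (breaking all inter-taxon association while
#' preserving marginals), re-estimates SparCC on each, and reports per pair
#' the proportion of null data sets whose `|rho|` is at least as extreme as
#' the observed one (no +1 correction by default, matching the literal
#' proportion definition).
#'
#' @param counts samples x taxa integer matrix.
#' @param fit optional precomputed `sparcc_fit` for these counts.
#' @param B number of null data sets (default 1000).
#' @param corrected use the `(r + 1) / (B + 1)` convention instead of the
#'   literal proportion.
#' @param seed integer seed.
#' @param ... passed to [sparcc()] (inner draws etc.) for both observed and
#'   null fits.
#' @return the `sparcc_fit` with `pseudo_p` (S x S in `[0, 1]`) and
#'   `n_bootstrap` filled in.
#' @export
sparcc_pseudo_p <- function(counts, fit = NULL, B = 1000L, corrected = FALSE,
                            seed = 1L, ...) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (is.null(fit)) fit <- sparcc(counts, seed = seed, ...)
  obs <- abs(fit$rho)
  hits <- matrix(0, nrow(obs), ncol(obs))
  n <- nrow(counts)
  for (b in seq_len(B)) {
    set.seed(split_seed(seed, paste0("sparcc-null-", b)))
    perm <- apply(counts, 2L, function(col) col[sample.int(n)])
    null_fit <- sparcc(perm, seed = split_seed(seed, paste0("null-fit-", b)),
                       ...)
    hits <- hits + (abs(null_fit$rho) >= obs)
  }
  p <- if (corrected) (hits + 1) / (B + 1) else hits / B
  diag(p) <- 1
  dimnames(p) <- dimnames(fit$rho)
  fit$pseudo_p <- p
  fit$n_bootstrap <- as.integer(B)
  fit
}

#' Extract significant co-occurrence edges
#'
#' Pairs with bootstrap pseudo-P strictly below the cutoff, carrying the
#' correlation sign and optional node metadata (e.g. enterotype enrichment
#' or log10 mean abundance for node sizing).
#'
#' @param fit a `sparcc_fit` with `pseudo_p` computed.
#' @param cutoff strict pseudo-P threshold (default 0.01).
#' @param node_annotations optional data frame keyed by taxon name; its
#'   columns are joined onto both endpoints (prefixed `a_` / `b_`).
#' @return data frame (source, target, rho, pseudo_p, sign) — the edge list.
#' @export
significant_edges <- function(fit, cutoff = 0.01, node_annotations = NULL) {
  if (is.null(fit$pseudo_p))
    stop("pseudo_p not computed; run sparcc_pseudo_p() first", call. = FALSE)
  S <- nrow(fit$rho)
  nm <- rownames(fit$rho)
  if (is.null(nm)) nm <- paste0("taxon", seq_len(S))
  idx <- which(upper.tri(fit$pseudo_p) & fit$pseudo_p < cutoff, arr.ind = TRUE)
  out <- data.frame(
    source = nm[idx[, 1]], target = nm[idx[, 2]],
    rho = fit$rho[idx], pseudo_p = fit$pseudo_p[idx],
    sign = ifelse(fit$rho[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  if (!is.null(node_annotations) && nrow(out) > 0) {
    for (col in setdiff(names(node_annotations), "taxon")) {
      out[[paste0("a_", col)]] <-
        node_annotations[[col]][match(out$source, node_annotations$taxon)]
      out[[paste0("b_", col)]] <-
        node_annotations[[col]][match(out$target, node_annotations$taxon)]
    }
  }
  out[order(out$pseudo_p, -abs(out$rho)), , drop = FALSE]
}
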