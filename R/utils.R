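# Internal numerical helpers shared across modules.

# log(sum(exp(x))) guarded against overflow; x a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp for a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

#' Derive a per-operation random stream seed from a root seed
#'
#' Every stochastic operation in the package draws its seed from the user's
#' root seed and a short operation label, so stages can be re-run in
#' isolation and still reproduce the exact stream they would see inside the
#' full pipeline. The derived seed is always a positive 32-bit integer.
#'
#' @param seed root integer seed.
#' @param label character operation label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  # two rounds of a Lehmer-style mix keep distinct labels well separated
  for (i in 1:2) s <- (s * 48271 + h + i) %% 2147483646
  as.integer(s + 1)
}

# One Dirichlet draw; zero gamma draws (possible for tiny shapes) are floored.
rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

# n Dirichlet draws with a common alpha, rows are draws.
rdirichlet_n <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g[g == 0] <- .Machine$double.xmin
  g / rowSums(g)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # degenerate: both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# All injective assignments of `from` indices into `to` indices (small K only).
assignments <- function(from, to) {
  if (length(from) == 0L) return(list(integer(0)))
  out <- list()
  for (j in to) {
    rest <- assignments(from[-1L], setdiff(to, j))
    out <- c(out, lapply(rest, function(r) c(j, r)))
  }
  out
}

# Check a count matrix: numeric, non-negative, (near-)integer.
check_counts <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (samples x features)", call. = FALSE)
  if (any(x < 0)) stop(what, " contain negative entries", call. = FALSE)
  if (max(abs(x - round(x))) > 1e-8)
    stop(what, " must be integer read counts", call. = FALSE)
  invisible(TRUE)
}
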