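# Dirichlet-multinomial mixture (DMM) fitting by EM, with a Laplace
# approximation of the negative log model evidence for choosing the number
# of components. Parameters are optimized in log space for positivity,
# under a diffuse Gamma(eta, nu) prior on every Dirichlet parameter.

DMM_ETA <- 0.1
DMM_NU <- 0.1

# Per-sample Dirichlet-multinomial log-likelihood for one component
# (multinomial coefficient omitted: constant across components and K).
dm_loglik_vec <- function(X, N, alpha) {
  A <- sum(alpha)
  lgamma(A) - lgamma(N + A) +
    rowSums(lgamma(sweep(X, 2L, alpha, `+`))) - sum(lgamma(alpha))
}

# log prior over one component's parameters, in theta = log(alpha) space
# (includes the Jacobian): sum(eta*theta - nu*alpha) + normalizing constant.
dm_logprior <- function(alpha) {
  sum(DMM_ETA * log(alpha) - DMM_NU * alpha) +
    length(alpha) * (DMM_ETA * log(DMM_NU) - lgamma(DMM_ETA))
}

# Responsibility-weighted penalized negative log-likelihood and gradient in
# theta = log(alpha); used by the M-step quasi-Newton update.
dm_mstep_obj <- function(theta, X, N, w) {
  a <- exp(theta)
  A <- sum(a)
  sw <- sum(w)
  ll <- sum(w * (lgamma(A) - lgamma(N + A))) +
    sum(colSums(w * lgamma(sweep(X, 2L, a, `+`)))) - sw * sum(lgamma(a))
  -(ll + sum(DMM_ETA * theta - DMM_NU * a))
}

dm_mstep_grad <- function(theta, X, N, w) {
  a <- exp(theta)
  A <- sum(a)
  sw <- sum(w)
  c1 <- sum(w * (digamma(A) - digamma(N + A)))
  g_a <- c1 + colSums(w * digamma(sweep(X, 2L, a, `+`))) - sw * digamma(a)
  -(a * g_a + DMM_ETA - DMM_NU * a)
}

# Negative Hessian of the log posterior in theta space for one component
# (responsibility-weighted block).
dm_neg_hessian <- function(alpha, X, N, w) {
  a <- alpha
  S <- length(a)
  A <- sum(a)
  sw <- sum(w)
  c1 <- sum(w * (digamma(A) - digamma(N + A)))
  g_a <- c1 + colSums(w * digamma(sweep(X, 2L, a, `+`))) - sw * digamma(a)
  c2 <- sum(w * (trigamma(A) - trigamma(N + A)))
  hdiag <- colSums(w * trigamma(sweep(X, 2L, a, `+`))) - sw * trigamma(a)
  H_a <- matrix(c2, S, S)
  diag(H_a) <- diag(H_a) + hdiag
  H_theta <- (a %o% a) * H_a + diag(a * g_a, S)
  # prior contribution: d^2/dtheta^2 (eta*theta - nu*exp(theta)) = -nu*alpha
  -(H_theta + diag(-DMM_NU * a, S))
}

# Method-of-moments Dirichlet init from a block of proportion rows.
dm_moment_init <- function(P) {
  m <- colMeans(P)
  m <- pmax(m, 1e-6); m <- m / sum(m)
  if (nrow(P) < 2L) return(m * 50)
  v <- apply(P, 2L, stats::var)
  ok <- v > 1e-12 & m > 1e-6 & m < 1 - 1e-6
  s <- if (any(ok)) stats::median(m[ok] * (1 - m[ok]) / v[ok] - 1) else 50
  s <- min(max(s, 1), 1e4)
  pmax(m * s, 1e-4)
}

#' Fit a Dirichlet-multinomial mixture to taxa counts
#'
#' EM fit of a K-component Dirichlet-multinomial mixture. The E-step computes
#' responsibilities proportional to the mixture weight times the
#' Dirichlet-multinomial likelihood; the M-step updates the weights and
#' maximizes the responsibility-weighted penalized log-likelihood over each
#' component's log-Dirichlet parameters by bounded quasi-Newton iteration.
#' The best of `restarts` seeded k-means initializations is returned. The
#' negative log model evidence is computed by Laplace approximation around
#' the posterior mode (log-likelihood plus log-prior, plus d/2 log 2*pi,
#' minus half the log-determinant of the negative Hessian in log-parameter
#' space, negated), and is the criterion minimized by [select_k()].
#'
#' @param counts samples x taxa integer count matrix.
#' @param K number of components (>= 1).
#' @param restarts independent EM initializations (default 5).
#' @param tol relative change in the penalized log-likelihood declaring
#'   convergence (default 1e-6).
#' @param max_iter maximum EM iterations (default 1000).
#' @param seed integer seed (controls all restarts).
#' @return an object of class `dmm_fit` with elements `K`, `alpha`
#'   (K x S), `weights`, `responsibilities` (n x K, rows sum to 1),
#'   `neg_log_evidence`, `loglik`, `converged`, `n_iter`, `labels`
#'   (hard assignments).
#' @examples
#' cfg <- preset_config(n_samples = 40, n_taxa = 8, depth = 500, seed = 7)
#' sim <- sample_dmm_counts(cfg)
#' fit <- fit_dmm(sim$counts, K = 3, restarts = 2, seed = 1)
#' table(fit$labels, sim$truth$labels)
#' @export
fit_dmm <- function(counts, K, restarts = 5L, tol = 1e-6, max_iter = 1000L,
                    seed = 1L) {
  check_counts(counts, "taxa counts")
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  X <- counts
  storage.mode(X) <- "double"
  n <- nrow(X); S <- ncol(X)
  if (K > n) stop("K exceeds the number of samples", call. = FALSE)
  N <- rowSums(X)
  P <- X / pmax(N, 1)
  bounds <- c(-8, 8)  # log-alpha box keeps the optimizer away from collapse

  run_em <- function(alpha, pi) {
    obj_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    ll_mat <- matrix(0, n, K)
    r <- matrix(1 / K, n, K)
    repeat {
      iter <- iter + 1L
      for (k in seq_len(K)) ll_mat[, k] <- dm_loglik_vec(X, N, alpha[k, ])
      lp <- sweep(ll_mat, 2L, log(pmax(pi, 1e-300)), `+`)
      mix_ll <- sum(row_logsumexp(lp))
      obj <- mix_ll + sum(apply(alpha, 1L, dm_logprior))
      if (obj < obj_prev - 1e-6 * (1 + abs(obj_prev)))
        warning("EM objective decreased; optimization unstable",
                call. = FALSE)
      done <- abs(obj - obj_prev) < tol * (1 + abs(obj)) || iter >= max_iter
      r <- exp(lp - row_logsumexp(lp))
      if (done) { converged <- iter < max_iter; break }
      obj_prev <- obj
      pi <- pmax(colMeans(r), 1e-10)
      pi <- pi / sum(pi)
      for (k in seq_len(K)) {
        op <- stats::optim(pmin(pmax(log(alpha[k, ]), bounds[1]), bounds[2]),
                           fn = dm_mstep_obj, gr = dm_mstep_grad,
                           X = X, N = N, w = r[, k],
                           method = "L-BFGS-B",
                           lower = bounds[1], upper = bounds[2],
                           control = list(maxit = 30L))
        alpha[k, ] <- exp(op$par)
      }
    }
    list(alpha = alpha, pi = pi, r = r, obj = obj, mix_ll = mix_ll,
         converged = converged, iter = iter)
  }

  best <- NULL
  n_restarts <- if (K == 1L) 1L else as.integer(restarts)
  for (rs in seq_len(n_restarts)) {
    set.seed(split_seed(seed, paste0("dmm-restart-", rs)))
    if (K == 1L) {
      lab <- rep(1L, n)
    } else {
      lab <- tryCatch(stats::kmeans(P, centers = K, nstart = 10L)$cluster,
                      error = function(e) sample.int(K, n, replace = TRUE))
    }
    alpha0 <- matrix(0, K, S)
    for (k in seq_len(K)) {
      rows <- which(lab == k)
      if (length(rows) == 0L) rows <- sample.int(n, max(2L, n %/% K))
      alpha0[k, ] <- dm_moment_init(P[rows, , drop = FALSE])
    }
    pi0 <- pmax(tabulate(lab, K) / n, 1e-3)
    pi0 <- pi0 / sum(pi0)
    fit <- run_em(alpha0, pi0)
    if (is.null(best) || fit$obj > best$obj) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations",
            call. = FALSE)

  # Laplace approximation of the log evidence at the posterior mode
  logdet <- 0
  for (k in seq_len(K)) {
    nh <- dm_neg_hessian(best$alpha[k, ], X, N, best$r[, k])
    ev <- eigen((nh + t(nh)) / 2, symmetric = TRUE, only.values = TRUE)$values
    logdet <- logdet + sum(log(pmax(ev, 1e-10)))
  }
  d <- K * S
  logprior <- sum(apply(best$alpha, 1L, dm_logprior))
  evidence <- best$mix_ll + logprior + d / 2 * log(2 * pi) - logdet / 2
  colnames(best$alpha) <- colnames(counts)
  structure(list(
    K = as.integer(K), alpha = best$alpha, weights = best$pi,
    responsibilities = best$r, neg_log_evidence = -evidence,
    loglik = best$mix_ll, converged = best$converged, n_iter = best$iter,
    labels = max.col(best$r, ties.method = "first"),
    n = n, S = S, call = match.call()
  ), class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat("Dirichlet-multinomial mixture fit\n")
  cat(sprintf("  K = %d components, %d samples, %d taxa\n", x$K, x$n, x$S))
  cat(sprintf("  weights: %s\n", paste(round(x$weights, 3), collapse = " ")))
  cat(sprintf("  log-likelihood %.2f; Laplace neg. log evidence %.2f\n",
              x$loglik, x$neg_log_evidence))
  cat(sprintf("  converged: %s (%d EM iterations)\n", x$converged, x$n_iter))
  invisible(x)
}

#' @export
summary.dmm_fit <- function(object, ...) {
  sizes <- tabulate(object$labels, object$K)
  top <- apply(object$alpha, 1L, function(a) {
    p <- a / sum(a)
    nm <- colnames(object$alpha)
    if (is.null(nm)) nm <- paste0("taxon", seq_along(a))
    paste0(nm[which.max(p)], " (", round(100 * max(p), 1), "%)")
  })
  out <- data.frame(component = seq_len(object$K), size = sizes,
                    weight = round(object$weights, 3),
                    concentration = round(rowSums(object$alpha), 2),
                    dominant_taxon = top)
  cat("Component summary:\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.dmm_fit <- function(object, ...) {
  list(alpha = object$alpha, weights = object$weights)
}

#' @export
logLik.dmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$K * object$S + object$K - 1,
            nobs = object$n, class = "logLik")
}

#' Posterior component membership for new count profiles
#'
#' @param object a `dmm_fit`.
#' @param newdata samples x taxa count matrix on the same taxa.
#' @param type `"response"` for hard labels, `"prob"` for responsibilities.
#' @param ... unused.
#' @export
predict.dmm_fit <- function(object, newdata,
                            type = c("response", "prob"), ...) {
  type <- match.arg(type)
  check_counts(newdata)
  if (ncol(newdata) != object$S)
    stop("newdata must have ", object$S, " taxa", call. = FALSE)
  X <- newdata; storage.mode(X) <- "double"
  N <- rowSums(X)
  lp <- vapply(seq_len(object$K), function(k)
    dm_loglik_vec(X, N, object$alpha[k, ]) + log(object$weights[k]),
    numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  r <- exp(lp - row_logsumexp(lp))
  if (type == "prob") r else max.col(r, ties.method = "first")
}

#' Simulate count profiles from a fitted mixture
#'
#' @param object a `dmm_fit`.
#' @param nsim number of samples to draw.
#' @param seed integer seed.
#' @param depth reads per simulated sample.
#' @param ... unused.
#' @return samples x taxa integer matrix with attribute `"component"`.
#' @export
simulate.dmm_fit <- function(object, nsim = 1, seed = 1L, depth = 5000, ...) {
  set.seed(split_seed(seed, "dmm-simulate"))
  z <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  out <- matrix(0L, nsim, object$S, dimnames = list(NULL,
                                                    colnames(object$alpha)))
  for (i in seq_len(nsim)) {
    p <- rdirichlet_one(object$alpha[z[i], ])
    out[i, ] <- as.integer(stats::rmultinom(1, depth, p))
  }
  attr(out, "component") <- z
  out
}
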