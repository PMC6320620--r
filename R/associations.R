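# Phenotype-microbiome association battery: single-factor PERMANOVA,
# Spearman correlation matrices with per-parameter BH families, group
# tests (Kruskal-Wallis + Dunn, rank-sum, chi-square), PCA factor
# summaries, and covariate-adjusted regression with Box-Cox.

permanova_F <- function(G, H, df_model, df_resid) {
  In <- diag(nrow(G))
  num <- sum(diag(H %*% G %*% H)) / df_model
  R <- In - H
  den <- sum(diag(R %*% G %*% R)) / df_resid
  num / den
}

#' Single-factor PERMANOVA on a distance matrix
#'
#' Gower-centers the squared distances into an inner-product matrix G, forms
#' the hat matrix of the single-factor design (dummy-coded when categorical),
#' and computes `pseudo-F = [tr(HGH)/df_model] / [tr((I-H)G(I-H))/df_resid]`
#' with `R^2 = tr(HGH)/tr(G)`. The permutation P uses the +1 convention
#' `(1 + hits) / (1 + n_perm)`; `n_perm = "exact"` enumerates all label
#' permutations (small n only) and reports the literal proportion.
#'
#' @param D symmetric distance matrix.
#' @param fct factor (categorical, >= 2 levels) or numeric covariate, one
#'   value per sample; samples with missing values are dropped (logged).
#' @param n_perm number of permutations (default 9999) or `"exact"`.
#' @param seed integer seed.
#' @return object of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `df`, `n`, `n_perm`.
#' @export
permanova_single <- function(D, fct, n_perm = 9999L, seed = 1L) {
  D <- as.matrix(D)
  ok <- !is.na(fct)
  if (!all(ok)) {
    message("permanova: dropping ", sum(!ok), " sample(s) with missing factor")
    D <- D[ok, ok, drop = FALSE]
    fct <- fct[ok]
  }
  n <- nrow(D)
  if (is.character(fct)) fct <- factor(fct)
  if (is.factor(fct) && nlevels(droplevels(fct)) < 2)
    stop("factor is constant; nothing to test", call. = FALSE)
  if (is.numeric(fct) && stats::var(fct) == 0)
    stop("factor is constant; nothing to test", call. = FALSE)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  hat_of <- function(f) {
    X <- stats::model.matrix(~f)
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    list(H = Q %*% t(Q), rank = qr_x$rank)
  }
  hx <- hat_of(fct)
  df_model <- hx$rank - 1L
  df_resid <- n - hx$rank
  F_obs <- permanova_F(G, hx$H, df_model, df_resid)
  R2 <- sum(diag(hx$H %*% G %*% hx$H)) / sum(diag(G))
  eps <- 1e-10 * (1 + abs(F_obs))
  if (identical(n_perm, "exact")) {
    if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- permutations_all(n)
    Fp <- vapply(perms, function(p)
      permanova_F(G, hat_of(fct[p])$H, df_model, df_resid), 0)
    pval <- mean(Fp >= F_obs - eps)
    n_used <- length(perms)
  } else {
    set.seed(split_seed(seed, "permanova"))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (permanova_F(G, hat_of(fct[p])$H, df_model, df_resid) >= F_obs - eps)
        hits <- hits + 1L
    }
    pval <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = F_obs, R2 = R2, p_value = pval,
                 df = c(model = df_model, resid = df_resid), n = n,
                 n_perm = n_used),
            class = "permanova_result")
}

# All permutations of 1..n (n small).
permutations_all <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations_all(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.4f, P = %.4g (%s perms)\n",
    x$pseudo_F, x$df["model"], x$df["resid"], x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' PERMANOVA over a list of phenotype factors with BH adjustment
#'
#' Runs [permanova_single()] for each column of `phenotypes` against the same
#' distance matrix and BH-adjusts the permutation P values across factors.
#'
#' @param D distance matrix.
#' @param phenotypes data frame of factors (one test per column).
#' @param n_perm permutations per factor.
#' @param seed integer seed.
#' @return data frame: factor, pseudo_F, R2, n, p_value, p_adj.
#' @export
permanova_battery <- function(D, phenotypes, n_perm = 9999L, seed = 1L) {
  res <- lapply(names(phenotypes), function(nm)
    permanova_single(D, phenotypes[[nm]], n_perm = n_perm,
                     seed = split_seed(seed, paste0("perm-", nm))))
  out <- data.frame(
    factor = names(phenotypes),
    pseudo_F = vapply(res, `[[`, 0, "pseudo_F"),
    R2 = vapply(res, `[[`, 0, "R2"),
    n = vapply(res, `[[`, 0L, "n"),
    p_value = vapply(res, `[[`, 0, "p_value"), stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Spearman correlation matrix with per-parameter BH families
#'
#' Rank correlation (midrank ties) between every column of `X` (parameters)
#' and every column of `Y` (features), on complete pairs. P values are
#' BH-adjusted within each parameter's family by default (`"per_parameter"`)
#' or across the whole matrix (`"global"`). Cells with fewer than
#' `min_pairs` complete pairs or a constant vector are reported as missing.
#'
#' @param X data frame / matrix of continuous parameters.
#' @param Y data frame / matrix of features (abundances or other parameters).
#' @param adjust_scope `"per_parameter"` or `"global"`.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return data frame: parameter, feature, n, rho, p_value, p_adj,
#'   significant (adjusted P < 0.05).
#' @export
spearman_matrix <- function(X, Y, adjust_scope = c("per_parameter", "global"),
                            min_pairs = 3L) {
  adjust_scope <- match.arg(adjust_scope)
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  rows <- list()
  for (px in names(X)) for (py in names(Y)) {
    x <- X[[px]]; y <- Y[[py]]
    ok <- stats::complete.cases(x, y)
    n_ok <- sum(ok)
    if (n_ok < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = px, feature = py, n = n_ok, rho = NA_real_,
        p_value = NA_real_, stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = px, feature = py, n = n_ok, rho = unname(ct$estimate),
      p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  if (adjust_scope == "per_parameter") {
    for (px in unique(out$parameter)) {
      sel <- out$parameter == px
      out$p_adj[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
    }
  } else {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Group comparison tests
#'
#' Continuous values across >= 2 groups: Kruskal-Wallis H with tie
#' correction, Dunn's post-hoc pairwise z tests (BH-adjusted), and the
#' two-group Wilcoxon rank-sum where applicable. Categorical values:
#' Pearson chi-square on the contingency table (no continuity correction by
#' default).
#'
#' @param values numeric vector (continuous) or vector of categories.
#' @param groups per-sample group labels.
#' @param type `"continuous"` or `"categorical"`.
#' @param correct Yates continuity correction for the chi-square
#'   (default FALSE).
#' @return list; for continuous: `kruskal` (htest), `dunn` (data frame with
#'   pairwise z, p, p_adj), `ranksum` (htest, 2 groups only); for
#'   categorical: `chisq` (htest).
#' @export
group_tests <- function(values, groups, type = c("continuous", "categorical"),
                        correct = FALSE) {
  type <- match.arg(type)
  groups <- as.factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("need >= 2 nonempty groups", call. = FALSE)
  if (type == "categorical") {
    return(list(chisq = stats::chisq.test(table(values, groups),
                                          correct = correct)))
  }
  kw <- stats::kruskal.test(values, groups)
  dunn <- dunn_posthoc(values, groups)
  rs <- if (nlevels(groups) == 2L)
    stats::wilcox.test(values[groups == levels(groups)[1]],
                       values[groups == levels(groups)[2]], exact = FALSE)
  else NULL
  list(kruskal = kw, dunn = dunn, ranksum = rs)
}

# Dunn's pairwise z tests on the joint ranks with tie correction.
dunn_posthoc <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    na <- sum(groups == a); nb <- sum(groups == b)
    ra <- mean(r[groups == a]); rb <- mean(r[groups == b])
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    z[i] <- (ra - rb) / sigma
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group_a = combs[1, ], group_b = combs[2, ], z = z, p_value = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' PCA of continuous phenotype factors with major-contributor flags
#'
#' Standardizes the complete-case continuous block (zero-variance variables
#' dropped with a warning), decomposes it by singular values, and flags
#' variables whose |loading| on PC1 or PC2 reaches the threshold as major
#' contributors. Per-sample PC scores are returned for downstream group
#' comparisons.
#'
#' @param X data frame / matrix of continuous variables (>= 2).
#' @param loading_threshold |loading| cutoff for the contributor flag
#'   (default 0.2).
#' @return list: `scores` (samples x PCs), `loadings` (variables x PCs),
#'   `variance_fraction`, `contributors` (data frame variable/PC1/PC2
#'   loadings + flag), `n` (complete cases used).
#' @export
pca_factors <- function(X, loading_threshold = 0.2) {
  X <- as.data.frame(X)
  cc <- stats::complete.cases(X)
  message("pca_factors: using ", sum(cc), " complete cases of ", nrow(X))
  X <- X[cc, , drop = FALSE]
  v <- vapply(X, stats::sd, 0)
  if (any(v == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(names(X)[v == 0], collapse = ", "), call. = FALSE)
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need >= 2 variables", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  L <- pc$rotation
  contributors <- data.frame(
    variable = rownames(L),
    pc1_loading = L[, 1],
    pc2_loading = if (ncol(L) >= 2) L[, 2] else NA_real_,
    stringsAsFactors = FALSE)
  contributors$major <- abs(contributors$pc1_loading) >= loading_threshold |
    (!is.na(contributors$pc2_loading) &
       abs(contributors$pc2_loading) >= loading_threshold)
  list(scores = pc$x, loadings = L, variance_fraction = vf,
       contributors = contributors, n = nrow(X))
}

#' Box-Cox transform via grid profile likelihood
#'
#' Selects the lambda on the grid maximizing the profile log-likelihood of
#' the (optionally covariate-adjusted) normal model, and returns the
#' transformed outcome `(y^lambda - 1) / lambda` (`log(y)` at lambda = 0).
#' Non-positive outcomes are shifted by `min + epsilon` with a warning.
#'
#' @param y positive outcome vector.
#' @param design optional model frame / data frame of covariates defining
#'   the regression whose residual normality is targeted (intercept-only if
#'   `NULL`).
#' @param lambda_grid candidate lambdas (default `seq(-2, 2, 0.1)`).
#' @return list: `lambda`, `y_transformed`, `shift` applied.
#' @export
boxcox_lambda <- function(y, design = NULL, lambda_grid = seq(-2, 2, 0.1)) {
  if (stats::var(y, na.rm = TRUE) == 0) stop("constant outcome", call. = FALSE)
  shift <- 0
  if (any(y <= 0, na.rm = TRUE)) {
    shift <- -min(y, na.rm = TRUE) + 1e-6
    warning("non-positive outcome shifted by ", signif(shift, 4),
            call. = FALSE)
    y <- y + shift
  }
  df <- if (is.null(design)) data.frame(.y = y)
        else cbind(data.frame(.y = y), as.data.frame(design))
  fml <- if (is.null(design)) .y ~ 1
         else stats::as.formula(paste(".y ~", paste(setdiff(names(df), ".y"),
                                                    collapse = " + ")))
  bc <- MASS::boxcox(fml, data = df, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  yt <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(lambda = lambda, y_transformed = yt, shift = shift)
}

#' Covariate-adjusted linear regression with residual-normality repair
#'
#' Ordinary least squares of the outcome on the exposure plus covariates.
#' If the Shapiro-Wilk P of the residuals is <= 0.05, the outcome is Box-Cox
#' transformed (lambda from the grid profile likelihood) and the model
#' refit. Confounder sets follow the two standard models: model 1 adjusts
#' for sex, age and BMI z-score; model 2 additionally for all early events —
#' the caller supplies the matching `covars`.
#'
#' @param y numeric outcome.
#' @param x numeric/factor exposure.
#' @param covars data frame of adjustment covariates or `NULL`.
#' @param model_id label (1 or 2) recorded in the result.
#' @return object of class `glm_result`: `beta`, `se`, `p_value` (two-
#'   tailed, exposure coefficient), `lambda` (`NA` when no transform),
#'   `shapiro_p` (post-transformation), `n`, `model_id`, `fit`.
#' @export
glm_adjusted <- function(y, x, covars = NULL, model_id = 1L) {
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covars)) df <- cbind(df, as.data.frame(covars))
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  p_design <- ncol(df)
  if (nrow(df) < p_design + 2)
    stop("too few complete cases (", nrow(df), ")", call. = FALSE)
  message("glm_adjusted: ", nrow(df), " complete cases")
  rhs <- paste(setdiff(names(df), ".y"), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sw <- function(f) {
    r <- stats::residuals(f)
    if (length(r) < 3 || length(r) > 5000) return(NA_real_)
    stats::shapiro.test(r)$p.value
  }
  shapiro_p <- sw(fit)
  lambda <- NA_real_
  if (!is.na(shapiro_p) && shapiro_p <= 0.05) {
    design <- df[, setdiff(names(df), ".y"), drop = FALSE]
    bc <- boxcox_lambda(df$.y, design = design)
    lambda <- bc$lambda
    df$.y <- bc$y_transformed
    fit <- stats::lm(fml, data = df)
    shapiro_p <- sw(fit)
  }
  sm <- summary(fit)$coefficients
  xrow <- grep("^\\.x", rownames(sm))[1]
  structure(list(beta = sm[xrow, 1], se = sm[xrow, 2],
                 p_value = sm[xrow, 4], lambda = lambda,
                 shapiro_p = shapiro_p, n = nrow(df),
                 model_id = model_id, fit = fit),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf(
    "Adjusted regression (model %s, n = %d): beta = %.4g (SE %.3g), P = %.4g\n",
    x$model_id, x$n, x$beta, x$se, x$p_value))
  if (!is.na(x$lambda))
    cat(sprintf("  Box-Cox lambda = %.2f applied\n", x$lambda))
  cat(sprintf("  residual Shapiro-Wilk P = %.3g\n", x$shapiro_p))
  invisible(x)
}

#' Overweight stratification of gene richness
#'
#' Dichotomizes BMI z-score at the overweight cutoff (default 1.04, the 85th
#' percentile of the standard normal) and gene richness at a count
#' threshold, and rank-sum-compares BMI z between low- and high-richness
#' children within each BMI stratum.
#'
#' @param bmi_z numeric BMI z-scores.
#' @param gene_richness per-sample gene counts (see [richness()]).
#' @param bmi_cutoff overweight threshold (default 1.04).
#' @param richness_cutoff low-richness threshold (default 6e5, configurable
#'   for synthetic scales).
#' @return list with the 2-way classification table and the within-stratum
#'   rank-sum tests.
#' @export
overweight_richness_test <- function(bmi_z, gene_richness, bmi_cutoff = 1.04,
                                     richness_cutoff = 6e5) {
  ow <- ifelse(bmi_z >= bmi_cutoff, "overweight", "lean")
  lowrich <- ifelse(gene_richness < richness_cutoff, "low", "high")
  tests <- lapply(stats::setNames(nm = unique(ow)), function(g) {
    sel <- ow == g
    if (length(unique(lowrich[sel])) < 2) return(NULL)
    stats::wilcox.test(bmi_z[sel & lowrich == "low"],
                       bmi_z[sel & lowrich == "high"], exact = FALSE)
  })
  list(table = table(bmi = ow, richness = lowrich), tests = tests,
       bmi_cutoff = bmi_cutoff, richness_cutoff = richness_cutoff)
}
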