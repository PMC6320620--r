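# Synthetic cohort generator: Dirichlet-multinomial community mixtures,
# gene-level expansion with taxonomic/KO annotation, planted basis
# correlations, planted module enrichment, and component-dependent
# phenotypes, all with exported ground truth for recovery testing.

#' Build and validate a synthetic-cohort configuration
#'
#' Defines the generative model behind all synthetic fixtures: a K-component
#' Dirichlet-multinomial mixture over taxa, a gene layer that distributes each
#' taxon's reads over its genes (with partial taxonomic/KO annotation and
#' module-level abundance boosts), and phenotype covariates whose
#' distributions depend on the mixture component.
#'
#' @param n_samples number of samples.
#' @param n_taxa number of taxa (species-level features).
#' @param genes_per_taxon genes carried by each taxon.
#' @param depth sequencing depth per sample: a single fixed value or a
#'   length-2 range `c(min, max)` sampled uniformly per sample.
#' @param K number of mixture components.
#' @param weights mixture proportions (length K, summing to 1).
#' @param alpha optional `K x n_taxa` matrix of positive Dirichlet parameters.
#'   If `NULL`, derived from `separation`/`base_alpha`: component k has
#'   `alpha = base_alpha` everywhere except taxon k, which gets `separation`,
#'   so each component is dominated by a distinct taxon.
#' @param separation,base_alpha scalars used to derive `alpha` when it is not
#'   supplied.
#' @param correlation_spec data frame with columns `taxon_a`, `taxon_b`,
#'   `rho` giving planted basis correlations (used by
#'   [sample_correlated_counts()]), or `NULL`.
#' @param module_spec list of module definitions, each a list with elements
#'   `module_id`, `kos` (character vector), `component` (enriched component
#'   index, or `NA` for an unenriched background module) and `multiplier`
#'   (> 0 abundance boost in the enriched component).
#' @param phenotype_spec list of covariate definitions, each a list with
#'   `name`, `type` (`"continuous"`, `"categorical"` or `"linked"`) and type-
#'   specific parameters; see [sample_phenotypes()].
#' @param unannotated_fraction fraction of genes left without taxonomic
#'   annotation (default 0.35).
#' @param ko_fraction fraction of genes carrying a KO label (default 0.8).
#' @param n_kos size of the KO pool; defaults to one KO per ~10 genes.
#' @param seed root integer seed; every generator derives its stream from it.
#' @return a validated object of class `synthetic_config`.
#' @seealso [preset_config()] for the shipped three-enterotype preset.
#' @export
synthetic_config <- function(n_samples, n_taxa, genes_per_taxon = 10L,
                             depth = 5000, K = 1L,
                             weights = rep(1 / K, K),
                             alpha = NULL, separation = 15, base_alpha = 0.5,
                             correlation_spec = NULL, module_spec = NULL,
                             phenotype_spec = NULL,
                             unannotated_fraction = 0.35, ko_fraction = 0.8,
                             n_kos = NULL, seed = 1L) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  if (!length(depth) %in% 1:2) stop("depth must be a scalar or a range",
                                    call. = FALSE)
  if (n_samples < 1 || n_taxa < 1 || genes_per_taxon < 1)
    stop("n_samples, n_taxa and genes_per_taxon must be positive",
         call. = FALSE)
  if (length(weights) != K || abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("weights must be a length-K simplex vector (sum 1)", call. = FALSE)
  if (is.null(alpha)) {
    if (K > n_taxa) stop("need n_taxa >= K to assign dominant taxa",
                         call. = FALSE)
    alpha <- matrix(base_alpha, nrow = K, ncol = n_taxa)
    for (k in seq_len(K)) alpha[k, k] <- separation
  }
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(K, n_taxa)))
    stop("alpha must be K x n_taxa", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha entries must be > 0", call. = FALSE)
  if (!is.null(correlation_spec)) {
    cs <- as.data.frame(correlation_spec)
    stopifnot(all(c("taxon_a", "taxon_b", "rho") %in% names(cs)))
    if (any(abs(cs$rho) >= 1))
      stop("basis correlations must satisfy |rho| < 1", call. = FALSE)
    if (any(cs$taxon_a > n_taxa | cs$taxon_b > n_taxa | cs$taxon_a < 1 |
            cs$taxon_b < 1 | cs$taxon_a == cs$taxon_b))
      stop("correlation_spec references invalid taxa", call. = FALSE)
    correlation_spec <- cs
  }
  if (!is.null(module_spec)) {
    for (m in module_spec) {
      stopifnot(all(c("module_id", "kos", "multiplier") %in% names(m)))
      if (m$multiplier <= 0)
        stop("module effect multiplier must be > 0", call. = FALSE)
      if (!is.na(m$component) && (m$component < 1 || m$component > K))
        stop("module_spec references unknown component ", m$component,
             call. = FALSE)
    }
  }
  if (is.null(n_kos))
    n_kos <- max(20L, round(n_taxa * genes_per_taxon / 10))
  structure(list(
    n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
    genes_per_taxon = as.integer(genes_per_taxon), depth = depth,
    K = as.integer(K), weights = weights, alpha = alpha,
    correlation_spec = correlation_spec, module_spec = module_spec,
    phenotype_spec = phenotype_spec,
    unannotated_fraction = unannotated_fraction, ko_fraction = ko_fraction,
    n_kos = as.integer(n_kos), seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Shipped synthetic presets
#'
#' `"three_enterotype"` emulates a school-age gut cohort stratified into three
#' community types: 200 samples, 50 taxa at depth 5000, three equally weighted
#' mixture components each dominated by a distinct taxon, one KEGG-like module
#' enriched per component (plus unenriched background modules), and an
#' insulin-like blood covariate whose inverse dependence on a dietary-fiber
#' covariate is restricted to the first two components.
#'
#' @param name preset name; currently `"three_enterotype"`.
#' @param ... overrides passed to [synthetic_config()] (e.g. smaller
#'   `n_samples` for quick runs).
#' @return a `synthetic_config`.
#' @export
preset_config <- function(name = "three_enterotype", ...) {
  name <- match.arg(name)
  kos <- sprintf("KO%04d", 1:30)
  module_spec <- list(
    list(module_id = "M001", kos = kos[1:5],   component = 1L, multiplier = 6),
    list(module_id = "M002", kos = kos[6:10],  component = 2L, multiplier = 6),
    list(module_id = "M003", kos = kos[11:15], component = 3L, multiplier = 6),
    list(module_id = "M004", kos = kos[16:20], component = NA, multiplier = 1),
    list(module_id = "M005", kos = kos[21:25], component = NA, multiplier = 1),
    list(module_id = "M006", kos = kos[26:30], component = NA, multiplier = 1)
  )
  phenotype_spec <- list(
    list(name = "sex", type = "categorical", levels = c("f", "m"),
         probs = matrix(0.5, nrow = 3, ncol = 2)),
    list(name = "age", type = "continuous", means = c(7.3, 7.3, 7.3),
         sd = 0.8),
    list(name = "bmi_z", type = "continuous", means = c(0, 0, 0), sd = 1),
    list(name = "fiber", type = "continuous", means = c(16, 18, 12), sd = 3),
    # insulin-like outcome: inverse fiber dependence only in components 1-2
    list(name = "insulin", type = "linked", source = "fiber",
         intercepts = c(90, 90, 60), slopes = c(-2, -2, 0), sd = 5)
  )
  defaults <- list(n_samples = 200L, n_taxa = 50L, genes_per_taxon = 12L,
                   depth = 5000, K = 3L, weights = rep(1 / 3, 3),
                   separation = 15, base_alpha = 0.5,
                   module_spec = module_spec, phenotype_spec = phenotype_spec,
                   seed = 20260901L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

new_ground_truth <- function(labels, config, planted_edges = NULL,
                             basis_log = NULL) {
  enriched <- NULL
  if (!is.null(config$module_spec)) {
    enriched <- do.call(rbind, lapply(config$module_spec, function(m)
      data.frame(module_id = m$module_id, component = m$component,
                 multiplier = m$multiplier)))
  }
  structure(list(labels = labels, alpha = config$alpha,
                 weights = config$weights, planted_edges = planted_edges,
                 enriched_modules = enriched,
                 phenotype_effects = config$phenotype_spec,
                 basis_log = basis_log),
            class = "ground_truth")
}

sample_depths <- function(config) {
  d <- config$depth
  if (length(d) == 1L) rep(as.integer(d), config$n_samples)
  else as.integer(round(stats::runif(config$n_samples, d[1], d[2])))
}

#' Draw taxa counts from a Dirichlet-multinomial mixture
#'
#' For each sample a component is drawn from the mixture weights, a
#' composition from that component's Dirichlet, and integer counts from a
#' multinomial at the configured depth. Fully reproducible from the config
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (samples x taxa integer matrix) and `truth`
#'   (a `ground_truth` with per-sample component labels).
#' @export
sample_dmm_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(split_seed(config$seed, "dmm-counts"))
  n <- config$n_samples
  z <- sample.int(config$K, n, replace = TRUE, prob = config$weights)
  depths <- sample_depths(config)
  counts <- matrix(0L, nrow = n, ncol = config$n_taxa,
                   dimnames = list(sprintf("s%03d", seq_len(n)),
                                   sprintf("t%02d", seq_len(config$n_taxa))))
  for (i in seq_len(n)) {
    p <- rdirichlet_one(config$alpha[z[i], ])
    counts[i, ] <- as.integer(stats::rmultinom(1, depths[i], p))
  }
  list(counts = counts, truth = new_ground_truth(z, config))
}

#' Draw taxa counts with planted basis correlations
#'
#' Latent log-abundances are multivariate normal with unit variances and the
#' correlation structure given by `config$correlation_spec` (unspecified
#' pairs 0); the exponentiated basis is closed to compositions and sampled
#' multinomially to depth. This is the null/alternative generator for the
#' SparCC stage.
#'
#' @param config a [synthetic_config()]; `correlation_spec` may be `NULL`
#'   (independent null case).
#' @return list with `counts` and `truth`; `truth$basis_log` holds the latent
#'   log-abundance draws and `truth$planted_edges` the planted pairs.
#' @export
sample_correlated_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(split_seed(config$seed, "correlated-counts"))
  n <- config$n_samples; S <- config$n_taxa
  Sigma <- diag(S)
  cs <- config$correlation_spec
  if (!is.null(cs) && nrow(cs) > 0) {
    for (r in seq_len(nrow(cs))) {
      Sigma[cs$taxon_a[r], cs$taxon_b[r]] <- cs$rho[r]
      Sigma[cs$taxon_b[r], cs$taxon_a[r]] <- cs$rho[r]
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("completed correlation matrix is not positive semi-definite",
         call. = FALSE)
  R <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  L <- matrix(stats::rnorm(n * S), nrow = n) %*% R
  basis <- exp(L)
  depths <- sample_depths(config)
  counts <- matrix(0L, nrow = n, ncol = S,
                   dimnames = list(sprintf("s%03d", seq_len(n)),
                                   sprintf("t%02d", seq_len(S))))
  for (i in seq_len(n))
    counts[i, ] <- as.integer(stats::rmultinom(1, depths[i],
                                               basis[i, ] / sum(basis[i, ])))
  dimnames(L) <- dimnames(counts)
  list(counts = counts,
       truth = new_ground_truth(rep(1L, n), config, planted_edges = cs,
                                basis_log = L))
}

#' Expand taxa counts to a gene-level table with annotation
#'
#' Distributes each taxon's reads multinomially over its genes using fixed
#' per-gene weights (so gene abundance ranks are stable across samples),
#' leaves a configurable fraction of genes taxonomically unannotated, assigns
#' KO labels from a pool, and boosts genes carrying the KOs of each enriched
#' module in samples belonging to that module's target component. Per-sample
#' totals are conserved exactly.
#'
#' @param taxa_counts samples x taxa integer matrix.
#' @param config a [synthetic_config()].
#' @param truth the matching `ground_truth` (component labels drive module
#'   boosts); `NULL` disables boosting.
#' @return list with `gene_counts` (samples x genes), `annotation`
#'   (data frame: gene_id, genus, species, ko) and `module_catalog`
#'   (named list module_id -> KO vector).
#' @export
expand_to_genes <- function(taxa_counts, config, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  check_counts(taxa_counts, "taxa counts")
  set.seed(split_seed(config$seed, "expand-genes"))
  n <- nrow(taxa_counts); S <- ncol(taxa_counts); G <- config$genes_per_taxon
  gene_id <- as.vector(t(outer(seq_len(S), seq_len(G),
                               function(t, g) sprintf("t%02d_g%02d", t, g))))
  taxon_of <- rep(seq_len(S), each = G)
  # stable per-gene weights within each taxon
  w <- stats::rgamma(S * G, shape = 2, rate = 1) + 1e-6
  # annotation: genus == species == taxon here (one species per genus);
  # a fraction of genes is left taxonomically unannotated
  unann <- stats::runif(S * G) < config$unannotated_fraction
  # KO pool always covers the module-spec KOs; labels are cycled over the
  # pool and randomly permuted across genes so KO-taxon coupling is random
  module_kos <- unique(unlist(lapply(config$module_spec, `[[`, "kos")))
  kopool <- union(module_kos, sprintf("KO%04d", seq_len(config$n_kos)))
  kopool <- kopool[seq_len(max(config$n_kos, length(module_kos)))]
  ko <- kopool[((seq_len(S * G) - 1L) %% length(kopool)) + 1L]
  ko <- sample(ko)
  ko[stats::runif(S * G) > config$ko_fraction] <- NA_character_
  annotation <- data.frame(
    gene_id = gene_id,
    genus = ifelse(unann, NA_character_, sprintf("g%02d", taxon_of)),
    species = ifelse(unann, NA_character_, sprintf("s%02d", taxon_of)),
    ko = ko, stringsAsFactors = FALSE)
  module_catalog <- NULL
  boost_ko <- list()
  if (!is.null(config$module_spec)) {
    module_catalog <- stats::setNames(
      lapply(config$module_spec, `[[`, "kos"),
      vapply(config$module_spec, `[[`, "", "module_id"))
    for (m in config$module_spec)
      if (!is.na(m$component))
        boost_ko[[as.character(m$component)]] <-
          c(boost_ko[[as.character(m$component)]],
            list(list(kos = m$kos, mult = m$multiplier)))
  }
  labels <- if (!is.null(truth)) truth$labels else rep(NA_integer_, n)
  gene_counts <- matrix(0L, nrow = n, ncol = S * G,
                        dimnames = list(rownames(taxa_counts), gene_id))
  gene_ko <- annotation$ko
  for (i in seq_len(n)) {
    wi <- w
    z <- labels[i]
    if (!is.na(z) && !is.null(boost_ko[[as.character(z)]]))
      for (b in boost_ko[[as.character(z)]])
        wi[gene_ko %in% b$kos] <- wi[gene_ko %in% b$kos] * b$mult
    for (t in seq_len(S)) {
      ct <- taxa_counts[i, t]
      if (ct == 0) next
      idx <- which(taxon_of == t)
      gene_counts[i, idx] <- as.integer(
        stats::rmultinom(1, ct, wi[idx] / sum(wi[idx])))
    }
  }
  list(gene_counts = gene_counts, annotation = annotation,
       module_catalog = module_catalog)
}

#' Draw phenotype covariates with component-dependent effects
#'
#' Continuous covariates are component mean plus Gaussian noise; categorical
#' covariates are drawn from component-dependent probabilities; "linked"
#' covariates are a linear function of a previously generated covariate with
#' component-specific intercepts and slopes plus noise (used to plant
#' enterotype-restricted associations such as the fiber-insulin link).
#'
#' @param truth a `ground_truth` (supplies per-sample component labels).
#' @param config a [synthetic_config()] with a `phenotype_spec`.
#' @return data frame of covariates with a `types` attribute
#'   (named character vector, `"continuous"`/`"categorical"`), rownames are
#'   sample ids.
#' @export
sample_phenotypes <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "ground_truth"))
  if (is.null(config$phenotype_spec))
    stop("config has no phenotype_spec", call. = FALSE)
  set.seed(split_seed(config$seed, "phenotypes"))
  z <- truth$labels
  n <- length(z)
  out <- data.frame(row.names = sprintf("s%03d", seq_len(n)))
  types <- character(0)
  for (ph in config$phenotype_spec) {
    if (ph$type == "continuous") {
      out[[ph$name]] <- ph$means[z] + stats::rnorm(n, 0, ph$sd)
      types[ph$name] <- "continuous"
    } else if (ph$type == "categorical") {
      v <- character(n)
      for (i in seq_len(n))
        v[i] <- sample(ph$levels, 1, prob = ph$probs[z[i], ])
      out[[ph$name]] <- v
      types[ph$name] <- "categorical"
    } else if (ph$type == "linked") {
      if (!ph$source %in% names(out))
        stop("linked covariate '", ph$name, "' references '", ph$source,
             "' which has not been generated yet", call. = FALSE)
      out[[ph$name]] <- ph$intercepts[z] + ph$slopes[z] * out[[ph$source]] +
        stats::rnorm(n, 0, ph$sd)
      types[ph$name] <- "continuous"
    } else {
      stop("unknown covariate type '", ph$type, "'", call. = FALSE)
    }
  }
  attr(out, "types") <- types
  out
}
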