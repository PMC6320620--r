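# Configuration-driven pipeline: simulate -> profile -> enterotype ->
# network -> enrich -> associate, with per-stage TSV outputs, manifests
# and seed management. All stochastic stages derive their stream from the
# root seed, so re-running a config reproduces outputs bit-identically.

STAGE_ORDER <- c("simulate", "profile", "enterotype", "network", "enrich",
                 "associate")

#' Default pipeline configuration
#'
#' @param preset synthetic preset name fed to [preset_config()] (inputs may
#'   alternatively be supplied on disk; see [run_pipeline()]).
#' @param seed root integer seed for every stochastic stage.
#' @param rarefy_depth rarefaction depth (default 5000, the synthetic-scale
#'   default; 2e7 is the documented real-data depth).
#' @param k_range candidate cluster numbers.
#' @param method enterotyping protocol.
#' @param dmm_restarts EM restarts per DMM fit.
#' @param sparcc_bootstraps bootstrap count for pseudo-P values.
#' @param sparcc_inner_draws SparCC inner Dirichlet draws.
#' @param edge_cutoff pseudo-P cutoff for exported edges.
#' @param n_perm PERMANOVA permutations.
#' @param preset_overrides named list forwarded to [preset_config()].
#' @return a named list (class `run_config`), losslessly serializable to
#'   YAML.
#' @export
default_run_config <- function(preset = "three_enterotype", seed = 1L,
                               rarefy_depth = 5000, k_range = 1:6,
                               method = "dmm", dmm_restarts = 5L,
                               sparcc_bootstraps = 1000L,
                               sparcc_inner_draws = 20L, edge_cutoff = 0.01,
                               n_perm = 9999L, preset_overrides = list()) {
  structure(list(preset = preset, seed = as.integer(seed),
                 rarefy_depth = rarefy_depth,
                 k_range = as.integer(k_range), method = method,
                 dmm_restarts = as.integer(dmm_restarts),
                 sparcc_bootstraps = as.integer(sparcc_bootstraps),
                 sparcc_inner_draws = as.integer(sparcc_inner_draws),
                 edge_cutoff = edge_cutoff, n_perm = as.integer(n_perm),
                 preset_overrides = preset_overrides),
            class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML path.
#' @name config_io
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$k_range <- as.integer(cfg$k_range)
  do.call(default_run_config, cfg)
}

stage_manifest <- function(outdir, stage, params, files) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("microstrat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    params = params,
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

require_stage_output <- function(outdir, file, stage_needed) {
  if (!file.exists(file.path(outdir, file)))
    stop("missing output '", file, "'; run stage '", stage_needed,
         "' first", call. = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing per-stage TSV
#' outputs plus a JSON manifest (package version, parameters, output
#' checksums) into `outdir`. With a synthetic preset the `simulate` stage
#' writes the generated tables and ground truth; alternatively, pre-existing
#' `gene_counts.tsv`, `annotation.tsv`, `module_catalog.tsv` and
#' `phenotypes.tsv` in `outdir` (the formats written by the io functions)
#' serve as inputs and `simulate` is skipped.
#'
#' @param config a [default_run_config()] list.
#' @param outdir output directory (created if needed).
#' @param stages `"all"` or a subset of
#'   simulate/profile/enterotype/network/enrich/associate.
#' @return invisibly, `outdir`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir,
                         stages = "all") {
  if (identical(stages, "all")) stages <- STAGE_ORDER
  bad <- setdiff(stages, STAGE_ORDER)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- STAGE_ORDER[STAGE_ORDER %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if ("simulate" %in% stages) {
    cfg <- do.call(preset_config,
                   c(list(name = config$preset,
                          seed = split_seed(seed, "simulate")),
                     config$preset_overrides))
    sim <- sample_dmm_counts(cfg)
    genes <- expand_to_genes(sim$counts, cfg, sim$truth)
    pheno <- sample_phenotypes(sim$truth, cfg)
    write_count_table(sim$counts, file.path(outdir, "taxa_counts.tsv"))
    write_count_table(genes$gene_counts, file.path(outdir, "gene_counts.tsv"))
    write_annotation(genes$annotation, file.path(outdir, "annotation.tsv"))
    write_module_catalog(genes$module_catalog,
                         file.path(outdir, "module_catalog.tsv"))
    write_phenotypes(pheno, file.path(outdir, "phenotypes.tsv"))
    write_ground_truth(sim$truth, outdir)
    stage_manifest(outdir, "simulate",
                   list(preset = config$preset, seed = seed),
                   c("taxa_counts.tsv", "gene_counts.tsv", "annotation.tsv",
                     "module_catalog.tsv", "phenotypes.tsv"))
    message("simulate: wrote synthetic cohort (n = ", nrow(sim$counts), ")")
  }

  if ("profile" %in% stages) {
    for (f in c("gene_counts.tsv", "annotation.tsv"))
      require_stage_output(outdir, f, "simulate")
    gene_counts <- read_count_table(file.path(outdir, "gene_counts.tsv"))
    ann <- read_annotation(file.path(outdir, "annotation.tsv"))
    rare <- rarefy(gene_counts, config$rarefy_depth,
                   seed = split_seed(seed, "profile"))
    gene_abund <- relative_abundance(rare)
    species <- aggregate_abundance(gene_abund, ann, "species")
    ko <- aggregate_abundance(gene_abund, ann, "ko")
    div <- data.frame(sample_id = rownames(rare),
                      gene_richness = richness(rare),
                      shannon = shannon_diversity(gene_abund))
    write_count_table(rare, file.path(outdir, "gene_counts_rarefied.tsv"))
    write_count_table(species, file.path(outdir, "species_abundance.tsv"))
    write_count_table(ko, file.path(outdir, "ko_abundance.tsv"))
    utils::write.table(div, file.path(outdir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_manifest(outdir, "profile", list(depth = config$rarefy_depth),
                   c("gene_counts_rarefied.tsv", "species_abundance.tsv",
                     "ko_abundance.tsv", "diversity.tsv"))
    message("profile: rarefied to ", config$rarefy_depth,
            " reads; ", nrow(rare), " samples retained")
  }

  if ("enterotype" %in% stages) {
    require_stage_output(outdir, "species_abundance.tsv", "profile")
    counts <- round(read_count_table(
      file.path(outdir, "species_abundance.tsv")) * config$rarefy_depth)
    storage.mode(counts) <- "integer"
    sel <- select_k(counts, method = config$method,
                    k_range = config$k_range,
                    seed = split_seed(seed, "enterotype"),
                    restarts = config$dmm_restarts)
    utils::write.table(sel$criteria, file.path(outdir, "model_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(counts), enterotype = sel$labels),
      file.path(outdir, "enterotypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    stage_manifest(outdir, "enterotype",
                   list(method = config$method, k = sel$selected_k),
                   c("model_selection.tsv", "enterotypes.tsv"))
    message("enterotype: ", config$method, " selected k = ", sel$selected_k)
  }

  if ("network" %in% stages) {
    require_stage_output(outdir, "species_abundance.tsv", "profile")
    counts <- round(read_count_table(
      file.path(outdir, "species_abundance.tsv")) * config$rarefy_depth)
    counts <- counts[, colnames(counts) != "unannotated", drop = FALSE]
    storage.mode(counts) <- "integer"
    fit <- sparcc_pseudo_p(counts, B = config$sparcc_bootstraps,
                           inner_draws = config$sparcc_inner_draws,
                           seed = split_seed(seed, "network"))
    edges <- significant_edges(fit, cutoff = config$edge_cutoff)
    write_count_table(fit$rho, file.path(outdir, "sparcc_rho.tsv"))
    write_count_table(fit$pseudo_p, file.path(outdir, "sparcc_pseudo_p.tsv"))
    write_edge_list(edges, file.path(outdir, "network_edges.tsv"))
    stage_manifest(outdir, "network",
                   list(B = config$sparcc_bootstraps,
                        cutoff = config$edge_cutoff),
                   c("sparcc_rho.tsv", "sparcc_pseudo_p.tsv",
                     "network_edges.tsv"))
    message("network: ", nrow(edges), " significant edge(s)")
  }

  if ("enrich" %in% stages) {
    for (f in c("ko_abundance.tsv", "module_catalog.tsv", "enterotypes.tsv"))
      require_stage_output(outdir, f,
                           if (f == "enterotypes.tsv") "enterotype"
                           else "profile")
    ko <- read_count_table(file.path(outdir, "ko_abundance.tsv"))
    modules <- read_module_catalog(file.path(outdir, "module_catalog.tsv"))
    et <- utils::read.delim(file.path(outdir, "enterotypes.tsv"))
    labels <- stats::setNames(et$enterotype, et$sample_id)[rownames(ko)]
    all_scores <- list()
    for (k in sort(unique(labels))) {
      kd <- ko_differential(ko, rownames(ko)[labels == k],
                            rownames(ko)[labels != k])
      rs <- reporter_scores(kd, modules,
                            seed = split_seed(seed, paste0("enrich-", k)))
      rs$contrast <- paste0("E", k, "_vs_rest")
      all_scores[[as.character(k)]] <- rs
    }
    scores <- do.call(rbind, all_scores)
    utils::write.table(scores, file.path(outdir, "reporter_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_manifest(outdir, "enrich", list(contrast = "one_vs_rest"),
                   "reporter_scores.tsv")
    message("enrich: ", sum(scores$significant), " significant module-",
            "contrast pair(s)")
  }

  if ("associate" %in% stages) {
    for (f in c("species_abundance.tsv", "phenotypes.tsv", "enterotypes.tsv"))
      require_stage_output(outdir, f,
                           if (f == "phenotypes.tsv") "simulate"
                           else if (f == "enterotypes.tsv") "enterotype"
                           else "profile")
    species <- read_count_table(file.path(outdir, "species_abundance.tsv"))
    pheno <- read_phenotypes(file.path(outdir, "phenotypes.tsv"))
    pheno <- pheno[rownames(species), , drop = FALSE]
    types <- attr(pheno, "types")
    D <- bray_curtis(species)
    cont <- names(types)[types == "continuous"]
    perma <- permanova_battery(D, pheno[, cont, drop = FALSE],
                               n_perm = config$n_perm,
                               seed = split_seed(seed, "associate"))
    sp_cor <- spearman_matrix(pheno[, cont, drop = FALSE],
                              as.data.frame(species))
    utils::write.table(perma, file.path(outdir, "permanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sp_cor, file.path(outdir, "spearman.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_manifest(outdir, "associate", list(n_perm = config$n_perm),
                   c("permanova.tsv", "spearman.tsv"))
    message("associate: ", sum(perma$p_adj < 0.05), " factor(s) at ",
            "adjusted P < 0.05")
  }

  invisible(outdir)
}
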