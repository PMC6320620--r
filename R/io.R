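# Plain-text TSV readers/writers. On-disk convention for count/abundance
# tables: features as rows, samples as columns (first column = feature id);
# in-memory convention everywhere else: samples x features.

#' Write / read a count or abundance table
#'
#' @param x samples x features matrix.
#' @param path TSV path (features as rows on disk).
#' @name table_io
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(feature_id = colnames(x), t(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed table in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1] + 1L
    stop("non-numeric entries in ", path, " (column ", bad, ")",
         call. = FALSE)
  }
  rownames(m) <- df[[1]]
  t(m)
}

#' Write / read a gene annotation map
#'
#' TSV with columns gene_id, genus, species, ko; empty fields mean
#' unannotated.
#'
#' @param annotation annotation data frame.
#' @param path TSV path.
#' @name annotation_io
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("gene_id", "genus", "species", "ko")
  if (!all(need %in% names(df)))
    stop("annotation in ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

#' Write / read a module catalog
#'
#' Format: `module_id<TAB>KO1 KO2 ...` (space-separated member list).
#'
#' @param modules named list module id -> KO character vector.
#' @param path TSV path.
#' @name module_io
#' @export
write_module_catalog <- function(modules, path) {
  lines <- vapply(names(modules), function(m)
    paste0(m, "\t", paste(modules[[m]], collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname module_io
#' @export
read_module_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed module catalog in ", path, " at line ", bad[1],
         call. = FALSE)
  stats::setNames(lapply(parts, function(p) strsplit(p[2], " +")[[1]]),
                  vapply(parts, `[[`, "", 1L))
}

#' Write / read a phenotype table with a type sidecar
#'
#' The sidecar `<path>.types` declares each covariate as continuous or
#' categorical.
#'
#' @param phenotypes data frame with a `types` attribute (see
#'   [sample_phenotypes()]).
#' @param path TSV path.
#' @name phenotype_io
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(sample_id = rownames(phenotypes), phenotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  types <- attr(phenotypes, "types")
  utils::write.table(
    data.frame(covariate = names(types), type = unname(types)),
    paste0(path, ".types"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname phenotype_io
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  tp <- paste0(path, ".types")
  if (file.exists(tp)) {
    td <- utils::read.delim(tp, stringsAsFactors = FALSE)
    attr(df, "types") <- stats::setNames(td$type, td$covariate)
  }
  df
}

#' Write / read a square distance matrix
#'
#' @param D symmetric distance matrix.
#' @param path TSV path.
#' @name distance_io
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname distance_io
#' @export
read_distance_matrix <- function(path) {
  m <- read_count_table(path)  # same layout checks
  t(m)
}

#' Write an edge list for network viewers
#'
#' @param edges data frame from [significant_edges()].
#' @param path TSV path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ground truth emitted by the synthetic generator
#'
#' Labels as TSV plus a machine-readable JSON summary of the planted
#' structure.
#'
#' @param truth a `ground_truth`.
#' @param dir output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  utils::write.table(
    data.frame(sample_id = sprintf("s%03d", seq_along(truth$labels)),
               component = truth$labels),
    file.path(dir, "truth_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  summ <- list(weights = truth$weights,
               alpha_rowsums = rowSums(truth$alpha),
               planted_edges = truth$planted_edges,
               enriched_modules = truth$enriched_modules)
  jsonlite::write_json(summ, file.path(dir, "truth_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
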