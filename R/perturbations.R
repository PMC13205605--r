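#' Perturbation profile library
#'
#' A genes x instances matrix of differential-expression ranking statistics
#' (LINCS-style moderated z-scores) plus per-instance metadata. This is the
#' search space of the D-FR20 connectivity screen.
#'
#' @param stat_matrix Numeric matrix, genes as rows, instances as columns; no
#'   missing values.
#' @param metadata Data frame with at least `instance_id` and `compound_name`
#'   (optional `mode_of_action`); exactly one row per instance column.
#' @param gene_ids,instance_ids Optional overrides for dimnames.
#' @return An object of class `perturb_library`.
#' @export
perturbation_library <- function(stat_matrix, metadata,
                                 gene_ids = rownames(stat_matrix),
                                 instance_ids = colnames(stat_matrix)) {
  stat_matrix <- as.matrix(stat_matrix)
  storage.mode(stat_matrix) <- "double"
  gene_ids <- toupper(as.character(gene_ids))
  instance_ids <- as.character(instance_ids)
  if (length(gene_ids) != nrow(stat_matrix) ||
      length(instance_ids) != ncol(stat_matrix)) {
    abort("gene/instance id lengths do not match the matrix.")
  }
  if (anyDuplicated(gene_ids)) abort("Duplicate gene symbols in library.")
  if (anyDuplicated(instance_ids)) abort("Duplicate instance identifiers.")
  if (anyNA(stat_matrix)) {
    idx <- which(is.na(stat_matrix), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing statistic for gene %s, instance %s.",
                  gene_ids[idx[1]], instance_ids[idx[2]]))
  }
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("instance_id", "compound_name") %in% names(metadata))) {
    abort("Metadata needs columns `instance_id` and `compound_name`.")
  }
  missing_meta <- setdiff(instance_ids, metadata$instance_id)
  if (length(missing_meta) > 0) {
    abort(paste0("Instances missing from metadata: ",
                 paste(head(missing_meta, 10), collapse = ", ")))
  }
  if (anyDuplicated(metadata$instance_id)) {
    abort("Metadata has duplicated instance rows.")
  }
  metadata <- metadata[match(instance_ids, metadata$instance_id), ]
  dimnames(stat_matrix) <- list(gene_ids, instance_ids)
  structure(
    list(stat_matrix = stat_matrix, gene_ids = gene_ids,
         instance_ids = instance_ids, metadata = metadata),
    class = "perturb_library"
  )
}

#' @export
print.perturb_library <- function(x, ...) {
  cat(sprintf("<perturb_library> %d genes x %d instances\n",
              length(x$gene_ids), length(x$instance_ids)))
  invisible(x)
}

#' Read a perturbation library from disk
#'
#' The statistic matrix is a TSV (first column `gene`, instance ids in the
#' header) or a parquet file with the same layout; metadata is a TSV with
#' `instance_id`, `compound_name` and optionally `mode_of_action`.
#'
#' @param matrix_path Path to the statistic matrix (`.tsv` or `.parquet`).
#' @param metadata_path Path to the instance metadata TSV.
#' @return A [perturbation_library()].
#' @export
read_perturbations <- function(matrix_path, metadata_path) {
  for (f in c(matrix_path, metadata_path)) {
    if (!file.exists(f)) abort(sprintf("File not found: %s", f))
  }
  if (grepl("\\.parquet$", matrix_path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Reading parquet requires the `arrow` package.")
    }
    tab <- tibble::as_tibble(arrow::read_parquet(matrix_path))
  } else {
    tab <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                             data.table = FALSE)
  }
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  if (nrow(meta) != ncol(m)) {
    abort(sprintf("Metadata has %d rows for %d instance columns.",
                  nrow(meta), ncol(m)))
  }
  perturbation_library(m, meta, gene_ids = genes, instance_ids = colnames(m))
}

#' Write a perturbation library
#'
#' @param x A [perturbation_library()].
#' @param matrix_path Output path (`.tsv` or `.parquet`).
#' @param metadata_path Output metadata TSV path.
#' @return `matrix_path`, invisibly.
#' @export
write_perturbations <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "perturb_library"))
  tab <- tibble::as_tibble(cbind(
    tibble::tibble(gene = x$gene_ids),
    as.data.frame(x$stat_matrix)
  ))
  if (grepl("\\.parquet$", matrix_path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Writing parquet requires the `arrow` package.")
    }
    arrow::write_parquet(tab, matrix_path)
  } else {
    readr::write_tsv(tab, matrix_path)
  }
  readr::write_tsv(x$metadata, metadata_path)
  invisible(matrix_path)
}

#' Read a drug-response table
#'
#' @param path TSV with columns `sample_id` and `response_value` (AUC- or
#'   IC50-like scalars; higher AUC = less sensitive).
#' @return A tibble with unique `sample_id` and finite `response_value`.
#' @export
read_response <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "response_value") %in% names(tab))) {
    abort("Response table needs columns `sample_id` and `response_value`.")
  }
  if (anyDuplicated(tab$sample_id)) abort("Duplicate sample ids in response table.")
  if (any(!is.finite(tab$response_value))) abort("Non-finite response values.")
  tibble::as_tibble(tab)
}
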