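#' Expression matrix container
#'
#' A light S3 wrapper around a genes x observations numeric matrix carrying
#' the per-observation condition labels and a layer flag recording what the
#' values are (raw UMI counts, log-normalized expression, or per-gene
#' z-scores). All pipeline stages consume and return this container.
#'
#' @param values Numeric matrix, genes as rows, observations (cells or
#'   samples) as columns. Row and column names, if present, are overridden by
#'   `gene_ids` / `obs_ids`.
#' @param gene_ids Character vector of unique gene symbols (one per row).
#'   Symbols are upper-cased so catalog matching is case-insensitive.
#' @param obs_ids Character vector of unique observation identifiers (one per
#'   column).
#' @param condition Per-observation condition labels (e.g. "sensitive" /
#'   "resistant"); recycled from length 1. Defaults to a single group.
#' @param layer One of `"raw_counts"`, `"log_normalized"`, `"zscore"`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              obs_ids = colnames(values),
                              condition = NULL,
                              layer = c("raw_counts", "log_normalized", "zscore")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(obs_ids)) {
    abort("`gene_ids` and `obs_ids` are required (or set dimnames on `values`).")
  }
  gene_ids <- toupper(as.character(gene_ids))
  obs_ids <- as.character(obs_ids)
  if (length(gene_ids) != nrow(values)) {
    abort(sprintf("%d gene ids for %d rows.", length(gene_ids), nrow(values)))
  }
  if (length(obs_ids) != ncol(values)) {
    abort(sprintf("%d observation ids for %d columns.", length(obs_ids), ncol(values)))
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene symbols: ", paste(head(dup, 10), collapse = ", ")))
  }
  if (anyDuplicated(obs_ids)) {
    abort("Duplicate observation identifiers.")
  }
  if (is.null(condition)) condition <- "group1"
  condition <- as.character(condition)
  if (length(condition) == 1) condition <- rep(condition, ncol(values))
  if (length(condition) != ncol(values)) {
    abort("`condition` must have one label per observation.")
  }
  if (anyNA(values)) abort("Expression values contain missing entries.")
  if (layer == "raw_counts") {
    if (any(values < 0) || any(values != floor(values))) {
      abort("layer = \"raw_counts\" requires non-negative integer values.")
    }
  }
  dimnames(values) <- list(gene_ids, obs_ids)
  structure(
    list(values = values, gene_ids = gene_ids, obs_ids = obs_ids,
         condition = condition, layer = layer),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d observations [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  tab <- table(x$condition)
  cat("conditions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix
#'
#' Reads either a Matrix Market triplet directory (`matrix.mtx` +
#' `genes.tsv`/`features.tsv` + `barcodes.tsv`, the 10x-style layout) or a
#' dense TSV with genes as rows, a `gene` first column and observation ids in
#' the header. Condition labels come from `conditions`, from a
#' `conditions.tsv` sidecar (columns `obs_id`, `condition`) next to the input,
#' or default to a single group.
#'
#' @param path Directory (for `mtx_dir`) or TSV file (for `dense_tsv`).
#' @param format `"mtx_dir"` or `"dense_tsv"`.
#' @param layer Layer flag to stamp on the result (see
#'   [expression_matrix()]).
#' @param conditions Optional: a character vector (one label per observation,
#'   in column order) or a data frame with columns `obs_id` and `condition`.
#' @param transpose For `dense_tsv` files written observations-as-rows.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path,
                            format = c("mtx_dir", "dense_tsv"),
                            layer = c("raw_counts", "log_normalized", "zscore"),
                            conditions = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(path)) abort(sprintf("Input path not found: %s", path))
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    if (!file.exists(genes)) genes <- file.path(path, "features.tsv")
    barcodes <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, barcodes)) {
      if (!file.exists(f)) {
        abort(sprintf("MTX directory is missing companion file: %s", basename(f)))
      }
    }
    m <- as.matrix(Matrix::readMM(mtx))
    gene_ids <- readr::read_tsv(genes, col_names = FALSE,
                                show_col_types = FALSE)[[1]]
    obs_ids <- readr::read_tsv(barcodes, col_names = FALSE,
                               show_col_types = FALSE)[[1]]
    sidecar <- file.path(path, "conditions.tsv")
  } else {
    # fread: correctly rounded double parsing, so TSV round trips bit-for-bit
    tab <- data.table::fread(path, sep = "\t", header = TRUE,
                             data.table = FALSE)
    gene_ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    obs_ids <- colnames(m)
    if (transpose) {
      m <- t(m)
      tmp <- gene_ids; gene_ids <- obs_ids; obs_ids <- tmp
    }
    sidecar <- file.path(dirname(path),
                         paste0(sub("\\.[^.]+$", "", basename(path)), ".conditions.tsv"))
  }
  if (is.null(conditions) && file.exists(sidecar)) {
    conditions <- readr::read_tsv(sidecar, show_col_types = FALSE)
  }
  if (is.data.frame(conditions)) {
    if (!all(c("obs_id", "condition") %in% names(conditions))) {
      abort("Condition table needs columns `obs_id` and `condition`.")
    }
    idx <- match(obs_ids, conditions$obs_id)
    if (anyNA(idx)) abort("Condition table does not cover every observation.")
    conditions <- conditions$condition[idx]
  }
  expression_matrix(m, gene_ids = gene_ids, obs_ids = obs_ids,
                    condition = conditions, layer = layer)
}

#' Write an expression matrix
#'
#' `dense_tsv` writes the values with the shortest decimal representation
#' that restores each double bit-for-bit, so a write/read round trip is
#' value-identical; a `<stem>.conditions.tsv` sidecar carries the labels.
#' `mtx_dir` writes the Matrix Market triplet layout.
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV path (`dense_tsv`) or directory (`mtx_dir`).
#' @param format `"dense_tsv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("dense_tsv", "mtx_dir")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  if (format == "dense_tsv") {
    tab <- as.data.frame(x$values)
    out <- tibble::as_tibble(cbind(gene = x$gene_ids, tab))
    readr::write_tsv(out, path)
    side <- file.path(dirname(path),
                      paste0(sub("\\.[^.]+$", "", basename(path)), ".conditions.tsv"))
    readr::write_tsv(tibble::tibble(obs_id = x$obs_ids, condition = x$condition), side)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble::tibble(g = x$gene_ids), file.path(path, "genes.tsv"),
                     col_names = FALSE)
    readr::write_tsv(tibble::tibble(b = x$obs_ids), file.path(path, "barcodes.tsv"),
                     col_names = FALSE)
    readr::write_tsv(tibble::tibble(obs_id = x$obs_ids, condition = x$condition),
                     file.path(path, "conditions.tsv"))
  }
  invisible(path)
}
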