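#' Quality-control thresholds
#'
#' Defaults follow the standard droplet scRNA-seq screen used to derive the
#' resistance signature: drop cells covering fewer than 200 genes or with more
#' than 20% of UMIs from mitochondrial genes, then drop genes expressed in
#' fewer than 3 surviving cells.
#'
#' @param min_cells_per_gene Genes expressed (count > 0) in fewer surviving
#'   cells than this are removed.
#' @param min_genes_per_cell Cells covering fewer genes are removed.
#' @param max_mito_fraction Cells with a higher fraction of counts on
#'   mitochondrial genes are removed.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3L,
                          min_genes_per_cell = 200L,
                          max_mito_fraction = 0.20,
                          mito_prefix = "MT-") {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter low-quality cells and sparsely expressed genes
#'
#' Two fixed passes: cells failing either cell rule are removed first, then
#' genes expressed in fewer than `min_cells_per_gene` of the *surviving*
#' cells are removed.
#'
#' @param matrix An [expression_matrix()] with `layer = "raw_counts"`.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered counts matrix; the numbers removed at each stage are
#'   attached as attribute `qc_log`.
#' @export
qc_filter <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(thresholds, "qc_thresholds"))
  if (matrix$layer != "raw_counts") {
    abort("qc_filter() expects raw counts.")
  }
  v <- matrix$values
  genes_per_cell <- colSums(v > 0)
  mito <- startsWith(matrix$gene_ids, toupper(thresholds$mito_prefix))
  total <- colSums(v)
  mito_frac <- ifelse(total > 0, colSums(v[mito, , drop = FALSE]) / total, 0)
  keep_cells <- genes_per_cell >= thresholds$min_genes_per_cell &
    mito_frac <= thresholds$max_mito_fraction
  if (!any(keep_cells)) {
    abort(sprintf("All %d cells removed by QC (min %d genes/cell, max %.0f%% mito).",
                  ncol(v), thresholds$min_genes_per_cell,
                  100 * thresholds$max_mito_fraction))
  }
  v2 <- v[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(v2 > 0) >= thresholds$min_cells_per_gene
  if (!any(keep_genes)) {
    abort(sprintf("All %d genes removed by QC (min %d cells/gene after cell filter).",
                  nrow(v), thresholds$min_cells_per_gene))
  }
  out <- expression_matrix(v2[keep_genes, , drop = FALSE],
                           gene_ids = matrix$gene_ids[keep_genes],
                           obs_ids = matrix$obs_ids[keep_cells],
                           condition = matrix$condition[keep_cells],
                           layer = "raw_counts")
  attr(out, "qc_log") <- list(
    cells_removed = sum(!keep_cells),
    genes_removed = sum(!keep_genes),
    cells_kept = sum(keep_cells),
    genes_kept = sum(keep_genes)
  )
  out
}

#' Library-size normalization
#'
#' The standard log-normalization: each count is divided by its cell's total,
#' multiplied by `scale_factor`, and log-transformed —
#' `value = ln(1 + scale_factor * count / colsum)`.
#'
#' @param matrix An [expression_matrix()] with raw counts.
#' @param scale_factor Positive scalar, default `1e4`.
#' @return An [expression_matrix()] with `layer = "log_normalized"`.
#' @export
normalize_counts <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "expr_matrix"), scale_factor > 0)
  if (matrix$layer != "raw_counts") abort("normalize_counts() expects raw counts.")
  cs <- colSums(matrix$values)
  if (any(cs == 0)) {
    abort(paste0("Zero total counts for observation(s): ",
                 paste(head(matrix$obs_ids[cs == 0], 5), collapse = ", ")))
  }
  v <- log1p(sweep(matrix$values, 2, scale_factor / cs, `*`))
  expression_matrix(v, gene_ids = matrix$gene_ids, obs_ids = matrix$obs_ids,
                    condition = matrix$condition, layer = "log_normalized")
}

#' Per-gene z-scoring across observations
#'
#' Standardizes each gene across observations using the sample standard
#' deviation (n - 1). Zero-variance genes are set to all zeros with a note.
#' This is the default FR20 input layer for bulk cohorts, where platform
#' scales differ between genes.
#'
#' @param matrix An [expression_matrix()] with at least 2 observations.
#' @return An [expression_matrix()] with `layer = "zscore"`.
#' @export
zscore_genes <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (ncol(v) < 2) abort("z-scoring needs at least 2 observations.")
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  flat <- s == 0
  if (any(flat)) {
    inform(sprintf("%d zero-variance gene(s) set to all-zero z-scores.", sum(flat)))
    s[flat] <- 1
  }
  z <- (v - mu) / s
  z[flat, ] <- 0
  expression_matrix(z, gene_ids = matrix$gene_ids, obs_ids = matrix$obs_ids,
                    condition = matrix$condition, layer = "zscore")
}
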