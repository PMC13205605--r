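#' Per-gene differential expression between two conditions
#'
#' For each gene expressed in at least `min_pct` of cells in either group, a
#' two-sided Wilcoxon rank-sum test on log-normalized values (exact
#' enumeration when both groups have <= 25 tie-free observations, normal
#' approximation with tie correction otherwise), the Seurat-style
#' pseudocount fold change
#' `log2((mean_a + 1) / (mean_b + 1))` on de-logged normalized expression,
#' and Benjamini-Hochberg FDR across all tested genes. Direction is `up`
#' when `log2_fc > lfc_threshold` and `fdr < fdr_threshold`, `down` for the
#' mirror case, `ns` otherwise.
#'
#' @param matrix An [expression_matrix()] with `layer = "log_normalized"`.
#' @param group_a,group_b Condition labels; fold changes are `group_a` vs
#'   `group_b` (the group of interest first, e.g. resistant vs sensitive).
#' @param lfc_threshold Absolute log2 fold-change cut for calling direction
#'   (default 0.25).
#' @param fdr_threshold FDR cut for calling direction (default 0.01).
#' @param min_pct Minimum fraction of cells expressing the gene in at least
#'   one group for the gene to be tested (default 0.1).
#' @return A tibble of class `fr20_de` with columns `gene`, `log2_fc`,
#'   `p_value`, `fdr`, `pct_in_a`, `pct_in_b`, `direction`; thresholds and
#'   group labels attached as attribute `params`.
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    lfc_threshold = 0.25,
                                    fdr_threshold = 0.01,
                                    min_pct = 0.1) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "log_normalized") {
    abort("differential_expression() expects log-normalized values.")
  }
  for (g in c(group_a, group_b)) {
    if (!g %in% matrix$condition) abort(sprintf("Unknown condition label: %s", g))
  }
  ia <- matrix$condition == group_a
  ib <- matrix$condition == group_b
  if (sum(ia) < 3 || sum(ib) < 3) abort("Each group needs >= 3 observations.")
  va <- matrix$values[, ia, drop = FALSE]
  vb <- matrix$values[, ib, drop = FALSE]
  pct_a <- rowMeans(va > 0)
  pct_b <- rowMeans(vb > 0)
  tested <- pct_a >= min_pct | pct_b >= min_pct
  if (!any(tested)) abort("No genes pass the min_pct expression filter.")
  genes <- matrix$gene_ids[tested]
  va <- va[tested, , drop = FALSE]
  vb <- vb[tested, , drop = FALSE]
  exact <- ncol(va) <= 25 && ncol(vb) <= 25
  pvals <- vapply(seq_along(genes), function(i) {
    x <- va[i, ]; y <- vb[i, ]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = !exact)$p.value
    )
  }, numeric(1))
  mean_a <- rowMeans(expm1(va))
  mean_b <- rowMeans(expm1(vb))
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  fdr <- p.adjust(pvals, method = "BH")
  direction <- dplyr::case_when(
    lfc > lfc_threshold & fdr < fdr_threshold ~ "up",
    lfc < -lfc_threshold & fdr < fdr_threshold ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::tibble(
    gene = genes,
    log2_fc = unname(lfc),
    p_value = unname(pvals),
    fdr = unname(fdr),
    pct_in_a = unname(pct_a[tested]),
    pct_in_b = unname(pct_b[tested]),
    direction = factor(direction, levels = c("up", "down", "ns"))
  )
  structure(out, class = c("fr20_de", class(out)),
            params = list(group_a = group_a, group_b = group_b,
                          lfc_threshold = lfc_threshold,
                          fdr_threshold = fdr_threshold, min_pct = min_pct))
}

#' Write a differential-expression table
#'
#' Fixed column order: gene, log2_fc, p_value, fdr, pct_in_a, pct_in_b,
#' direction.
#'
#' @param diff A `fr20_de` tibble.
#' @param path Output TSV path.
#' @export
write_de <- function(diff, path) {
  cols <- c("gene", "log2_fc", "p_value", "fdr", "pct_in_a", "pct_in_b", "direction")
  readr::write_tsv(tibble::as_tibble(diff)[, cols], path)
  invisible(path)
}

#' Direction-by-role enrichment test
#'
#' One-sided Fisher exact test (enrichment alternative) asking whether genes
#' called in a given direction are over-represented among catalog genes of a
#' given role, over the universe of genes tested in the DE step. The odds
#' ratio is the sample cross-product ratio, with a 0.5 continuity correction
#' only when a cell is zero (flagged).
#'
#' @param diff A `fr20_de` tibble.
#' @param catalog A [regulator_catalog()].
#' @param direction `"up"` or `"down"`.
#' @param role `"suppressor"` or `"driver"`.
#' @return A one-row tibble of class `fr20_enrichment`: `direction`, `role`,
#'   `odds_ratio`, `p_value`, the four contingency cells, and
#'   `continuity_corrected`; the universe definition is attached as attribute
#'   `universe`.
#' @export
fisher_direction_enrichment <- function(diff, catalog,
                                        direction = c("up", "down"),
                                        role = c("suppressor", "driver")) {
  direction <- match.arg(direction)
  role <- match.arg(role)
  stopifnot(nrow(diff) > 0)
  universe <- diff$gene
  in_role <- universe %in% catalog$gene[catalog$role == role]
  if (!any(universe %in% catalog$gene)) {
    abort("No catalog genes in the tested universe.")
  }
  in_dir <- diff$direction == direction
  a <- sum(in_dir & in_role)
  b <- sum(in_dir & !in_role)
  c_ <- sum(!in_dir & in_role)
  d <- sum(!in_dir & !in_role)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  cc <- any(tab == 0)
  or <- if (cc) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else (a * d) / (b * c_)
  out <- tibble::tibble(
    direction = direction, role = role,
    odds_ratio = or, p_value = p,
    n_dir_role = a, n_dir_other = b, n_ns_role = c_, n_ns_other = d,
    continuity_corrected = cc
  )
  structure(out, class = c("fr20_enrichment", class(out)),
            universe = "genes tested in the differential-expression step")
}
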