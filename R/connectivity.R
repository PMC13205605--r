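#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic preranked-GSEA running-sum statistic. Genes are sorted by
#' statistic descending (ties broken by gene symbol ascending so rankings are
#' reproducible); walking down the list the sum gains
#' `|stat|^p / sum_set(|stat|^p)` at member positions and loses `1 / (N - m)`
#' at non-member positions. The enrichment score is the running-sum value of
#' maximum absolute deviation from zero, signed. Positive scores mean the set
#' concentrates at the top of the ranking (induced genes), negative at the
#' bottom (repressed genes).
#'
#' @param stats Named numeric vector of per-gene ranking statistics (names
#'   are gene symbols; >= 2 genes).
#' @param gene_set Character vector of member genes, or a single-element
#'   named list. At least one member must match the profile, and the matched
#'   set must not cover every profile gene.
#' @param weight_exponent Weight exponent `p >= 0`; 1 is the classic weighted
#'   statistic, 0 the unweighted KS variant.
#' @return The enrichment score, a scalar in `[-1, 1]`, with the matched set
#'   size as attribute `set_size_used`.
#' @export
enrichment_score <- function(stats, gene_set, weight_exponent = 1) {
  ord <- rank_profile(stats)
  pos <- member_positions(ord, gene_set)
  es_from_positions(ord$stats, pos, weight_exponent)
}

# Sort a named profile by statistic descending, gene symbol ascending on ties.
rank_profile <- function(stats) {
  if (is.null(names(stats)) || anyNA(names(stats))) {
    abort("Profile statistics must be named by gene symbol.")
  }
  if (length(stats) < 2) abort("Profile needs >= 2 genes.")
  if (anyNA(stats)) abort("Profile statistics contain missing values.")
  nm <- toupper(names(stats))
  o <- order(-stats, nm, method = "radix")
  list(stats = unname(stats[o]), genes = nm[o])
}

member_positions <- function(ord, gene_set) {
  if (is.list(gene_set)) gene_set <- gene_set[[1]]
  gene_set <- unique(toupper(gene_set))
  pos <- which(ord$genes %in% gene_set)
  n <- length(ord$genes)
  if (length(pos) == 0) abort("Gene set does not intersect the profile.")
  if (length(pos) == n) abort("Gene set covers the whole profile; ES undefined.")
  pos
}

# O(m) enrichment score given sorted descending stats and sorted member
# positions: extrema of the running sum occur just after a hit step (top)
# or just before one (bottom).
es_from_positions <- function(sorted_stats, pos, weight_exponent = 1) {
  stopifnot(weight_exponent >= 0)
  n <- length(sorted_stats)
  m <- length(pos)
  w <- abs(sorted_stats[pos])^weight_exponent
  tot <- sum(w)
  # all-zero member stats with p > 0: fall back to equal weights
  if (tot == 0) { w <- rep(1, m); tot <- m }
  hit <- cumsum(w) / tot
  miss_step <- 1 / (n - m)
  j <- seq_len(m)
  top <- hit - (pos - j) * miss_step
  bottom <- c(0, hit[-m]) - (pos - j) * miss_step
  max_pos <- max(top)
  min_neg <- min(bottom)
  es <- if (max_pos >= -min_neg) max_pos else min_neg
  attr(es, "set_size_used") <- m
  es
}

#' Permutation-normalized enrichment score
#'
#' The null distribution comes from `n_perm` random gene sets of the matched
#' size drawn without replacement from the profile genes (the preranked-GSEA
#' gene-set permutation). `nes = es / mean(|null ES of the same sign|)` and
#' `p = (1 + #same-sign null |ES| >= |es|) / (1 + #same-sign null)`. When no
#' same-sign null ES exists, the fallback normalizes by `mean(|all null
#' ES|)` with `p = 1/(n_perm + 1)` and sets `degenerate_null = TRUE`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 10; default 1000).
#' @param seed Integer seed for the permutation draw (default 20).
#' @param gene_set_name Label carried into the result.
#' @return One-row tibble of class `fr20_gsea`: `gene_set_name`, `es`,
#'   `nes`, `p_value`, `set_size_used`, `n_null_same_sign` (size of the
#'   same-sign null used by the estimator, so `p_value`'s attainable floor is
#'   `1/(n_null_same_sign + 1)`), `degenerate_null`.
#' @export
normalized_enrichment <- function(stats, gene_set, n_perm = 1000,
                                  seed = fr20_default_seed,
                                  weight_exponent = 1,
                                  gene_set_name = "gene_set") {
  if (n_perm < 10) abort("n_perm must be >= 10.")
  ord <- rank_profile(stats)
  pos <- member_positions(ord, gene_set)
  es <- es_from_positions(ord$stats, pos, weight_exponent)
  m_used <- attr(es, "set_size_used")
  null_es <- withr::with_seed(seed, null_es_draw(ord$stats, length(pos),
                                                 n_perm, weight_exponent))
  res <- nes_from_null(as.numeric(es), null_es, n_perm)
  tibble::new_tibble(
    tibble::tibble(gene_set_name = gene_set_name, es = as.numeric(es),
                   nes = res$nes, p_value = res$p,
                   set_size_used = m_used,
                   n_null_same_sign = res$n_same,
                   degenerate_null = res$degenerate),
    class = "fr20_gsea"
  )
}

null_es_draw <- function(sorted_stats, m, n_perm, weight_exponent) {
  n <- length(sorted_stats)
  vapply(seq_len(n_perm), function(i) {
    p <- sort.int(sample.int(n, m))
    as.numeric(es_from_positions(sorted_stats, p, weight_exponent))
  }, numeric(1))
}

nes_from_null <- function(es, null_es, n_perm) {
  if (es == 0) {
    return(list(nes = 0, p = 1, n_same = NA_integer_, degenerate = FALSE))
  }
  same <- if (es > 0) null_es[null_es > 0] else null_es[null_es < 0]
  if (length(same) == 0) {
    denom <- mean(abs(null_es))
    if (denom == 0) denom <- 1
    return(list(nes = es / denom, p = 1 / (n_perm + 1), n_same = 0L,
                degenerate = TRUE))
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p = p, n_same = length(same), degenerate = FALSE)
}

#' Weighted connectivity score
#'
#' Combines the normalized enrichment of the up-suppressor arm and the
#' down-driver arm: `(nes_up - nes_down) / 2` when the two scores have
#' opposite signs, `0` otherwise (including when either is zero). A more
#' negative WTCS means a stronger predicted reversal of the resistance
#' signature.
#'
#' @param nes_up,nes_down Normalized enrichment scores of the two arms
#'   (vectorized).
#' @return The WTCS value(s).
#' @export
wtcs_combine <- function(nes_up, nes_down) {
  ifelse(sign(nes_up) != sign(nes_down) & nes_up != 0 & nes_down != 0,
         (nes_up - nes_down) / 2, 0)
}

#' D-FR20 connectivity screen
#'
#' For every instance in the library, computes ES/NES/p for the signature's
#' up-suppressor arm and down-driver arm against the instance's ranked
#' profile, adjusts p-values per arm across instances (Benjamini-Hochberg),
#' retains instances significant for both arms
#' (`fdr_up < fdr_threshold & fdr_down < fdr_threshold`), combines the two
#' NES into the WTCS, and ranks retained instances by ascending WTCS
#' (ties broken by instance id). The `top_k` retained instances are flagged
#' as re-sensitizer candidates.
#'
#' @param library A [perturbation_library()].
#' @param signature A [resistance_signature()].
#' @param n_perm Permutations per arm per instance (default 1000).
#' @param fdr_threshold BH-FDR retention cut per arm (default 0.05).
#' @param top_k Number of retained instances flagged as candidates
#'   (default 10).
#' @param seed Integer seed; each instance/arm draw is seeded independently
#'   from it so results do not depend on evaluation order.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return A tibble of class `fr20_connectivity`, one row per instance:
#'   `instance_id`, `compound_name`, `es_up`, `nes_up`, `p_up`, `fdr_up`,
#'   `es_down`, `nes_down`, `p_down`, `fdr_down`, `wtcs`, `retained`, `rank`
#'   (NA for unretained), `candidate`. Sorted by rank, then instance id.
#' @export
screen_library <- function(library, signature,
                           n_perm = 1000, fdr_threshold = 0.05, top_k = 10,
                           seed = fr20_default_seed, weight_exponent = 1) {
  stopifnot(inherits(library, "perturb_library"),
            inherits(signature, "fr20_signature"))
  up <- intersect(signature$up_suppressors, library$gene_ids)
  down <- intersect(signature$down_drivers, library$gene_ids)
  if (length(up) == 0 || length(down) == 0) {
    abort("Library genes must cover at least one gene of each signature arm.")
  }
  dropped <- setdiff(c(signature$up_suppressors, signature$down_drivers),
                     library$gene_ids)
  if (length(dropped) > 0) {
    warn(paste0("Signature gene(s) absent from the library: ",
                paste(dropped, collapse = ", ")))
  }
  ids <- library$instance_ids
  # independent sub-seed per instance x arm, derived from the master seed
  sub_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2 * length(ids)), ncol = 2))
  one_arm <- function(i, genes, arm) {
    stats <- setNames(library$stat_matrix[, i], library$gene_ids)
    normalized_enrichment(stats, genes, n_perm = n_perm,
                          seed = sub_seeds[i, arm],
                          weight_exponent = weight_exponent,
                          gene_set_name = c("up_suppressors", "down_drivers")[arm])
  }
  res_up <- purrr::map_dfr(seq_along(ids), one_arm, genes = up, arm = 1L)
  res_down <- purrr::map_dfr(seq_along(ids), one_arm, genes = down, arm = 2L)
  out <- tibble::tibble(
    instance_id = ids,
    compound_name = library$metadata$compound_name,
    es_up = res_up$es, nes_up = res_up$nes, p_up = res_up$p_value,
    fdr_up = p.adjust(res_up$p_value, method = "BH"),
    es_down = res_down$es, nes_down = res_down$nes, p_down = res_down$p_value,
    fdr_down = p.adjust(res_down$p_value, method = "BH")
  ) |>
    dplyr::mutate(
      wtcs = wtcs_combine(.data$nes_up, .data$nes_down),
      retained = .data$fdr_up < fdr_threshold & .data$fdr_down < fdr_threshold
    )
  if (!any(out$retained)) {
    warn("No instances retained at the FDR threshold; candidate list is empty.")
  }
  ret <- out |>
    dplyr::filter(.data$retained) |>
    dplyr::arrange(.data$wtcs, .data$instance_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  out <- out |>
    dplyr::left_join(ret[, c("instance_id", "rank")], by = "instance_id") |>
    dplyr::mutate(candidate = !is.na(.data$rank) & .data$rank <= top_k) |>
    dplyr::arrange(is.na(.data$rank), .data$rank, .data$instance_id)
  structure(out, class = c("fr20_connectivity", class(out)),
            params = list(n_perm = n_perm, fdr_threshold = fdr_threshold,
                          top_k = top_k, seed = seed,
                          weight_exponent = weight_exponent,
                          fdr_scope = "BH per signature arm across instances, AND-combined",
                          dropped_genes = dropped))
}

#' Write connectivity screen outputs
#'
#' `connectivity.tsv` holds every instance; `candidates.tsv` the flagged
#' top-k rows.
#'
#' @param result A `fr20_connectivity` tibble.
#' @param dir Output directory (created if needed).
#' @export
write_connectivity <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("instance_id", "compound_name", "es_up", "nes_up", "p_up", "fdr_up",
            "es_down", "nes_down", "p_down", "fdr_down", "wtcs", "retained", "rank")
  readr::write_tsv(tibble::as_tibble(result)[, cols],
                   file.path(dir, "connectivity.tsv"))
  readr::write_tsv(tibble::as_tibble(result)[result$candidate, cols],
                   file.path(dir, "candidates.tsv"))
  invisible(dir)
}
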