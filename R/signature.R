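#' Resistance signature
#'
#' The signed gene signature behind FR20: up-regulated ferroptosis
#' suppressors carry weight +1, down-regulated drivers carry weight -1, so a
#' high score means a ferroptosis-inhibited (resistance-like) expression
#' state.
#'
#' @param up_suppressors Character vector of suppressor genes (weight +1).
#' @param down_drivers Character vector of driver genes (weight -1).
#' @param provenance Free-text description of how the signature was derived.
#' @return An object of class `fr20_signature` with elements
#'   `up_suppressors`, `down_drivers`, `n`, `provenance`.
#' @export
resistance_signature <- function(up_suppressors, down_drivers,
                                 provenance = "user-supplied") {
  up_suppressors <- unique(toupper(as.character(up_suppressors)))
  down_drivers <- unique(toupper(as.character(down_drivers)))
  if (length(intersect(up_suppressors, down_drivers)) > 0) {
    abort("A gene cannot be in both signature arms.")
  }
  n <- length(up_suppressors) + length(down_drivers)
  if (n < 1) abort("Signature is empty.")
  structure(list(up_suppressors = up_suppressors, down_drivers = down_drivers,
                 n = n, provenance = provenance),
            class = "fr20_signature")
}

#' @export
print.fr20_signature <- function(x, ...) {
  cat(sprintf("<fr20_signature> n = %d (%d up suppressors, %d down drivers)\n",
              x$n, length(x$up_suppressors), length(x$down_drivers)))
  cat("up:  ", paste(x$up_suppressors, collapse = ", "), "\n")
  cat("down:", paste(x$down_drivers, collapse = ", "), "\n")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' The packaged 20-gene resistance signature
#'
#' Eight ferroptosis suppressors up-regulated and twelve drivers
#' down-regulated in JQ1-resistant TNBC cells; shipped so scoring works with
#' no derivation step.
#'
#' @return A [resistance_signature()] with n = 20.
#' @export
packaged_signature <- function() {
  resistance_signature(FR20_UP_SUPPRESSORS, FR20_DOWN_DRIVERS,
                       provenance = "packaged 20-gene JQ1-resistance signature")
}

#' Derive a resistance signature from DE results and a catalog
#'
#' Intersects direction calls with regulator roles: suppressors called `up`
#' enter the +1 arm, drivers called `down` enter the -1 arm. Genes are
#' ordered by ascending FDR within each arm.
#'
#' @param diff A `fr20_de` tibble (see [differential_expression()]).
#' @param catalog A [regulator_catalog()].
#' @return A [resistance_signature()].
#' @export
derive_signature <- function(diff, catalog) {
  stopifnot(inherits(diff, "fr20_de"), nrow(catalog) > 0)
  roles <- setNames(catalog$role, catalog$gene)
  tab <- tibble::as_tibble(diff) |>
    dplyr::mutate(role = unname(roles[.data$gene])) |>
    dplyr::filter(!is.na(.data$role)) |>
    dplyr::arrange(.data$fdr)
  up <- tab$gene[tab$direction == "up" & tab$role == "suppressor"]
  down <- tab$gene[tab$direction == "down" & tab$role == "driver"]
  if (length(up) + length(down) == 0) {
    abort(paste0("No up-regulated suppressors or down-regulated drivers at the ",
                 "current thresholds; consider reviewing lfc/fdr cuts."))
  }
  p <- attr(diff, "params")
  resistance_signature(
    up, down,
    provenance = sprintf(
      "derived: %s vs %s, |log2FC| > %g, FDR < %g, min_pct %g",
      p$group_a, p$group_b, p$lfc_threshold, p$fdr_threshold, p$min_pct)
  )
}

#' Write / read a signature as GMT
#'
#' Two records: `FR20_UP_SUPPRESSORS` and `FR20_DOWN_DRIVERS`.
#'
#' @param signature A [resistance_signature()].
#' @param path GMT file path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "fr20_signature"))
  write_gmt(list(FR20_UP_SUPPRESSORS = signature$up_suppressors,
                 FR20_DOWN_DRIVERS = signature$down_drivers),
            path, description = signature$provenance)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  sets <- read_gmt(path)
  need <- c("FR20_UP_SUPPRESSORS", "FR20_DOWN_DRIVERS")
  if (!all(need %in% names(sets))) {
    abort("Signature GMT needs records FR20_UP_SUPPRESSORS and FR20_DOWN_DRIVERS.")
  }
  resistance_signature(sets$FR20_UP_SUPPRESSORS, sets$FR20_DOWN_DRIVERS,
                       provenance = sprintf("read from %s", basename(path)))
}

#' FR20 resistance score per observation
#'
#' The signed sum of normalized expression over the signature genes:
#' `FR20_c = sum(Exp over up-suppressors) - sum(Exp over down-drivers)`.
#' Use log-normalized values for single-cell input and per-gene z-scores
#' (see [zscore_genes()]) for bulk cohorts.
#'
#' @param matrix An [expression_matrix()] with layer `log_normalized` or
#'   `zscore`.
#' @param signature A [resistance_signature()].
#' @param missing_policy What to do with signature genes absent from the
#'   matrix: `"drop_and_warn"` (default) drops them and records them in the
#'   `dropped_genes` attribute; `"error"` fails.
#' @return A tibble of class `fr20_scores` with columns `obs_id`, `fr20`,
#'   `condition`; attributes `dropped_genes` and `layer`.
#' @export
fr20_score <- function(matrix, signature = packaged_signature(),
                       missing_policy = c("drop_and_warn", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(matrix, "expr_matrix"), inherits(signature, "fr20_signature"))
  if (matrix$layer == "raw_counts") {
    abort("fr20_score() needs log-normalized or z-scored values, not raw counts.")
  }
  up <- intersect(signature$up_suppressors, matrix$gene_ids)
  down <- intersect(signature$down_drivers, matrix$gene_ids)
  missing <- setdiff(c(signature$up_suppressors, signature$down_drivers),
                     matrix$gene_ids)
  if (length(up) + length(down) == 0) {
    abort(paste0("No signature genes found in the matrix. Missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(missing) > 0) {
    if (missing_policy == "error") {
      abort(paste0("Signature genes absent from the matrix: ",
                   paste(missing, collapse = ", ")))
    }
    warn(paste0("Dropping ", length(missing), " signature gene(s) absent from ",
                "the matrix: ", paste(missing, collapse = ", ")))
  }
  score <- colSums(matrix$values[up, , drop = FALSE]) -
    colSums(matrix$values[down, , drop = FALSE])
  out <- tibble::tibble(obs_id = matrix$obs_ids, fr20 = unname(score),
                        condition = matrix$condition)
  structure(out, class = c("fr20_scores", class(out)),
            dropped_genes = missing, layer = matrix$layer,
            signature_n_used = length(up) + length(down))
}

#' Compare FR20 scores between condition groups
#'
#' @param scores A `fr20_scores` tibble (or any tibble with `fr20` and
#'   `condition` columns).
#' @param test `"wilcoxon"` (two-sided rank-sum, exactly 2 groups), `"t"`
#'   (two-tailed Welch t, exactly 2 groups), or `"anova"` (one-way, >= 2
#'   groups).
#' @return A list of class `fr20_comparison` with `test_name`, `statistic`,
#'   `p_value`, and a `group_summaries` tibble (label, n, mean, median).
#' @export
compare_scores <- function(scores, test = c("wilcoxon", "t", "anova")) {
  test <- match.arg(test)
  stopifnot(all(c("fr20", "condition") %in% names(scores)))
  groups <- split(scores$fr20, scores$condition)
  if (any(lengths(groups) < 2)) abort("Each group needs n >= 2.")
  k <- length(groups)
  if (test %in% c("wilcoxon", "t") && k != 2) {
    abort(sprintf("%s test needs exactly 2 groups, found %d.", test, k))
  }
  if (k < 2) abort("Need >= 2 groups.")
  if (test == "wilcoxon") {
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                       alternative = "two.sided"))
    stat <- unname(ht$statistic); name <- "wilcoxon_two_sided"
  } else if (test == "t") {
    ht <- t.test(groups[[1]], groups[[2]], alternative = "two.sided")
    stat <- unname(ht$statistic); name <- "t_two_tailed"
  } else {
    fit <- aov(fr20 ~ condition, data = scores)
    s <- summary(fit)[[1]]
    ht <- list(p.value = s[["Pr(>F)"]][1])
    stat <- s[["F value"]][1]; name <- "anova_one_way"
  }
  summaries <- scores |>
    tibble::as_tibble() |>
    dplyr::group_by(label = .data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$fr20),
                     median = median(.data$fr20), .groups = "drop")
  structure(list(test_name = name, statistic = stat, p_value = ht$p.value,
                 group_summaries = summaries),
            class = "fr20_comparison")
}

#' @export
print.fr20_comparison <- function(x, ...) {
  cat(sprintf("<fr20_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$group_summaries)
  invisible(x)
}

#' Quartile stratification against drug response
#'
#' Samples in the top quartile of FR20 (score >= 75th percentile, type-7
#' quantiles) form the high-FR20 group, the bottom quartile (score <= 25th
#' percentile) the low-FR20 group; their drug-response values (e.g. AUC) are
#' compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param scores A `fr20_scores` tibble.
#' @param response A response tibble with `sample_id`, `response_value`
#'   (see [read_response()]).
#' @return A `fr20_comparison` whose groups are `high_fr20` / `low_fr20`,
#'   with the group memberships attached as attribute `membership`.
#' @export
stratify_quartiles <- function(scores, response) {
  stopifnot(all(c("obs_id", "fr20") %in% names(scores)),
            all(c("sample_id", "response_value") %in% names(response)))
  merged <- dplyr::inner_join(tibble::as_tibble(scores), response,
                              by = c(obs_id = "sample_id"))
  if (nrow(merged) < 8) abort("Need >= 8 samples with both score and response.")
  q <- quantile(merged$fr20, c(0.25, 0.75), type = 7)
  if (q[1] == q[2]) {
    abort("Score quartiles coincide (ties or constant scores); cannot stratify.")
  }
  merged <- merged |>
    dplyr::mutate(group = dplyr::case_when(
      .data$fr20 >= q[2] ~ "high_fr20",
      .data$fr20 <= q[1] ~ "low_fr20",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$group))
  if (!all(c("high_fr20", "low_fr20") %in% merged$group)) {
    abort("A quartile group is empty after boundary assignment.")
  }
  cmp <- compare_scores(
    tibble::tibble(fr20 = merged$response_value, condition = merged$group),
    test = "wilcoxon"
  )
  cmp$group_summaries <- merged |>
    dplyr::group_by(label = .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$response_value),
                     median = median(.data$response_value), .groups = "drop")
  attr(cmp, "membership") <- merged[, c("obs_id", "fr20", "response_value", "group")]
  cmp
}
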