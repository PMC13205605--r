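#' Tidy and glance methods
#'
#' `tidy()` returns a one-row-per-term tibble, `glance()` a one-row summary,
#' following the broom conventions.
#'
#' @param x A `fr20_comparison`, `fr20_signature`, or `fr20_connectivity`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name fr20-tidiers
NULL

#' @rdname fr20-tidiers
#' @export
tidy.fr20_comparison <- function(x, ...) {
  x$group_summaries
}

#' @rdname fr20-tidiers
#' @export
glance.fr20_comparison <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, n_groups = nrow(x$group_summaries),
                 n_obs = sum(x$group_summaries$n))
}

#' @rdname fr20-tidiers
#' @export
tidy.fr20_signature <- function(x, ...) {
  tibble::tibble(
    gene = c(x$up_suppressors, x$down_drivers),
    role = c(rep("suppressor", length(x$up_suppressors)),
             rep("driver", length(x$down_drivers))),
    weight = c(rep(1, length(x$up_suppressors)),
               rep(-1, length(x$down_drivers)))
  )
}

#' @rdname fr20-tidiers
#' @export
glance.fr20_signature <- function(x, ...) {
  tibble::tibble(n = x$n, n_up_suppressors = length(x$up_suppressors),
                 n_down_drivers = length(x$down_drivers),
                 provenance = x$provenance)
}

#' @rdname fr20-tidiers
#' @export
glance.fr20_connectivity <- function(x, ...) {
  tibble::tibble(n_instances = nrow(x), n_retained = sum(x$retained),
                 n_candidates = sum(x$candidate),
                 min_wtcs = min(x$wtcs), max_wtcs = max(x$wtcs))
}

#' Plot FR20 scores by condition
#'
#' @param object A `fr20_scores` tibble.
#' @param ... Unused.
#' @return A ggplot: boxplots of FR20 per condition with jittered points.
#' @export
autoplot.fr20_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$condition, y = .data$fr20,
                                       fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "FR20 score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a connectivity screen as a ranked WTCS profile
#'
#' @param object A `fr20_connectivity` tibble.
#' @param ... Unused.
#' @return A ggplot: retained instances ordered by WTCS, candidates
#'   highlighted.
#' @export
autoplot.fr20_connectivity <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$retained)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$wtcs,
                                    colour = .data$candidate)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027", `FALSE` = "grey50"),
                                 name = "candidate") +
    ggplot2::labs(x = "rank (ascending WTCS)", y = "WTCS") +
    ggplot2::theme_minimal()
}

#' Plot the enrichment running sum for one profile and gene set
#'
#' @param stats Named per-gene statistic vector (see [enrichment_score()]).
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Weight exponent (default 1).
#' @return A ggplot of the running-sum walk with member positions marked.
#' @export
plot_enrichment <- function(stats, gene_set, weight_exponent = 1) {
  ord <- rank_profile(stats)
  pos <- member_positions(ord, gene_set)
  n <- length(ord$stats)
  m <- length(pos)
  w <- abs(ord$stats)^weight_exponent
  step <- rep(-1 / (n - m), n)
  tot <- sum(w[pos])
  step[pos] <- if (tot == 0) 1 / m else w[pos] / tot
  walk <- tibble::tibble(position = seq_len(n), running_sum = cumsum(step),
                         member = seq_len(n) %in% pos)
  ggplot2::ggplot(walk, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_rug(data = dplyr::filter(walk, .data$member), sides = "b",
                      colour = "#d73027", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "rank position", y = "running enrichment sum") +
    ggplot2::theme_minimal()
}
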