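#' Parameters for the two-condition scRNA-seq count simulator
#'
#' The generator emulates a sensitive-vs-resistant droplet scRNA-seq design:
#' negative-binomial UMI counts with log-normal baseline means and library
#' sizes, a planted dysregulation pattern on the 20 packaged signature genes
#' (+1 log2 fold change on the 8 suppressors, -1 on the 12 drivers in the
#' resistant condition), decoy catalog regulators with no effect, and a slab
#' of background differentially expressed genes outside the catalog.
#'
#' @param n_genes Total genes (must cover signature + decoys + background).
#' @param n_cells_per_condition Cells per condition (default 500).
#' @param baseline_log_mean_mu,baseline_log_mean_sigma Natural-log mean and
#'   sd of per-gene baseline expression means.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_log_sigma Log-sd of per-cell library size factors.
#' @param planted_suppressor_lfc,planted_driver_lfc Planted log2 fold changes
#'   (resistant vs sensitive) on the signature suppressors / drivers.
#' @param n_background_de Non-catalog genes given a background fold change.
#' @param background_lfc_magnitude Magnitude of background log2 fold changes
#'   (signs alternate by seeded draw).
#' @param n_decoy_regulators Catalog decoys with zero fold change (split
#'   evenly driver/suppressor).
#' @param seed Integer seed.
#' @return A list of class `sc_sim_params`.
#' @export
sc_sim_params <- function(n_genes = 2000,
                          n_cells_per_condition = 500,
                          baseline_log_mean_mu = 0.5,
                          baseline_log_mean_sigma = 1.0,
                          nb_dispersion = 0.3,
                          libsize_log_sigma = 0.3,
                          planted_suppressor_lfc = 1.0,
                          planted_driver_lfc = -1.0,
                          n_background_de = 100,
                          background_lfc_magnitude = 1.0,
                          n_decoy_regulators = 50,
                          seed = fr20_default_seed) {
  p <- list(n_genes = as.integer(n_genes),
            n_cells_per_condition = as.integer(n_cells_per_condition),
            baseline_log_mean_mu = baseline_log_mean_mu,
            baseline_log_mean_sigma = baseline_log_mean_sigma,
            nb_dispersion = nb_dispersion,
            libsize_log_sigma = libsize_log_sigma,
            planted_suppressor_lfc = planted_suppressor_lfc,
            planted_driver_lfc = planted_driver_lfc,
            n_background_de = as.integer(n_background_de),
            background_lfc_magnitude = background_lfc_magnitude,
            n_decoy_regulators = as.integer(n_decoy_regulators),
            seed = as.integer(seed))
  stopifnot(p$nb_dispersion > 0, p$libsize_log_sigma > 0,
            p$n_cells_per_condition >= 1)
  n_sig <- length(FR20_UP_SUPPRESSORS) + length(FR20_DOWN_DRIVERS)
  if (p$n_genes < n_sig + p$n_decoy_regulators + p$n_background_de) {
    abort(sprintf("n_genes = %d cannot hold %d signature + %d decoy + %d background genes.",
                  p$n_genes, n_sig, p$n_decoy_regulators, p$n_background_de))
  }
  structure(p, class = "sc_sim_params")
}

#' Simulate two-condition scRNA-seq counts with a planted signature
#'
#' @param params A [sc_sim_params()].
#' @return A list with `matrix` (an [expression_matrix()] of raw counts,
#'   conditions `sensitive` / `resistant`), `ground_truth` (tibble: `gene`,
#'   `role`, `lfc`, `planted`), and `catalog` (the matching
#'   [regulator_catalog()] of signature + decoy genes).
#' @export
simulate_sc <- function(params = sc_sim_params()) {
  stopifnot(inherits(params, "sc_sim_params"))
  p <- params
  n_drv_decoy <- p$n_decoy_regulators %/% 2
  n_sup_decoy <- p$n_decoy_regulators - n_drv_decoy
  decoy_drv <- decoy_gene_names("driver", n_drv_decoy)
  decoy_sup <- decoy_gene_names("suppressor", n_sup_decoy)
  n_sig <- length(FR20_UP_SUPPRESSORS) + length(FR20_DOWN_DRIVERS)
  n_other <- p$n_genes - n_sig - p$n_decoy_regulators
  other <- sprintf("GENE%04d", seq_len(n_other))
  genes <- c(FR20_UP_SUPPRESSORS, FR20_DOWN_DRIVERS, decoy_drv, decoy_sup, other)
  role <- c(rep("suppressor", length(FR20_UP_SUPPRESSORS)),
            rep("driver", length(FR20_DOWN_DRIVERS)),
            rep("driver", n_drv_decoy), rep("suppressor", n_sup_decoy),
            rep(NA_character_, n_other))
  out <- withr::with_seed(p$seed, {
    lfc <- rep(0, p$n_genes)
    lfc[seq_along(FR20_UP_SUPPRESSORS)] <- p$planted_suppressor_lfc
    lfc[length(FR20_UP_SUPPRESSORS) + seq_along(FR20_DOWN_DRIVERS)] <-
      p$planted_driver_lfc
    bg_idx <- n_sig + p$n_decoy_regulators + seq_len(p$n_background_de)
    lfc[bg_idx] <- sample(c(-1, 1), p$n_background_de, replace = TRUE) *
      p$background_lfc_magnitude
    baseline <- exp(rnorm(p$n_genes, p$baseline_log_mean_mu,
                          p$baseline_log_mean_sigma))
    n_cells <- 2L * p$n_cells_per_condition
    condition <- rep(c("sensitive", "resistant"), each = p$n_cells_per_condition)
    libsize <- exp(rnorm(n_cells, 0, p$libsize_log_sigma))
    mu <- outer(baseline, libsize) *
      2^(outer(lfc, as.numeric(condition == "resistant")))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion),
                     nrow = p$n_genes)
    list(counts = counts, condition = condition, lfc = lfc)
  })
  mat <- expression_matrix(out$counts, gene_ids = genes,
                           obs_ids = sprintf("cell%04d", seq_len(ncol(out$counts))),
                           condition = out$condition, layer = "raw_counts")
  truth <- tibble::tibble(gene = toupper(genes), role = role, lfc = out$lfc,
                          planted = out$lfc != 0 & !is.na(role))
  catalog <- regulator_catalog(genes[!is.na(role)], role[!is.na(role)],
                               source_label = "simulate_sc catalog")
  list(matrix = mat, ground_truth = truth, catalog = catalog)
}

#' Simulate a bulk resistant-vs-sensitive cohort
#'
#' Gaussian log-expression per gene; in the resistant condition the packaged
#' signature genes are shifted by `shift` in their signature direction (+ for
#' suppressors, - for drivers). Mirrors the small bulk validation designs
#' (a few replicates per condition).
#'
#' @param n_replicates Replicates per condition (default 3).
#' @param n_genes Total genes including the 20 signature genes (default 500).
#' @param shift Planted shift magnitude on signature genes (log-expression
#'   units, default 1).
#' @param noise_sd Residual sd (default 0.5).
#' @param baseline_mean,baseline_sd Per-gene baseline level distribution.
#' @param seed Integer seed.
#' @return A list with `matrix` (layer `log_normalized`, conditions
#'   `sensitive`/`resistant`) and `ground_truth`.
#' @export
simulate_bulk <- function(n_replicates = 3, n_genes = 500, shift = 1.0,
                          noise_sd = 0.5, baseline_mean = 5, baseline_sd = 2,
                          seed = fr20_default_seed) {
  if (n_replicates < 1) abort("n_replicates must be >= 1.")
  n_sig <- length(FR20_UP_SUPPRESSORS) + length(FR20_DOWN_DRIVERS)
  stopifnot(n_genes >= n_sig)
  genes <- c(FR20_UP_SUPPRESSORS, FR20_DOWN_DRIVERS,
             sprintf("GENE%04d", seq_len(n_genes - n_sig)))
  w <- c(rep(1, length(FR20_UP_SUPPRESSORS)),
         rep(-1, length(FR20_DOWN_DRIVERS)),
         rep(0, n_genes - n_sig))
  out <- withr::with_seed(seed, {
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    n_obs <- 2L * n_replicates
    condition <- rep(c("sensitive", "resistant"), each = n_replicates)
    mu <- baseline + outer(w * shift, as.numeric(condition == "resistant"))
    vals <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow = n_genes)
    list(vals = vals, condition = condition)
  })
  mat <- expression_matrix(out$vals, gene_ids = genes,
                           obs_ids = sprintf("sample%02d", seq_len(ncol(out$vals))),
                           condition = out$condition, layer = "log_normalized")
  list(matrix = mat,
       ground_truth = tibble::tibble(gene = toupper(genes), weight = w,
                                     shift = w * shift))
}

#' Parameters for the perturbation-library simulator
#'
#' @param n_genes Genes in the library (includes the 20 signature genes;
#'   default 1000).
#' @param n_null_instances Instances with pure noise profiles (default 200).
#' @param n_reversers Instances that reverse the signature: `-s` added to the
#'   suppressor stats, `+s` to the drivers (default 5).
#' @param n_aggravators Instances with the opposite shifts (default 5).
#' @param reverser_strength Shift magnitude `s` (default 3).
#' @param noise_sd Per-gene statistic noise sd (default 1).
#' @param seed Integer seed.
#' @return A list of class `perturb_sim_params`.
#' @export
perturb_sim_params <- function(n_genes = 1000, n_null_instances = 200,
                               n_reversers = 5, n_aggravators = 5,
                               reverser_strength = 3.0, noise_sd = 1.0,
                               seed = fr20_default_seed) {
  stopifnot(reverser_strength > 0, noise_sd > 0,
            n_genes >= length(FR20_UP_SUPPRESSORS) + length(FR20_DOWN_DRIVERS))
  structure(list(n_genes = as.integer(n_genes),
                 n_null_instances = as.integer(n_null_instances),
                 n_reversers = as.integer(n_reversers),
                 n_aggravators = as.integer(n_aggravators),
                 reverser_strength = reverser_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "perturb_sim_params")
}

#' Simulate a perturbation library with planted reversers and aggravators
#'
#' Null instances are iid Gaussian rank statistics; reverser instances
#' additionally repress the 8 up-suppressors (statistic shift `-s`) and
#' induce the 12 down-drivers (`+s`); aggravator instances do the opposite.
#' The class of each instance lives only in the returned `ground_truth`
#' table, not in the library metadata seen by [screen_library()].
#'
#' @param params A [perturb_sim_params()].
#' @return A list with `library` (a [perturbation_library()]) and
#'   `ground_truth` (tibble: `instance_id`, `class`).
#' @export
simulate_perturbations <- function(params = perturb_sim_params()) {
  stopifnot(inherits(params, "perturb_sim_params"))
  p <- params
  n_sig <- length(FR20_UP_SUPPRESSORS) + length(FR20_DOWN_DRIVERS)
  genes <- c(FR20_UP_SUPPRESSORS, FR20_DOWN_DRIVERS,
             sprintf("GENE%04d", seq_len(p$n_genes - n_sig)))
  n_inst <- p$n_null_instances + p$n_reversers + p$n_aggravators
  cls <- c(rep("reverser", p$n_reversers), rep("aggravator", p$n_aggravators),
           rep("null", p$n_null_instances))
  stats <- withr::with_seed(p$seed, {
    m <- matrix(rnorm(p$n_genes * n_inst, 0, p$noise_sd), nrow = p$n_genes)
    sup_idx <- seq_along(FR20_UP_SUPPRESSORS)
    drv_idx <- length(FR20_UP_SUPPRESSORS) + seq_along(FR20_DOWN_DRIVERS)
    rev_idx <- which(cls == "reverser")
    agg_idx <- which(cls == "aggravator")
    m[sup_idx, rev_idx] <- m[sup_idx, rev_idx] - p$reverser_strength
    m[drv_idx, rev_idx] <- m[drv_idx, rev_idx] + p$reverser_strength
    m[sup_idx, agg_idx] <- m[sup_idx, agg_idx] + p$reverser_strength
    m[drv_idx, agg_idx] <- m[drv_idx, agg_idx] - p$reverser_strength
    m
  })
  ids <- sprintf("inst_%03d", seq_len(n_inst))
  meta <- tibble::tibble(instance_id = ids,
                         compound_name = sprintf("cmpd_%03d", seq_len(n_inst)),
                         mode_of_action = NA_character_)
  lib <- perturbation_library(stats, meta, gene_ids = genes, instance_ids = ids)
  list(library = lib,
       ground_truth = tibble::tibble(instance_id = ids, class = cls))
}
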