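test_that("single-member sets hit the ES extremes", {
  stats <- setNames(c(5, 4, 3, 2, 1), sprintf("G%d", 1:5))
  expect_equal(as.numeric(enrichment_score(stats, "G1")), 1)
  expect_equal(as.numeric(enrichment_score(stats, "G5")), -1)
  expect_error(enrichment_score(stats, "NOPE"), "intersect")
  expect_error(enrichment_score(stats, names(stats)), "whole profile")
})

test_that("vectorized ES matches the cumulative-walk oracle", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    m <- sample(1:min(20, n - 1), 1)
    stats <- setNames(rnorm(n), sprintf("G%04d", sample.int(9999, n)))
    set <- sample(names(stats), m)
    p <- sample(c(0, 0.5, 1, 2), 1)
    es <- as.numeric(enrichment_score(stats, set, weight_exponent = p))
    expect_equal(es, oracle_es(stats, set, p), tolerance = 1e-12)
    expect_gte(es, -1); expect_lte(es, 1)
  }
})

test_that("ES agrees with an established GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(42)
  for (i in 1:20) {
    n <- sample(30:150, 1)
    stats <- setNames(rnorm(n), sprintf("G%04d", sample.int(9999, n)))
    set <- sample(names(stats), sample(3:12, 1))
    ord <- order(-stats, names(stats))
    ref <- fgsea::calcGseaStat(unname(stats[ord]),
                               selectedStats = which(names(stats)[ord] %in% set),
                               gseaParam = 1)
    expect_equal(as.numeric(enrichment_score(stats, set)), ref,
                 tolerance = 1e-10)
  }
})

test_that("ES is invariant to positive rescaling and deterministic under stat ties", {
  set.seed(43)
  stats <- setNames(rnorm(50), sprintf("G%02d", 1:50))
  set <- sample(names(stats), 7)
  es1 <- enrichment_score(stats, set)
  expect_equal(as.numeric(enrichment_score(stats * 3.7, set)),
               as.numeric(es1), tolerance = 1e-12)
  # ties broken by gene symbol ascending: permuting input order changes nothing
  stats_tied <- setNames(rep(c(2, 1), 10), sprintf("G%02d", 1:20))
  set2 <- c("G03", "G14")
  perm <- sample.int(20)
  expect_equal(as.numeric(enrichment_score(stats_tied[perm], set2)),
               as.numeric(enrichment_score(stats_tied, set2)))
})

test_that("NES normalization, p-value floor and degenerate fallback behave", {
  set.seed(44)
  stats <- setNames(rnorm(200), sprintf("G%03d", 1:200))
  strong <- names(sort(stats, decreasing = TRUE))[1:8]
  res <- normalized_enrichment(stats, strong, n_perm = 199, seed = 7)
  expect_gt(res$es, 0)
  expect_equal(sign(res$nes), sign(res$es))
  expect_gte(res$p_value, 1 / 200)
  expect_equal(res$set_size_used, 8)

  # es = 0 and same-sign-empty branches of the null summarization
  zero <- fr20:::nes_from_null(0, rnorm(50), 50)
  expect_equal(zero$nes, 0)
  expect_equal(zero$p, 1)
  expect_false(zero$degenerate)
  fb <- fr20:::nes_from_null(0.8, c(-0.5, -0.4, -0.3), 3)
  expect_true(fb$degenerate)
  expect_equal(fb$p, 1 / 4)
  expect_equal(fb$nes, 0.8 / 0.4)

  expect_error(normalized_enrichment(stats, strong, n_perm = 5), "n_perm")
})

test_that("a strongly planted set sits at the permutation p-value floor", {
  # "floor" = the estimator's attainable minimum given the same-sign null:
  # zero null exceedances, p = 1 / (n_null_same_sign + 1)
  floor_hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    stats <- setNames(rnorm(1000), sprintf("G%04d", 1:1000))
    members <- names(sort(stats, decreasing = TRUE))[sample.int(50, 8)]
    res <- normalized_enrichment(stats, members, n_perm = 199, seed = s)
    expect_gte(res$p_value, 1 / 200)
    abs(res$p_value - 1 / (res$n_null_same_sign + 1)) < 1e-12
  }, logical(1))
  expect_gt(mean(floor_hits), 0.5)
})

test_that("WTCS follows the sign rule and antisymmetry", {
  expect_equal(wtcs_combine(1.5, 0.7), 0)
  expect_equal(wtcs_combine(-2, 2), -2)
  expect_equal(wtcs_combine(2, -2), 2)
  expect_equal(wtcs_combine(0, 1.2), 0)
  expect_equal(wtcs_combine(1.2, 0), 0)
  set.seed(45)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(wtcs_combine(a, b), -wtcs_combine(b, a))
  same <- sign(a) == sign(b)
  expect_true(all(wtcs_combine(a, b)[same] == 0))
})

test_that("screen retains planted reversers and is seed-reproducible", {
  fx <- default_screen_fixture()
  res <- fx$res
  truth <- fx$sim$ground_truth
  merged <- dplyr::left_join(tibble::as_tibble(res), truth, by = "instance_id")

  reversers <- merged[merged$class == "reverser", ]
  expect_gte(sum(reversers$retained), 4)
  expect_true(all(reversers$wtcs < 0))
  top10 <- merged$instance_id[!is.na(merged$rank) & merged$rank <= 10]
  expect_true(all(reversers$instance_id %in% top10))

  aggravators <- merged[merged$class == "aggravator", ]
  expect_true(all(aggravators$wtcs >= 0 | !aggravators$retained))

  # ranks are 1..K ascending in wtcs over retained instances
  ret <- merged[merged$retained, ]
  ret <- ret[order(ret$rank), ]
  expect_equal(ret$rank, seq_len(nrow(ret)))
  expect_true(all(diff(ret$wtcs) >= 0))

  # identical seed => bit-identical output
  res2 <- screen_library(fx$sim$library, packaged_signature(), seed = 20)
  expect_identical(tibble::as_tibble(res2), tibble::as_tibble(res))

  # different seed changes permutation p-values but never the ES
  res3 <- suppressWarnings(
    screen_library(fx$sim$library, packaged_signature(), seed = 21,
                   n_perm = 100))
  res3 <- res3[match(res$instance_id, res3$instance_id), ]
  expect_equal(res3$es_up, res$es_up, tolerance = 1e-14)
  expect_false(identical(res3$p_up, res$p_up))
})

test_that("stronger reversal shifts expected WTCS down and screen edge cases hold", {
  grid <- c(1, 2, 4)
  mean_wtcs <- vapply(grid, function(s) {
    sim <- simulate_perturbations(perturb_sim_params(
      n_genes = 300, n_null_instances = 30, n_reversers = 3, n_aggravators = 0,
      reverser_strength = s, seed = 50))
    res <- suppressWarnings(
      screen_library(sim$library, packaged_signature(), n_perm = 99,
                     seed = 50))
    mean(res$wtcs[res$instance_id %in%
                    sim$ground_truth$instance_id[sim$ground_truth$class == "reverser"]])
  }, numeric(1))
  expect_true(all(diff(mean_wtcs) <= 1e-9))

  # libraries that cannot possibly retain anything warn, not error
  sim <- simulate_perturbations(perturb_sim_params(
    n_genes = 100, n_null_instances = 5, n_reversers = 0, n_aggravators = 0,
    seed = 51))
  expect_warning(res <- screen_library(sim$library, packaged_signature(),
                                       n_perm = 20, seed = 51),
                 "No instances retained")
  expect_equal(sum(res$candidate), 0)
  expect_true(all(is.na(res$rank)))

  # signature genes absent from the library are dropped with a warning
  small_sig <- resistance_signature(c("FTH1", "NOSUCHGENE"), "ACSL4")
  w <- capture_warnings(
    res2 <- screen_library(sim$library, small_sig, n_perm = 20, seed = 51))
  expect_true(any(grepl("absent from the library", w)))
  expect_equal(nrow(res2), 5)
})
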