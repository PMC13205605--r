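test_that("signature derivation intersects direction calls with roles", {
  catalog <- regulator_catalog(c("GPX4", "ACSL4", "ATF4", "FTH1"),
                               c("suppressor", "driver", "driver", "suppressor"))
  de <- fake_de(c("GPX4", "ACSL4", "ATF4", "FTH1", "OTHER"),
                c("up", "down", "up", "ns", "up"),
                fdr = c(1e-8, 1e-6, 1e-9, 0.5, 1e-10))
  sig <- derive_signature(de, catalog)
  expect_equal(sig$up_suppressors, "GPX4")     # ATF4 is a driver marked up: excluded
  expect_equal(sig$down_drivers, "ACSL4")      # FTH1 ns: excluded; OTHER not in catalog
  expect_equal(sig$n, 2)

  de_ns <- fake_de(c("GPX4", "ACSL4"), c("ns", "ns"), fdr = 0.9)
  expect_error(derive_signature(de_ns, catalog), "threshold")
})

test_that("signature arms are ordered by ascending FDR and arms stay disjoint", {
  catalog <- regulator_catalog(c("A", "B", "C"), rep("suppressor", 3))
  de <- fake_de(c("A", "B", "C"), rep("up", 3), fdr = c(1e-3, 1e-9, 1e-6))
  sig <- derive_signature(de, catalog)
  expect_equal(sig$up_suppressors, c("B", "C", "A"))
  expect_error(resistance_signature("A", "A"), "both signature arms")
})

test_that("FR20 is the signed sum of signature-gene expression", {
  sig <- resistance_signature("S", "D")
  m <- toy_matrix(rbind(c(2, 0), c(1, 0)), genes = c("S", "D"),
                  layer = "log_normalized")
  sc <- fr20_score(m, sig)
  expect_equal(sc$fr20, c(1, 0))  # 2 - 1, and all-zero observation -> 0
})

test_that("FR20 matches a per-cell loop oracle and its invariances", {
  set.seed(31)
  genes <- c(FR20_UP <- sprintf("U%02d", 1:8), FR20_DN <- sprintf("D%02d", 1:12),
             sprintf("X%02d", 1:30))
  sig <- resistance_signature(FR20_UP, FR20_DN)
  vals <- matrix(abs(rnorm(50 * 25, 1, 0.8)), nrow = 50)
  m <- toy_matrix(vals, genes = genes, layer = "log_normalized")
  sc <- fr20_score(m, sig)

  # naive per-cell loop oracle
  oracle <- vapply(seq_len(25), function(c) {
    tot <- 0
    for (g in seq_len(50)) {
      w <- if (genes[g] %in% FR20_UP) 1 else if (genes[g] %in% FR20_DN) -1 else 0
      tot <- tot + w * vals[g, c]
    }
    tot
  }, numeric(1))
  expect_lt(max(abs(sc$fr20 - oracle)), 1e-12)

  # linearity: +delta on a suppressor raises that cell's score by delta
  delta <- 0.37
  v2 <- vals; v2[3, 7] <- v2[3, 7] + delta   # gene U03
  sc2 <- fr20_score(toy_matrix(v2, genes = genes, layer = "log_normalized"), sig)
  expect_equal(sc2$fr20[7] - sc$fr20[7], delta, tolerance = 1e-12)
  expect_equal(sc2$fr20[-7], sc$fr20[-7])
  v3 <- vals; v3[10, 7] <- v3[10, 7] + delta  # gene D02 (driver)
  sc3 <- fr20_score(toy_matrix(v3, genes = genes, layer = "log_normalized"), sig)
  expect_equal(sc3$fr20[7] - sc$fr20[7], -delta, tolerance = 1e-12)

  # gene-order permutation invariance
  perm <- sample.int(50)
  mp <- toy_matrix(vals[perm, ], genes = genes[perm], layer = "log_normalized")
  expect_equal(fr20_score(mp, sig)$fr20, sc$fr20)

  # dropping a suppressor decreases every score by its non-negative expression
  sig_minus <- resistance_signature(setdiff(FR20_UP, "U01"), FR20_DN)
  sc4 <- fr20_score(m, sig_minus)
  expect_equal(sc$fr20 - sc4$fr20, unname(vals[1, ]))
  expect_true(all(sc$fr20 - sc4$fr20 >= 0))
})

test_that("missing signature genes follow the configured policy", {
  sig <- resistance_signature(c("S1", "S2"), "D1")
  m <- toy_matrix(rbind(c(1, 2), c(0.5, 0.25)), genes = c("S1", "D1"),
                  layer = "log_normalized")
  expect_warning(sc <- fr20_score(m, sig), "S2")
  expect_equal(attr(sc, "dropped_genes"), "S2")
  expect_equal(sc$fr20, c(0.5, 1.75))
  expect_error(fr20_score(m, sig, missing_policy = "error"), "S2")

  none <- toy_matrix(matrix(1, 1, 2), genes = "ZZZ", layer = "log_normalized")
  expect_error(suppressWarnings(fr20_score(none, sig)), "No signature genes")
  expect_error(fr20_score(toy_matrix(matrix(1L, 1, 2), genes = "S1",
                                     layer = "raw_counts"), sig),
               "raw counts")
})

test_that("group comparisons: ANOVA on two groups satisfies F = t^2", {
  set.seed(32)
  scores <- tibble::tibble(
    obs_id = sprintf("s%02d", 1:20),
    fr20 = c(rnorm(10, 0), rnorm(10, 1)),
    condition = rep(c("a", "b"), each = 10)
  )
  tt <- compare_scores(scores, "t")
  # pooled-variance t via anova identity needs var.equal; compare via aov
  av <- compare_scores(scores, "anova")
  t_pooled <- t.test(fr20 ~ condition, data = scores, var.equal = TRUE)$statistic
  expect_equal(av$statistic, unname(t_pooled^2), tolerance = 1e-10)
  expect_equal(av$test_name, "anova_one_way")
  expect_equal(sum(av$group_summaries$n), 20)
  expect_true(tt$p_value >= 0 && tt$p_value <= 1)

  three <- dplyr::mutate(scores, condition = rep(c("a", "b", "c"), length.out = 20))
  expect_error(compare_scores(three, "wilcoxon"), "exactly 2")
})

test_that("group comparisons are calibrated under the null and powered under shift", {
  set.seed(33)
  null_p <- vapply(1:100, function(i) {
    s <- tibble::tibble(fr20 = rnorm(40), condition = rep(c("a", "b"), each = 20))
    compare_scores(s, "wilcoxon")$p_value
  }, numeric(1))
  frac <- mean(null_p < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)

  s <- tibble::tibble(fr20 = c(rnorm(50), rnorm(50, 2)),
                      condition = rep(c("a", "b"), each = 50))
  expect_lt(compare_scores(s, "wilcoxon")$p_value, 1e-6)
  expect_lt(compare_scores(s, "t")$p_value, 1e-6)
})

test_that("quartile stratification assigns boundary samples by >= / <=", {
  scores <- structure(
    tibble::tibble(obs_id = sprintf("s%d", 1:8), fr20 = 1:8,
                   condition = "all"),
    class = c("fr20_scores", class(tibble::tibble())))
  resp <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                         response_value = (1:8) / 10)
  cmp <- stratify_quartiles(scores, resp)
  mem <- attr(cmp, "membership")
  expect_equal(sum(mem$group == "high_fr20"), 2)
  expect_equal(sum(mem$group == "low_fr20"), 2)
  expect_setequal(mem$obs_id[mem$group == "high_fr20"], c("s7", "s8"))

  # monotone response: high group responds more
  set.seed(34)
  sc2 <- structure(
    tibble::tibble(obs_id = sprintf("t%02d", 1:40), fr20 = rnorm(40),
                   condition = "all"),
    class = c("fr20_scores", class(tibble::tibble())))
  resp2 <- tibble::tibble(sample_id = sc2$obs_id,
                          response_value = sc2$fr20 + rnorm(40, 0, 0.3))
  cmp2 <- stratify_quartiles(sc2, resp2)
  summ <- cmp2$group_summaries
  expect_gt(summ$median[summ$label == "high_fr20"],
            summ$median[summ$label == "low_fr20"])
  expect_lt(cmp2$p_value, 0.05)

  # constant scores cannot be stratified
  flat <- structure(
    tibble::tibble(obs_id = sprintf("s%d", 1:8), fr20 = rep(1, 8),
                   condition = "all"),
    class = c("fr20_scores", class(tibble::tibble())))
  expect_error(stratify_quartiles(flat, resp), "quartile|ties|stratify")
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  sig <- packaged_signature()
  td <- tidy(sig)
  expect_equal(nrow(td), 20)
  expect_equal(sum(td$weight), 8 - 12)
  gl <- glance(sig)
  expect_equal(gl$n, 20)

  s <- tibble::tibble(fr20 = c(1, 2, 3, 7, 8, 9),
                      condition = rep(c("a", "b"), each = 3))
  cmp <- compare_scores(s, "t")
  expect_named(glance(cmp),
               c("test_name", "statistic", "p_value", "n_groups", "n_obs"))
  expect_equal(nrow(tidy(cmp)), 2)
})
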