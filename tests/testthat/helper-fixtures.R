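# Shared fixtures and independent oracles for the test suite.

# Cache expensive simulated datasets so several test files can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-condition scRNA-seq dataset plus the derived DE table (seed = 20,
# the package default) — the dataset the recovery and separation checks use.
default_sc_fixture <- function() {
  cached("default_sc", {
    sim <- simulate_sc()
    normalized <- normalize_counts(qc_filter(sim$matrix))
    de <- differential_expression(normalized, "resistant", "sensitive")
    list(sim = sim, normalized = normalized, de = de)
  })
}

# Default-condition perturbation screen (seed = 20).
default_screen_fixture <- function() {
  cached("default_screen", {
    sim <- simulate_perturbations()
    res <- screen_library(sim$library, packaged_signature(), seed = 20)
    list(sim = sim, res = res)
  })
}

# Small expression matrix built directly from values.
toy_matrix <- function(values, genes = NULL, obs = NULL, condition = NULL,
                       layer = "log_normalized") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(obs)) obs <- sprintf("c%02d", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = genes, obs_ids = obs,
                    condition = condition, layer = layer)
}

# A minimal DE table carrying the class the downstream functions expect.
fake_de <- function(gene, direction, fdr = 1e-4, log2_fc = NULL,
                    group_a = "resistant", group_b = "sensitive") {
  if (is.null(log2_fc)) {
    log2_fc <- ifelse(direction == "up", 1, ifelse(direction == "down", -1, 0))
  }
  tab <- tibble::tibble(
    gene = toupper(gene),
    log2_fc = log2_fc,
    p_value = fdr, fdr = fdr,
    pct_in_a = 1, pct_in_b = 1,
    direction = factor(direction, levels = c("up", "down", "ns"))
  )
  structure(tab, class = c("fr20_de", class(tab)),
            params = list(group_a = group_a, group_b = group_b,
                          lfc_threshold = 0.25, fdr_threshold = 0.01,
                          min_pct = 0.1))
}

# Independent O(N) cumulative-walk enrichment-score oracle: materializes the
# full running sum instead of the O(m) extrema formula used by the package.
oracle_es <- function(stats, gene_set, weight_exponent = 1) {
  nm <- toupper(names(stats))
  ord <- order(-stats, nm, method = "radix")
  s <- unname(stats[ord])
  hit <- nm[ord] %in% toupper(gene_set)
  n <- length(s)
  m <- sum(hit)
  stopifnot(m >= 1, m < n)
  w <- abs(s)^weight_exponent
  tot <- sum(w[hit])
  step <- rep(-1 / (n - m), n)
  step[hit] <- if (tot == 0) 1 / m else w[hit] / tot
  walk <- cumsum(step)
  mp <- max(walk)
  mn <- min(walk)
  if (mp >= -mn) mp else mn
}

# Exhaustive-enumeration two-sided Wilcoxon rank-sum p-value for tiny groups:
# enumerates every assignment of the pooled values to group A.
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  na <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
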