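---
title: "FR20 and D-FR20: models, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FR20 and D-FR20: models, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fr20)
```

## The scientific problem

BET bromodomain inhibitors (BBDIs, prototype JQ1) kill triple-negative
breast cancer (TNBC) cells by displacing BRD4 from chromatin, but resistant
populations emerge under sustained treatment. A recurring feature of the
resistant transcriptional state is ferroptosis inhibition: genes that
*suppress* ferroptosis (e.g. *GPX4*, *FTH1*) are up-regulated while genes
that *drive* it (e.g. *ACSL4*, *HMOX1*) are down-regulated. This package
implements two quantitative tools built on that observation:

* **FR20** — a per-cell (or per-sample) resistance score: the signed sum of
  normalized expression over 20 dysregulated ferroptosis regulators,

  $$\mathrm{FR20}_c \;=\; \sum_{i=1}^{n} w_i \, \mathrm{Exp}_{ic},
  \qquad w_i = \begin{cases} +1 & \text{suppressor (8 genes)} \\
  -1 & \text{driver (12 genes)} \end{cases}$$

  A high score means a ferroptosis-inhibited, resistance-like state.

* **D-FR20** — a connectivity screen over a library of drug-perturbation
  rank profiles: for each instance, weighted Kolmogorov–Smirnov enrichment
  scores of the two signature arms are permutation-normalized (NES) and
  combined into the weighted connectivity score

  $$\mathrm{WTCS} = \begin{cases}
  (\mathrm{NES}_{up} - \mathrm{NES}_{down})/2 &
    \mathrm{sign}(\mathrm{NES}_{up}) \ne \mathrm{sign}(\mathrm{NES}_{down})\\
  0 & \text{otherwise}
  \end{cases}$$

  Instances significant for **both** arms (BH FDR < 0.05 per arm) are
  ranked by ascending WTCS; the most negative instances repress the
  up-regulated suppressors *and* induce the down-regulated drivers — the
  profile of a candidate re-sensitizer.

## The derivation pipeline

The signature is derived, not assumed: `qc_filter()` →
`normalize_counts()` → `differential_expression()` → `derive_signature()`.

**Quality control** (`qc_thresholds()`): cells covering fewer than 200
genes or with more than 20% of UMIs on mitochondrial genes (symbol prefix
`MT-`, configurable for non-human data) are removed first; genes expressed
in fewer than 3 of the *surviving* cells are removed second. The order of
the two passes is fixed — cell rules, then gene rules — so the gene filter
is always evaluated against the retained cell population. The cell-coverage
threshold is stated for genome-scale panels; analyses on reduced gene
panels (such as the small simulated panels in the test suite) should scale
it to roughly the expected expressed-gene count.

**Normalization**: the standard library-size log-normalization
$v_{gc} = \ln(1 + 10^4 \, x_{gc} / \sum_g x_{gc})$. Columns with zero
totals are rejected by name.

**Differential expression**: per-gene two-sided Wilcoxon rank-sum test on
log-normalized values between the two conditions, with BH correction across
tested genes. Genes must be expressed in at least `min_pct = 0.1` of cells
in one of the groups to be tested (the common single-cell marker-test
default; the threshold is exposed). The fold change uses the pseudocount
convention on de-logged normalized means,
$\log_2\!\big((\bar m_a + 1)/(\bar m_b + 1)\big)$ — the behavior of the
widely used single-cell marker tests. Note its consequence: for genes with
low absolute expression the +1 pseudocount compresses the apparent fold
change, so a gene whose counts truly double may show an observed
`log2_fc` well below 1. Direction calls use `|log2_fc| > 0.25` and
`FDR < 0.01`.

Small groups (both $n \le 25$) use the exact rank-sum distribution;
larger groups the normal approximation with tie correction. This makes
p-values reproducible across platforms and exactly enumerable in tests.

**Catalog intersection**: a regulator catalog maps genes to
driver/suppressor roles. Genes annotated with *both* roles are excluded at
load time (the signed weighting is undefined for them) and reported. Roles
outside the two-level vocabulary are an error by default;
`drop_other_roles = TRUE` discards them with a message — FerrDb-style
sources also carry a "marker" category that has no weight in this score.
`derive_signature()` takes suppressors called up and drivers called down,
ordered by ascending FDR. `fisher_direction_enrichment()` provides the
companion check that the direction calls are enriched in the expected role,
as a one-sided Fisher exact test over the universe of *tested* genes (the
background choice is stamped into the result; enrichment p-values shift
with broader universes, so they are reported, not thresholds of the
pipeline).

## Scoring conventions

"Normalized expression" in the FR20 sum is resolved by modality:

* **single-cell**: log-normalized values. All terms are non-negative, so
  dropping a suppressor can only lower scores — a useful monotonicity for
  sanity checks.
* **bulk cohorts**: per-gene z-scores across the cohort (`zscore_genes()`,
  sample sd, zero-variance genes set to 0), because platform-native scales
  differ by orders of magnitude between genes and would otherwise dominate
  the sum.

Both paths are supported and the choice is recorded in the score metadata;
neither is claimed to be uniquely correct, and cross-study score magnitudes
are not comparable — only within-cohort contrasts are meaningful.

Missing signature genes (common on older arrays) are dropped with a warning
by default (`missing_policy = "drop_and_warn"`); strict mode errors.
Validation statistics follow the modality: Wilcoxon rank-sum for
single-cell contrasts, two-tailed t for small bulk designs, one-way ANOVA
for multi-group comparisons, and quartile stratification
(`stratify_quartiles()`, type-7 quantiles, boundary samples assigned by
$\ge$ / $\le$) against drug-response AUC tables.

## Enrichment, NES and the permutation null

`enrichment_score()` sorts a profile by statistic descending, breaking ties
by gene symbol ascending so rankings are deterministic. The running sum
gains $|s_g|^p / \sum_{set} |s|^p$ at member positions ($p = 1$ by
default; $p = 0$ gives the unweighted KS variant used to check closed
forms) and loses $1/(N-m)$ elsewhere; the ES is the extremum of maximum
absolute deviation. The implementation evaluates only the $2m$ candidate
extrema (just before and just after each member position) rather than the
full $N$-step walk; the test suite checks it against an independent
full-walk oracle and against an established GSEA implementation. If every
matched member has statistic exactly 0 (so the weighted increments are
undefined at $p>0$), equal weights are substituted. When the maximum
positive and negative excursions tie exactly, the positive one is reported.

The null model is gene-set permutation: random same-size gene sets drawn
without replacement from the profile, the only null available for
rank-only profiles. NES divides the ES by the mean |ES| of *same-sign*
null draws, and

$$p = \frac{1 + \#\{\text{same-sign null } |ES| \ge |es|\}}
          {1 + \#\{\text{same-sign null}\}}.$$

The add-one estimator keeps $p \ge 1/(n_{perm}+1)$; its attainable floor
for a given draw is $1/(\#\text{same-sign}+1)$, which the result exposes
as `n_null_same_sign`. If no same-sign null exists, NES falls back to the
all-null mean |ES| with $p = 1/(n_{perm}+1)$ and a `degenerate_null` flag —
this preserves the sign and avoids division by zero.

In `screen_library()`, BH correction is applied per signature arm across
instances and the two arms are AND-combined for retention; the scope is
stamped into the result parameters. Each instance × arm permutation draw
gets an independent sub-seed derived from the master seed, so results are
identical regardless of evaluation order and bit-reproducible for a given
seed. WTCS ties are broken by instance id. Compound instances are ranked
independently (no collapsing across instances of the same compound);
aggregation to the compound level is left to the user, since summarizing
discordant instances is a policy choice, not arithmetic.

## What the synthetic generators emulate — and what they do not

`simulate_sc()` draws UMI counts from a negative binomial with
$\mu_{gc} = \ell_c \, \beta_g \, 2^{\lambda_g [c \in \text{resistant}]}$
and dispersion 0.3 (size = 1/dispersion): log-normal baselines
($\ln \beta_g \sim N(0.5, 1)$), log-normal library-size factors
(log-sd 0.3), 500 cells per condition, 2000 genes. The planted pattern is
the packaged signature (+1 log2FC on the 8 suppressors, −1 on the 12
drivers), 50 decoy catalog regulators with no effect (the specificity
control), and 100 background DE genes outside the catalog (realistic
multiple-testing pressure). These values are the generator's fixed study
conditions; they were chosen as typical of droplet scRNA-seq depth and
overdispersion, not fit to any dataset.

`simulate_bulk()` is a Gaussian log-expression design with a few replicates
per condition and signature-direction shifts, mirroring small bulk
validation cohorts. `simulate_perturbations()` builds a LINCS-style
statistic matrix: iid Gaussian null instances plus reversers ($-s$ on
suppressors, $+s$ on drivers, default $s = 3$, noise sd 1 — a strong but
realistic moderated-z displacement) and aggravators with the opposite
shifts; instance classes live only in the ground-truth table, never in the
metadata the screen sees.

None of the generators model doublets, ambient RNA, batch effects, gene-gene
correlation, or compound-specific off-target structure. Passing recovery
tests on them therefore demonstrates the *machinery* — power at the planted
effect sizes, calibration under the null, correct ranking arithmetic — not
performance on real data, where signature genes are correlated and
perturbation profiles are far noisier.

## Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds (package default 20,
  the signature size); generators are pure functions of their parameters.
* Exact Wilcoxon below 25 per group, normal approximation with tie
  correction above; matrices with constant rows produce p = 1, not NaN.
* Fisher odds ratios use the sample cross-product, with a 0.5 continuity
  correction only when a cell is zero (flagged in the output).
* Quartile stratification refuses constant or massively tied scores (the
  two quantiles coincide) instead of returning an arbitrary partition.
* TSV matrix output writes shortest-exact decimal representations and is
  read back with a correctly rounded parser, so write/read round trips are
  bit-for-bit.
* Gene symbols are upper-cased at every boundary; matching is
  case-insensitive throughout, and no alias resolution is attempted.

## Problem sizes used in the shipped checks

The packaged test-and-verification runs use the generator defaults for the
headline recovery checks (2000 genes × 1000 cells; 210-instance screen with
1000 permutations per arm) and reduced panels (300–1000 genes, 20–200
cells per group, 99–199 permutations) for property and calibration loops
that repeat across many seeds, with the cell-coverage QC threshold scaled
to those panels. These sizes are the package's chosen verification design:
large enough for the planted effects to be identifiable, small enough to
iterate on.

## Known limitations

* The signature weights are ±1 by construction; no attempt is made to
  learn continuous weights, and FR20 is not a calibrated probability of
  resistance.
* The Fisher enrichment background (tested genes) is one defensible choice
  among several; enrichment p-values should be read accordingly.
* The screen treats instances independently; dose, cell line, and time
  covariates in real perturbation libraries are ignored.
* With few permutations or few instances, the per-arm BH + AND retention
  rule is conservative: the p-value floor may exceed what the FDR
  threshold requires, leaving nothing retained (the screen warns rather
  than errors).
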