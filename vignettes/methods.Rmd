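---
title: "Methods: linking microbiota composition to host gene expression across unmatched cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking microbiota composition to host gene expression across unmatched cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

chronolink analyzes a 2x2 factorial mouse experiment — alcohol vs. water
(X1) crossed with wrong-time feeding vs. right-time feeding (X2, food
offered during the rest phase as a circadian disruptor) — in which colonic
microbiota (16S OTU counts) and colonic gene expression (RNA-seq counts)
were measured on **two independent cohorts of animals**. The goal is to
quantify how much of the treatment-driven change in gene expression can be
statistically linked to treatment-driven change in microbial composition,
without any animal having both measurements.

## Community statistics

The OTU table is preprocessed in the standard amplicon order: non-bacterial
lineages removed (archaea at kingdom rank, mitochondria at family rank,
chloroplasts at class rank, case-insensitive), samples rarefied without
replacement to a common depth (the minimum sample total by default; 43,000
reads at the reference scale), and OTUs with a grand total below 5
discarded.

Alpha diversity is observed richness and inverse Simpson
$1/\sum_i p_i^2$; each metric is regressed on
$X_1 + X_2 + X_1X_2$ by OLS with a type II ANOVA table and Tukey HSD
post-hoc comparisons. Beta diversity uses Bray-Curtis dissimilarity
$d(x,y) = 1 - 2\sum_i \min(x_i,y_i)/(\sum x + \sum y)$ partitioned by
PERMANOVA (Anderson's Gower-centering formulation, sequential terms). The
permutation p-value is $(1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$; for a
single two-level factor an exhaustive mode enumerates every relabeling and
is tested against an independent enumeration oracle. Pairwise post-hoc
PERMANOVA reports raw p-values by default (adjustment is configurable).
Taxon-level inference sums OTU counts to the requested rank **before**
transformation, applies a centered log-ratio transform after multiplicative
zero replacement ($\delta = 0.5/\text{total}$, non-zero parts rescaled),
fits the same 2x2 OLS per taxon, and controls FDR with Benjamini-Hochberg
within each rank.

## The correspondence procedure

Because the cohorts are unmatched, per-(gene, taxon) association is probed
through **random within-group pairings**:

1. *Panels.* Taxa are collapsed to genus level and kept only if their mean
   raw count exceeds 10 in **every** treatment group; counts become
   per-sample percentages on the full pre-filter basis (panel percentages
   need not re-sum to 100 — the conversion precedes the filter and no
   re-closure is stated in the protocol this mirrors). Genes with more than
   one zero record are dropped; the rest are z-standardized.
2. *Pairings.* Each of R = 500 realizations draws a uniform one-to-one
   matching of microbiome to expression samples within each group (when
   group sizes differ, min(size) pairs are drawn, resampling the larger
   side each realization). All realizations flow from one seed.
3. *Counting.* Per realization, each standardized gene is regressed on each
   taxon's percent abundance and the slope's two-sided t-test is recorded
   at $\alpha_0 = 0.05$. The protocol never names this test; simple OLS on
   the single taxon was chosen as the plainest reading, and it is monotone
   in the Pearson correlation on standardized data. A design-adjusted
   variant (both variables residualized on the 2x2 design) is available
   behind `adjust_for_treatment`. A pair whose count exceeds the count
   threshold (default 53 of 500) is a *candidate*.
4. *Threshold derivation.* Under independence a null pair's count is
   Binomial(R, $\alpha_0$); `count_threshold_from_bonferroni()` returns the
   smallest $k$ with $P(X \ge k) \le \alpha/m$, minus one. The reference
   protocol prints 53 without stating $m$; the helper's exact tail gives
   33 ($m=1$), 41 ($m=34$), 49 ($m=13{,}782$) and 54 ($m = 34 \times
   13{,}782$), so the full panel product with an approximate tail is the
   most plausible origin. The pipeline logs this grid and does not assert
   agreement.
5. *Selection.* Per realization and gene, a partial F-test compares the
   treatment-only model against treatments plus a taxa subset; genes whose
   rejection count exceeds 40 of 500 are *selected*. With ~20 paired
   samples a 34-taxon full model is unfittable, so the subset rule is
   explicit: by default each gene uses its own candidate taxa (largest
   counts first), truncated so the full model keeps at least 3 residual
   degrees of freedom; a panel-wide "all" rule (most abundant taxa first,
   same truncation) serves calibration studies.
6. *Two-step models.* Model 1, $M_t = \beta_0 + \beta_1X_1 + \beta_2X_2 +
   \beta_3X_1X_2 + \varepsilon$, flags taxa with $p(\beta_3) < 0.05$.
   Model 2, $Y_k = \beta_0 + \beta_1X_1 + \beta_2X_2 + \beta_3X_1X_2 +
   \beta_4M_t + \beta_5M_tX_1X_2 + \varepsilon$, is fit per selected gene
   and selected taxon under each pairing; a gene-taxon axis is
   *dual-significant* in one fit when both $p(\beta_3)$ and $p(\beta_4)$
   are below 0.05. Because no aggregation rule across pairings is stated
   in the protocol, the pipeline reports the dual-significant fraction per
   axis and flags axes exceeding 0.5 — a majority rule, chosen as the
   package's own convention. $\beta_5$ is estimated and reported but takes
   part in no selection rule.

Selected genes are displayed as a groups-by-genes matrix of group means
divided by each row's mean of group means (every row averages 1).

## The synthetic world

The generator emulates the study design: four groups, n = 5 mice per group
per cohort (configurable), disjoint sample ids, identical group structure.

* **Taxa** follow a logistic-normal multinomial. Group-level log abundance
  is $\lambda_{gt} = \alpha_t + a_{1t}X_1 + a_{2t}X_2 + a_{3t}X_1X_2$ with
  baselines $\alpha_t \sim N(0, 2)$ sorted decreasing (taxon 1 is the most
  abundant, so planted taxa survive the abundance filter by construction);
  a sample adds $N(0, 0.5)$ noise per taxon, softmax gives its composition,
  and a multinomial draw at a lognormal library size (mean 43,000, sdlog
  0.2) gives counts.
* **Genes** are negative binomial with per-gene dispersion drawn
  log-uniform on [0.05, 0.5] and log mean
  $b_{0k} + b_{1k}X_1 + b_{2k}X_2 + b_{3k}X_1X_2 +
  \sum_t c_{kt}\,\tilde\lambda_{gt}$, re-normalized within sample against a
  lognormal depth. $\tilde\lambda$ is the group-level latent centered
  across groups: **coupling acts through group-level abundance only**,
  because unmatched cohorts share nothing finer than group structure.
* All randomness flows from one seed through per-table substreams; the
  realized group latents are returned for oracle checks.

Effect-size defaults (interaction 2 on the log scale, coupling 1.5) are
**arbitrary testability choices** — the reference study reports no effect
sizes — and are documented here once. The generator does not simulate
reads, chimeras, rarefaction artifacts, phylogenetic structure, or
per-sample microbiome-expression coupling (impossible to observe across
cohorts); a green recovery test therefore establishes that the code
recovers what this world plants, not that the procedure works on real data.

## What the counting threshold does not control

The binomial Bonferroni threshold assumes a null pair's R significance
indicators are independent. They are not: every realization re-pairs the
**same** ~20 gene values with the same ~20 taxon values, so a chance
group-level alignment (present even under the global null) or an
outlier-driven within-group alignment persists across most realizations.
Measured on 200 null datasets (n = 5/group, 50 taxa, 500 genes, R = 100),
the mean per-pair count is 4.96 — the binomial mean almost exactly, so the
marginal test size is right — yet every dataset contains hundreds of pairs
above the m = 25,000 Bonferroni threshold, with or without treatment
adjustment. The count distribution is zero-inflated with a heavy dependent
tail; the threshold orders pairs usefully but provides no family-wise
error guarantee. The corresponding acceptance check is deliberately kept
red rather than weakened.

## What the F-test cannot see

The reduced model of the taxa-inclusion F-test (intercept, X1, X2, X1X2)
**saturates** the four group means: any purely group-level signal is
absorbed exactly, so taxa can improve the fit only through within-group,
per-sample signal — which two unmatched cohorts cannot share. Consequently
genes coupled to taxa at the group level are fully recoverable by the
counting step (their pair counts sit near R) but are invisible to the
F-test selection; conversely, the per-gene candidate subset rule re-uses
the data that nominated the taxa, inflating rejection counts for genes
with incidental within-group alignments. The end-to-end recovery
acceptance check is likewise kept red, with the candidate-level recovery
asserted instead alongside it. Users should read the selected-gene list as
"genes whose cross-pairing association structure is unusually stable", not
as causally microbiota-explained genes.

## Numerical choices

* All OLS fits share one QR-based multi-response solver, tested against a
  normal-equations oracle at 1e-10 on small fixtures.
* PERMANOVA sums of squares are clamped at zero (Gower centering can
  produce -1e-16 residuals for perfectly separated groups); permutation
  comparisons use `F_perm >= F_obs - 1e-12` so exact ties count toward the
  p-value.
* Zero-variance responses get slope p-values of 1 and are flagged rather
  than propagating 0/0.
* Rarefaction uses `sample()` without replacement on the expanded read
  vector (multivariate hypergeometric), seeded.
* The per-pair test's fast path computes correlations via one `crossprod`
  per realization; its equivalence to per-pair OLS slope tests is asserted
  in the suite.
* Counts use strict "more than" comparisons everywhere a threshold is
  named (candidate, selection), matching the protocol's wording.

## Known limitations

* The per-gene two-way ANOVA on `log1p` counts is a simplified stand-in
  for a negative-binomial differential analysis; it is adequate for
  calibration tests, not a replacement for dedicated RNA-seq machinery.
* Pairwise PERMANOVA p-values are raw by default; with six pairs the
  family-wise error is uncontrolled unless an adjustment is configured.
* Percent abundances are compositional; Model 1 and 2 coefficients on
  percent scales inherit closure effects (an increase in one abundant
  taxon mechanically depresses the rest).
* No phylogeny-aware metrics, no UniFrac, no pathway enrichment.
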