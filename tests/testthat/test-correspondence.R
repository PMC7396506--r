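test_that("taxa panel applies the all-four-groups abundance rule", {
  md <- meta_2x2(2)
  # taxon A: group means (12, 11, 15, 20) -> kept; B: (12, 9, 15, 20) -> dropped
  a <- c(12, 12, 11, 11, 15, 15, 20, 20)
  b <- c(12, 12, 9, 9, 15, 15, 20, 20)
  counts <- cbind(A = a, B = b, C = rep(1000L, 8))
  storage.mode(counts) <- "integer"
  rownames(counts) <- md$sample_id
  tax <- data.frame(otu_id = c("A", "B", "C"),
                    lineage = sprintf("k__Bacteria;p__F;c__;o__;f__;g__G%s;s__",
                                      c("A", "B", "C")))
  tbl <- otu_table(counts, tax)
  panel <- build_taxa_panel(tbl, md, min_group_mean = 10)
  expect_setequal(panel$taxa, grep("GA|GC", colnames(collapse_taxa(tbl, "genus")),
                                   value = TRUE))
  # percentages computed on the full pre-filter basis
  expect_equal(unname(panel$values[1, ]),
               c(12, 1000) / (12 + 12 + 1000) * 100)
  all_panel <- build_taxa_panel(tbl, md, min_group_mean = 0)
  expect_equal(all_panel$n_after, 3)
  expect_error(build_taxa_panel(tbl, md, min_group_mean = 1e6), "no taxon")
})

test_that("gene panel enforces the at-most-one-zero rule and standardizes", {
  m <- cbind(g_two_zero = c(0, 0, 3, 4, 5, 6),
             g_one_zero = c(0, 2, 3, 4, 5, 6),
             g_clean = c(5, 6, 7, 8, 9, 10),
             g_const = rep(4, 6))
  rownames(m) <- paste0("e", 1:6)
  em <- expression_matrix(m, "raw_count")
  expect_warning(panel <- build_gene_panel(em), "g_const")
  expect_setequal(panel$genes, c("g_one_zero", "g_clean"))
  expect_true(all(abs(colMeans(panel$values)) < 1e-9))
  expect_true(all(abs(apply(panel$values, 2, sd) - 1) < 1e-9))
})

test_that("pairings are within-group bijections, reproducible and uniform", {
  md <- meta_two_cohorts(5)
  pr <- make_pairings(md, R = 400, seed = 99)
  expect_length(pr$realizations, 400)
  for (p in pr$realizations[1:5]) {
    expect_equal(nrow(p), 20)
    expect_false(anyDuplicated(p$microbiome) > 0)
    expect_false(anyDuplicated(p$expression) > 0)
    # no cross-group pairs
    expect_equal(md$group[match(p$microbiome, md$sample_id)],
                 md$group[match(p$expression, md$sample_id)])
  }
  pr2 <- make_pairings(md, R = 400, seed = 99)
  expect_identical(pr$realizations, pr2$realizations)
  # each (mb, ex) within-group pair occurs with frequency ~ 1/5
  hits <- vapply(pr$realizations, function(p)
    any(p$microbiome == "MB01" & p$expression == "EX03"), logical(1))
  expect_lt(abs(mean(hits) - 0.2), 4 * sqrt(0.2 * 0.8 / 400))
  # group present in one cohort only -> error
  bad <- md[!(md$cohort == "expression" & md$group == "water+RTF"), ]
  expect_error(make_pairings(bad, R = 2, seed = 1), "water\\+RTF")
})

test_that("unequal cohort sizes pair min(size) samples per group", {
  md <- meta_two_cohorts(5)
  md <- md[md$sample_id != "EX01", ]   # lose one expression sample
  pr <- make_pairings(md, R = 20, seed = 3)
  sizes <- vapply(pr$realizations, nrow, integer(1))
  expect_true(all(sizes == 19))
  g <- pr$realizations[[1]]$group
  expect_equal(sum(g == "water+RTF"), 4)
})

test_that("per-pair counting equals a direct per-pair OLS significance tally", {
  ds <- small_dataset(seed = 61, n_per_group = 4, n_taxa = 10, n_genes = 8)
  md <- ds$metadata
  tp <- build_taxa_panel(ds$otu, md[md$cohort == "microbiome", ],
                         min_group_mean = 0)
  gp <- build_gene_panel(ds$expr)
  pr <- make_pairings(md, R = 12, seed = 7)
  pc <- count_pair_significance(gp, tp, pr, md, alpha0 = 0.05,
                                count_threshold = 3)
  # oracle: per realization, per (gene, taxon), normal-equations slope test
  counts <- matrix(0L, ncol(gp$values), ncol(tp$values))
  for (p in pr$realizations) {
    g <- gp$values[p$expression, , drop = FALSE]
    t_ <- tp$values[p$microbiome, , drop = FALSE]
    for (k in seq_len(ncol(g))) {
      for (t2 in seq_len(ncol(t_))) {
        orc <- oracle_ols(cbind(1, t_[, t2]), g[, k])
        counts[k, t2] <- counts[k, t2] + (orc$p[2] < 0.05)
      }
    }
  }
  expect_equal(unname(pc$counts), counts)
  expect_identical(pc$candidate, pc$counts > 3)
  # counts invariant to gene/taxon ordering
  gp2 <- gp; gp2$values <- gp2$values[, rev(seq_len(ncol(gp2$values)))]
  gp2$raw <- gp2$raw[, rev(seq_len(ncol(gp2$raw)))]
  pc2 <- count_pair_significance(gp2, tp, pr, md, count_threshold = 3)
  expect_equal(pc2$counts[rownames(pc$counts), ], pc$counts)
  # boundary: threshold = R -> no candidates
  pcR <- count_pair_significance(gp, tp, pr, md, count_threshold = pr$R)
  expect_false(any(pcR$candidate))
})

test_that("adjusted per-pair test equals the design-adjusted slope test", {
  ds <- small_dataset(seed = 62, n_per_group = 4, n_taxa = 6, n_genes = 5)
  md <- ds$metadata
  tp <- build_taxa_panel(ds$otu, md[md$cohort == "microbiome", ],
                         min_group_mean = 0)
  gp <- build_gene_panel(ds$expr)
  pr <- make_pairings(md, R = 5, seed = 8)
  pc <- count_pair_significance(gp, tp, pr, md, adjust_for_treatment = TRUE,
                                count_threshold = 2)
  counts <- matrix(0L, ncol(gp$values), ncol(tp$values))
  for (p in pr$realizations) {
    mdp <- md[match(p$microbiome, md$sample_id), ]
    D <- design_2x2(mdp$X1, mdp$X2)
    g <- gp$values[p$expression, , drop = FALSE]
    t_ <- tp$values[p$microbiome, , drop = FALSE]
    for (k in seq_len(ncol(g))) {
      for (t2 in seq_len(ncol(t_))) {
        orc <- oracle_ols(cbind(D, t_[, t2]), g[, k])
        counts[k, t2] <- counts[k, t2] + (orc$p[5] < 0.05)
      }
    }
  }
  expect_equal(unname(pc$counts), counts)
})

test_that("gene coupled to a taxon's group latent reaches a count near R", {
  d <- synthetic_design(n_per_group = 5, n_taxa = 20, n_genes = 30, seed = 63,
                        library_size_taxa = 20000, library_size_genes = 1e5)
  tr <- planted_truth(d, n_interaction_taxa = 2, taxon_interaction_effect = 2,
                      n_coupled_genes = 4, coupling_strength = 3)
  ds <- generate_dataset(d, tr)
  md <- ds$metadata
  tp <- build_taxa_panel(ds$otu, md[md$cohort == "microbiome", ])
  gp <- build_gene_panel(ds$expr)
  pr <- make_pairings(md, R = 100, seed = 9)
  pc <- count_pair_significance(gp, tp, pr, md, count_threshold = 53)
  coupled <- sprintf("gene_%04d", tr$coupled_genes)
  expect_true(all(apply(pc$counts[coupled, , drop = FALSE], 1, max) > 80))
})

test_that("Bonferroni count threshold equals the summed-pmf oracle on a grid", {
  grid <- expand.grid(R = c(20, 100, 500), alpha0 = c(0.01, 0.05, 0.2),
                      m = c(1, 34, 500 * 34))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(count_threshold_from_bonferroni(g$R, g$alpha0, g$m),
                 oracle_count_threshold(g$R, g$alpha0, g$m),
                 info = paste(g, collapse = "/"))
  }
  expect_identical(count_threshold_from_bonferroni(500, 0.05, 1, alpha = 2), 0L)
  expect_error(count_threshold_from_bonferroni(5, 0.999, 1e12), "attainable")
  # paper-scale setting, logged not asserted: R=500, alpha0=0.05
  thr_m1 <- count_threshold_from_bonferroni(500, 0.05, 1)
  expect_true(thr_m1 >= 25 && thr_m1 <= 500)
})

test_that("F-test rejection counting matches per-gene nested fits", {
  ds <- small_dataset(seed = 64, n_per_group = 4, n_taxa = 10, n_genes = 6)
  md <- ds$metadata
  tp <- build_taxa_panel(ds$otu, md[md$cohort == "microbiome", ],
                         min_group_mean = 0)
  gp <- build_gene_panel(ds$expr)
  pr <- make_pairings(md, R = 10, seed = 11)
  rc <- count_ftest_rejections(gp, tp, pr, md, taxa_rule = list(type = "all"),
                               selection_threshold = 5, min_resid_df = 3)
  # oracle: taxa subset = most abundant (16 - 4 - 3 = 9 max, panel has 10)
  ord <- order(colMeans(tp$values), decreasing = TRUE)[1:9]
  counts <- integer(ncol(gp$values))
  for (p in pr$realizations) {
    mdp <- md[match(p$microbiome, md$sample_id), ]
    for (k in seq_len(ncol(gp$values))) {
      ft <- taxa_inclusion_ftest(gp$values[p$expression, k],
                                 tp$values[p$microbiome, ord], md,
                                 p$expression)
      counts[k] <- counts[k] + ft$rejected
    }
  }
  expect_equal(rc$table$count, counts)
  expect_identical(rc$table$selected, rc$table$tested & counts > 5)
  # boundary: selection_threshold = R -> none selected
  rcR <- count_ftest_rejections(gp, tp, pr, md, taxa_rule = list(type = "all"),
                                selection_threshold = pr$R)
  expect_false(any(rcR$table$selected))
  # candidate rule: genes without candidates are untested with count 0
  pc0 <- count_pair_significance(gp, tp, pr, md, count_threshold = pr$R)
  rc0 <- count_ftest_rejections(gp, tp, pr, md,
                                taxa_rule = list(type = "candidates",
                                                 pair_counts = pc0))
  expect_false(any(rc0$table$tested))
  expect_true(all(rc0$table$count == 0))
})

test_that("re-running with the same seed reproduces every count exactly", {
  ds <- small_dataset(seed = 65, n_per_group = 4, n_taxa = 12, n_genes = 15)
  md <- ds$metadata
  tp <- build_taxa_panel(ds$otu, md[md$cohort == "microbiome", ],
                         min_group_mean = 0)
  gp <- build_gene_panel(ds$expr)
  run <- function() {
    pr <- make_pairings(md, R = 30, seed = 17)
    pc <- count_pair_significance(gp, tp, pr, md, count_threshold = 10)
    rc <- count_ftest_rejections(gp, tp, pr, md, taxa_rule = list(type = "all"))
    list(pc = pc$counts, rc = rc$table$count)
  }
  a <- run(); b <- run()
  expect_identical(a$pc, b$pc)
  expect_identical(a$rc, b$rc)
})

test_that("heatmap rows are group means divided by the row mean", {
  md <- meta_2x2(2, cohort = "expression", prefix = "E")
  m <- matrix(0, 8, 2, dimnames = list(md$sample_id, c("g1", "g2")))
  m[, 1] <- rep(c(1, 2, 3, 2), each = 2)   # group means (1,2,3,2), mean 2
  m[, 2] <- 5                               # constant row
  hm <- heatmap_matrix(m, md)
  expect_equal(unname(hm["g1", c("water+RTF", "water+WTF",
                                 "alcohol+RTF", "alcohol+WTF")]),
               c(0.5, 1.0, 1.5, 1.0))
  expect_equal(unname(hm["g2", ]), rep(1, 4))
  expect_equal(unname(rowMeans(hm)), rep(1, 2))
  m[, 2] <- 0
  expect_warning(hm2 <- heatmap_matrix(m, md), "zero mean")
  expect_equal(rownames(hm2), "g1")
})
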