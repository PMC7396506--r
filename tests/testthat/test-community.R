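test_that("lineage exclusion removes archaea, mitochondria and chloroplasts", {
  tbl <- tiny_otu()
  out <- exclude_lineages(tbl)   # OTU3 archaea, OTU4 chloroplast+mitochondria
  expect_setequal(colnames(out$counts), c("OTU1", "OTU2"))
  # no matching lineages -> identity; empty rule list -> identity
  clean <- out
  expect_identical(exclude_lineages(clean)$counts, clean$counts)
  expect_identical(exclude_lineages(tbl, rules = list())$counts, tbl$counts)
})

test_that("rarefaction conserves depth exactly, drops shallow samples, is seeded", {
  set.seed(42)
  counts <- matrix(rpois(5 * 20, 10), 5, 20,
                   dimnames = list(paste0("S", 1:5), paste0("O", 1:20)))
  counts[5, ] <- 0L; counts[5, 1] <- 40L   # sample below depth
  storage.mode(counts) <- "integer"
  tax <- data.frame(otu_id = paste0("O", 1:20),
                    lineage = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__X;s__")
  tbl <- otu_table(counts, tax)
  expect_warning(r1 <- rarefy(tbl, 45, seed = 7), "S5")
  expect_equal(unname(rowSums(r1$counts)), rep(45, 4))
  expect_true(all(r1$counts <= tbl$counts[1:4, ]))  # without replacement
  expect_warning(r2 <- rarefy(tbl, 45, seed = 7), "S5")
  expect_identical(r1$counts, r2$counts)
  expect_error(rarefy(tbl, 1e6), "below the rarefaction depth")
})

test_that("rare-OTU filter applies the strict 'fewer than' rule", {
  counts <- matrix(c(1L, 1L, 2L,   # total 4: removed
                     1L, 1L, 3L,   # total 5: kept
                     0L, 0L, 0L), ncol = 3,
                   dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  tax <- data.frame(otu_id = c("A", "B", "C"), lineage = "k__B")
  tbl <- otu_table(counts, tax)
  out <- filter_rare_otus(tbl, min_total = 5)
  expect_identical(colnames(out$counts), "B")
  expect_identical(filter_rare_otus(tbl, min_total = 0)$counts, tbl$counts)
  expect_warning(filter_rare_otus(tbl, min_total = 100), "every OTU")
})

test_that("alpha diversity matches closed forms", {
  counts <- rbind(S1 = c(10L, 10L, 10L, 10L),
                  S2 = c(3L, 1L, 0L, 0L),
                  S3 = c(7L, 0L, 0L, 0L))
  colnames(counts) <- paste0("O", 1:4)
  tbl <- otu_table(counts, data.frame(otu_id = paste0("O", 1:4), lineage = "k__B"))
  div <- alpha_diversity(tbl)
  expect_equal(div$inv_simpson, c(4, 1.6, 1))   # uniform; 1/(0.75^2+0.25^2); single
  expect_equal(div$richness, c(4L, 2L, 1L))
  counts[3, ] <- 0L
  expect_error(alpha_diversity(otu_table(counts,
    data.frame(otu_id = paste0("O", 1:4), lineage = "k__B"))), "S3")
})

test_that("diversity regression matches the normal-equations oracle", {
  md <- meta_2x2(2)
  set.seed(1)
  y <- 3 + 2 * md$X1 - md$X2 + 5 * md$X1 * md$X2 + rnorm(8, 0, 0.3)
  dr <- diversity_regression(data.frame(sample_id = md$sample_id,
                                        richness = y), md)
  orc <- oracle_ols(design_2x2(md$X1, md$X2), y)
  expect_equal(dr$coefficients$estimate, orc$coef, tolerance = 1e-10)
  expect_equal(dr$coefficients$p, orc$p, tolerance = 1e-10)
})

test_that("an interaction-only metric is dominated by the interaction term", {
  md <- meta_2x2(3)
  set.seed(2)
  y <- md$X1 * md$X2 + rnorm(12, 0, 1e-3)
  dr <- diversity_regression(data.frame(sample_id = md$sample_id,
                                        richness = y), md)
  expect_gt(dr$r_squared, 0.999)
  pint <- dr$coefficients$p[dr$coefficients$term == "X1:X2"]
  expect_lt(pint, 1e-10)
  # constant metric: slopes zero, p-values 1 (flagged, not NaN)
  dr0 <- diversity_regression(data.frame(sample_id = md$sample_id,
                                         richness = rep(5, 12)), md)
  expect_equal(dr0$coefficients$p[-1], rep(1, 3))
})

test_that("Bray-Curtis matches hand values and is a valid dissimilarity", {
  m <- rbind(a = c(6, 2), b = c(2, 2), c = c(0, 5))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1 / 3)              # 1 - 8/12
  expect_equal(d["a", "a"], 0)
  expect_equal(bray_curtis(rbind(x = c(1, 0), y = c(0, 9)))["x", "y"], 1)
  # property sweep on random fixtures, checked against the oracle
  set.seed(10)
  for (i in 1:200) {
    mm <- matrix(rpois(4 * 6, 4), 4, 6,
                 dimnames = list(paste0("s", 1:4), NULL))
    mm[1, ] <- mm[1, ] + 1L  # avoid zero-total rows
    mm[cbind(2:4, 1)] <- mm[cbind(2:4, 1)] + 1L
    dd <- bray_curtis(mm)
    expect_identical(dd, t(dd))
    expect_true(all(diag(dd) == 0) && all(dd >= 0 & dd <= 1))
    expect_equal(dd[1, 2], oracle_bray(mm[1, ], mm[2, ]))
  }
})

test_that("PERMANOVA p equals the exhaustive relabeling oracle for n <= 7", {
  set.seed(20)
  fixtures <- list(c(3, 3), c(3, 4), c(2, 4), c(2, 5))
  for (sizes in fixtures) {
    n <- sum(sizes)
    m <- matrix(rpois(n * 8, 6), n, 8,
                dimnames = list(paste0("s", 1:n), NULL)) + 1
    labels <- rep(c("g1", "g2"), sizes)
    md <- data.frame(sample_id = paste0("s", 1:n), group = labels,
                     stringsAsFactors = FALSE)
    d <- bray_curtis(m)
    res <- permanova(d, md, formula_terms = "group",
                     permutations = "exhaustive")
    orc <- oracle_permanova_exhaustive(d, labels)
    expect_equal(res$table$F[1], orc$f, tolerance = 1e-10)
    expect_equal(res$table$p[1], orc$p, tolerance = 1e-12)
    expect_equal(res$nperm, orc$n_relabel)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 and hits the minimal p", {
  skip_if_not_installed("vegan")
  ds <- small_dataset(seed = 21, n_per_group = 5, n_taxa = 20, n_genes = 5)
  mb <- ds$metadata[ds$metadata$cohort == "microbiome", ]
  d <- bray_curtis(ds$otu)
  res <- permanova(d, mb, nperm = 199, seed = 1)
  df <- data.frame(X1 = mb$X1, X2 = mb$X2)
  veg <- vegan::adonis2(as.dist(d) ~ X1 * X2, data = df, permutations = 199,
                        by = "terms")
  expect_equal(res$table$SS[1:4], veg$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(res$table$F[1:3], veg$F[1:3], tolerance = 1e-8)
  # clearly separated groups reach the minimal attainable p; groups of 10
  # so that partition-preserving permutations (which tie with F_obs) are
  # vanishingly rare among random draws
  set.seed(99)
  m <- rbind(cbind(50L + rpois(10, 3), rpois(10, 1)),
             cbind(rpois(10, 1), 50L + rpois(10, 3)))
  rownames(m) <- paste0("s", 1:20)
  md <- data.frame(sample_id = rownames(m),
                   group = rep(c("a", "b"), each = 10))
  sep <- permanova(bray_curtis(m), md, formula_terms = "group",
                   nperm = 999, seed = 2)
  expect_equal(sep$table$p[1], 1 / 1000)
  expect_error(permanova(bray_curtis(m),
    data.frame(sample_id = rownames(m), group = "a"),
    formula_terms = "group"), "constant")
})

test_that("shuffled labels give approximately uniform PERMANOVA p", {
  ds <- small_dataset(seed = 22, n_per_group = 5, n_taxa = 15, n_genes = 5)
  mb <- ds$metadata[ds$metadata$cohort == "microbiome", ]
  d <- bray_curtis(ds$otu)
  set.seed(30)
  ps <- vapply(1:40, function(i) {
    md <- mb; md$group <- sample(md$group)
    permanova(d, md, formula_terms = "group", nperm = 99, seed = i)$table$p[1]
  }, numeric(1))
  expect_gt(mean(ps), 0.3); expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps < 0.2), 0.05); expect_lt(mean(ps < 0.2), 0.45)
})

test_that("pairwise PERMANOVA reports all six pairs consistently", {
  ds <- small_dataset(seed = 23, n_per_group = 3, n_taxa = 15, n_genes = 5)
  mb <- ds$metadata[ds$metadata$cohort == "microbiome", ]
  d <- bray_curtis(ds$otu)
  pw <- pairwise_permanova(d, mb, nperm = 99, seed = 5)
  expect_equal(nrow(pw), 6)
  # one pair's sub-call equals a direct call on the subset with the same seed
  sel <- mb$group %in% c(pw$group1[1], pw$group2[1])
  direct <- permanova(d[sel, sel], mb[sel, ], formula_terms = "group",
                      nperm = 99, seed = 5)
  expect_equal(pw$p[1], direct$table$p[1])
  expect_equal(pw$R2[1], direct$table$R2[1])
})

test_that("clr transform matches hand oracle and rows sum to zero", {
  expect_equal(unname(clr_transform(rbind(s = c(1, 1, 1, 1)))[1, ]),
               rep(0, 4))
  # (0,1,3): delta = 0.5/4; p = (1/8, (1/4)(7/8), (3/4)(7/8))
  p <- c(0.125, 0.25 * 0.875, 0.75 * 0.875)
  hand <- log(p) - mean(log(p))
  got <- clr_transform(rbind(s = c(0, 1, 3)))[1, ]
  expect_equal(unname(got), hand)
  set.seed(31)
  m <- matrix(rpois(10 * 8, 3), 10, 8, dimnames = list(paste0("s", 1:10), NULL))
  m[, 1] <- m[, 1] + 1L
  expect_true(all(abs(rowSums(clr_transform(m))) < 1e-9))
})

test_that("taxon collapse sums member OTUs before the transform", {
  tbl <- tiny_otu()
  ph <- collapse_taxa(tbl, "phylum")
  expect_equal(ncol(ph), 4)  # Firmicutes, Bacteroidetes, Euryarchaeota, Proteo
  firm <- ph[, grep("Firmicutes", colnames(ph))]
  expect_equal(unname(firm), unname(tbl$counts[, "OTU1"]))
})

test_that("BH q-values match the hand example and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("taxon regressions recover a planted genus effect with smallest q", {
  d <- synthetic_design(n_per_group = 10, n_taxa = 20, n_genes = 5, seed = 41,
                        library_size_taxa = 20000, library_size_genes = 1e4)
  te <- matrix(0, 20, 3); te[1, 1] <- 3   # strong X1 effect on taxon 1
  ds <- generate_dataset(d, synthetic_truth(20, 5, taxa_effects = te))
  mb <- ds$metadata[ds$metadata$cohort == "microbiome", ]
  tr <- taxon_regressions(ds$otu, mb, level = "genus")
  x1 <- tr[tr$term == "X1", ]
  expect_equal(x1$taxon[which.min(x1$q)], grep("g__Genus_0001", x1$taxon, value = TRUE))
  expect_true(all(tr$q >= tr$p - 1e-15))
  expect_true(all(tr$ci_lo <= tr$estimate & tr$estimate <= tr$ci_hi))
})

test_that("Firmicutes/Bacteroidetes ratio handles the boundary cases", {
  counts <- rbind(S1 = c(60L, 30L), S2 = c(0L, 10L), S3 = c(5L, 0L))
  colnames(counts) <- c("F1", "B1")
  tax <- data.frame(otu_id = c("F1", "B1"),
                    lineage = c("k__Bacteria;p__Firmicutes;c__;o__;f__;g__;s__",
                                "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__;s__"))
  tbl <- otu_table(counts, tax)
  expect_warning(fb <- fb_ratio(tbl), "S3")
  expect_equal(fb$ratio, c(2, 0, Inf))
})
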