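#' Exclude OTUs by taxonomic lineage rules
#'
#' The default rules drop archaea (kingdom), mitochondria (family) and
#' chloroplasts (class) — non-bacterial or host-derived 16S signal that
#' standard amplicon pipelines remove before community analysis. Matching
#' is case-insensitive on the parsed rank value.
#'
#' @param table an [otu_table()].
#' @param rules list of `list(rank = , value = )` entries; an OTU matching
#'   ANY rule is removed. Empty list leaves the table unchanged.
#' @return filtered [otu_table()].
#' @export
exclude_lineages <- function(table,
                             rules = list(
                               list(rank = "kingdom", value = "Archaea"),
                               list(rank = "family", value = "Mitochondria"),
                               list(rank = "class", value = "Chloroplast"))) {
  if (length(rules) == 0) return(table)
  drop <- rep(FALSE, ncol(table$counts))
  for (r in rules) {
    rv <- tolower(table$taxonomy[[r$rank]])
    drop <- drop | (!is.na(rv) & rv == tolower(r$value))
  }
  if (all(drop)) warning("exclude_lineages removed every OTU")
  subset_otus(table, !drop)
}

subset_otus <- function(table, keep) {
  structure(list(counts = table$counts[, keep, drop = FALSE],
                 taxonomy = table$taxonomy[keep, , drop = FALSE]),
            class = "otu_table")
}

#' Rarefy samples to a common depth by subsampling without replacement
#'
#' Each retained sample's reads are subsampled to exactly `depth` without
#' replacement (multivariate hypergeometric); samples with fewer total
#' reads than `depth` are dropped with a warning.
#'
#' @param table an [otu_table()].
#' @param depth target depth (paper-scale default 43,000 lives in the
#'   pipeline config; here it must be given).
#' @param seed integer seed; same seed gives an identical table.
#' @return rarefied [otu_table()].
#' @export
rarefy <- function(table, depth, seed = 1) {
  stopifnot(depth >= 1)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  if (any(!keep))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(rownames(table$counts)[!keep], collapse = ", "))
  set.seed(seed)
  m <- table$counts[keep, , drop = FALSE]
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(nrow(m))) {
    reads <- rep.int(seq_len(ncol(m)), m[j, ])
    picked <- sample(reads, depth, replace = FALSE)
    tb <- tabulate(picked, nbins = ncol(m))
    out[j, ] <- tb
  }
  structure(list(counts = out, taxonomy = table$taxonomy), class = "otu_table")
}

#' Remove OTUs rarer than a grand-total threshold
#'
#' Drops OTUs whose total count across the entire dataset is below
#' `min_total` (default 5: OTUs with fewer than five reads overall).
#'
#' @param table an [otu_table()].
#' @param min_total minimum grand total to retain an OTU.
#' @return filtered [otu_table()].
#' @export
filter_rare_otus <- function(table, min_total = 5) {
  keep <- colSums(table$counts) >= min_total
  if (!any(keep)) warning("filter_rare_otus removed every OTU")
  subset_otus(table, keep)
}

#' Per-sample alpha diversity: richness and inverse Simpson
#'
#' Richness is the number of OTUs with a non-zero count. Inverse Simpson is
#' `1 / sum(p_i^2)` with `p_i` the sample's relative abundances — the
#' effective number of equally-abundant taxa (1 for a single-taxon sample,
#' S for a uniform S-taxon community).
#'
#' @param table an [otu_table()].
#' @return data.frame with columns `sample_id`, `richness`, `inv_simpson`.
#' @export
alpha_diversity <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "))
  p <- table$counts / totals
  data.frame(sample_id = rownames(table$counts),
             richness = as.integer(rowSums(table$counts > 0)),
             inv_simpson = 1 / rowSums(p^2),
             stringsAsFactors = FALSE)
}

#' Regress a diversity metric on the two treatment factors and their
#' interaction
#'
#' Ordinary least squares of `metric ~ X1 * X2` with the usual ANOVA table
#' (type II sums of squares) and all-pairs post-hoc group comparisons
#' (Tukey HSD by default).
#'
#' @param metrics data.frame with `sample_id` and one metric column.
#' @param metadata [sample_metadata()] covering every metric sample.
#' @param metric name of the metric column.
#' @param posthoc_adjust `"tukey"` or a [stats::p.adjust()] method for
#'   pairwise t-tests.
#' @return list with `coefficients` (estimate, se, t, p per term),
#'   `r_squared`, `anova` and `posthoc` data.frames.
#' @export
diversity_regression <- function(metrics, metadata, metric = "richness",
                                 posthoc_adjust = "tukey") {
  check_metadata_join(metrics$sample_id, metadata)
  md <- metadata[match(metrics$sample_id, metadata$sample_id), ]
  if (length(unique(md$group)) < 4 || any(table(md$group) < 2))
    stop("need >= 2 samples in each of the four groups")
  y <- metrics[[metric]]
  X <- design_2x2(md$X1, md$X2)
  fit <- ols_multi(X, matrix(y, ncol = 1))
  r2 <- if (stats::var(y) == 0) NA_real_ else
    1 - fit$rss[1] / sum((y - mean(y))^2)
  coefs <- data.frame(term = colnames(X), estimate = fit$coef[, 1],
                      se = fit$se[, 1], t = fit$t[, 1], p = fit$p[, 1],
                      stringsAsFactors = FALSE)
  if (stats::var(y) == 0) {
    # degenerate response: slopes are exactly zero, flag p = 1
    coefs$p[-1] <- 1
    coefs$t[-1] <- 0
  }
  an <- anova_2x2(y, md$X1, md$X2)
  grp <- factor(md$group)
  posthoc <- if (identical(posthoc_adjust, "tukey")) {
    th <- stats::TukeyHSD(stats::aov(y ~ grp))$grp
    data.frame(pair = rownames(th), diff = th[, "diff"],
               p = th[, "p adj"], row.names = NULL, stringsAsFactors = FALSE)
  } else {
    pt <- stats::pairwise.t.test(y, grp, p.adjust.method = posthoc_adjust)$p.value
    idx <- which(!is.na(pt), arr.ind = TRUE)
    data.frame(pair = paste(rownames(pt)[idx[, 1]], colnames(pt)[idx[, 2]],
                            sep = "-"),
               diff = NA_real_, p = pt[idx], stringsAsFactors = FALSE)
  }
  list(metric = metric, coefficients = coefs, r_squared = r2,
       anova = an, posthoc = posthoc)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y)`: 0 for identical
#' samples, 1 for samples sharing no taxa.
#'
#' @param table an [otu_table()] or a samples x taxa numeric matrix.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  n <- nrow(m)
  tot <- rowSums(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(m[i, ], m[j, ])) / (tot[i] + tot[j])
    }
  }
  d
}

# Gower-centered inner-product matrix of a distance matrix
gower_center <- function(d) {
  a <- -0.5 * d^2
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

# build design columns for PERMANOVA terms from metadata
permanova_term_matrix <- function(md, term) {
  if (term == "X1:X2") return(matrix(md$X1 * md$X2, ncol = 1))
  v <- md[[term]]
  if (is.null(v)) stop("unknown term: ", term)
  if (is.character(v) || is.factor(v)) {
    f <- factor(v)
    if (nlevels(f) < 2) stop("constant grouping in term '", term, "'")
    stats::model.matrix(~f)[, -1, drop = FALSE]
  } else matrix(as.numeric(v), ncol = 1)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a dissimilarity matrix by sequentially-added model terms
#' (Anderson's method, as in `vegan::adonis2` with `by = "terms"`). The
#' pseudo-F null distribution comes from permuting sample labels; the
#' p-value is `(1 + #perm F >= F_obs) / (1 + nperm)`. For a single
#' two-level factor `permutations = "exhaustive"` enumerates every distinct
#' relabeling and reports the exact proportion with `F >= F_obs`
#' (including the observed labeling).
#'
#' @param dist square symmetric dissimilarity matrix with sample names.
#' @param metadata [sample_metadata()] (or data.frame with the term
#'   columns) covering all samples in `dist`.
#' @param formula_terms character vector of term names added in order;
#'   `"X1:X2"` denotes the interaction, any other name indexes a metadata
#'   column (factors are expanded to dummies).
#' @param nperm number of random permutations (default 9,999).
#' @param seed permutation seed.
#' @param permutations `"random"` or `"exhaustive"` (single two-level
#'   factor only).
#' @return list of class `permanova` with the partition table (`df`, `SS`,
#'   `R2`, `F`, `p`), `nperm` and `seed`.
#' @export
permanova <- function(dist, metadata, formula_terms = c("X1", "X2", "X1:X2"),
                      nperm = 9999, seed = 1,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stop("dist must be symmetric")
  ids <- rownames(dist)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples in dist")
  G <- gower_center(dist)
  ss_total <- sum(diag(G))

  term_mats <- lapply(formula_terms, function(tm) permanova_term_matrix(md, tm))
  # cumulative hat matrices (intercept implicit via Gower centering)
  hats <- list(); X <- matrix(1, n, 1)
  for (i in seq_along(term_mats)) {
    X <- cbind(X, term_mats[[i]])
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[i]] <- tcrossprod(Q)
  }
  df_cum <- vapply(seq_along(hats), function(i) qr(cbind(matrix(1, n, 1),
    do.call(cbind, term_mats[seq_len(i)])))$rank - 1L, integer(1))
  df_term <- diff(c(0L, df_cum))
  if (any(df_term == 0)) stop("constant/aliased term in formula_terms")

  explained <- function(Gm) {
    cum <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    diff(c(0, cum))
  }
  ss_term <- pmax(explained(G), 0)
  ss_res <- max(ss_total - sum(ss_term), 0)
  df_res <- n - 1L - sum(df_term)
  if (df_res < 1) stop("no residual degrees of freedom")
  f_obs <- (ss_term / df_term) / (ss_res / df_res)

  fstat_perm <- function(perm) {
    Gp <- G[perm, perm]
    st <- pmax(explained(Gp), 0)
    sr <- max(sum(diag(Gp)) - sum(st), 0)
    (st / df_term) / (sr / df_res)
  }

  if (permutations == "exhaustive") {
    if (length(term_mats) != 1 || ncol(term_mats[[1]]) != 1)
      stop("exhaustive permutations support a single two-level factor only")
    v <- term_mats[[1]][, 1]
    lev <- sort(unique(v))
    if (length(lev) != 2) stop("exhaustive permutations need a two-level factor")
    n1 <- sum(v == lev[1])
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(idx) {
      perm <- c(idx, setdiff(seq_len(n), idx))
      # build permutation mapping positions of group-1 labels to idx
      lab <- rep(lev[2], n); lab[idx] <- lev[1]
      Xp <- cbind(1, as.numeric(lab == lev[2]))
      qx <- qr(Xp); Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
      st <- max(sum(tcrossprod(Q) * G), 0)
      (st / df_term) / (max(ss_total - st, 0) / df_res)
    })
    p <- sum(fs >= f_obs - 1e-12) / length(fs)
    nperm_eff <- length(fs)
  } else {
    set.seed(seed)
    count <- rep(0L, length(f_obs))
    for (b in seq_len(nperm)) {
      fp <- fstat_perm(sample.int(n))
      count <- count + (fp >= f_obs - 1e-12)
    }
    p <- (1 + count) / (1 + nperm)
    nperm_eff <- nperm
  }

  tab <- data.frame(term = c(formula_terms, "Residual", "Total"),
                    df = c(df_term, df_res, n - 1L),
                    SS = c(ss_term, ss_res, ss_total),
                    R2 = c(ss_term, ss_res, ss_total) / ss_total,
                    F = c(f_obs, NA, NA),
                    p = c(p, NA, NA), stringsAsFactors = FALSE)
  structure(list(table = tab, nperm = nperm_eff, seed = seed,
                 permutations = permutations),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$permutations, " permutations: ", x$nperm, ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Pairwise post-hoc PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of each pair of groups with a
#' single group factor. P-value adjustment defaults to `"none"` (raw
#' pairwise p-values).
#'
#' @param dist dissimilarity matrix.
#' @param metadata [sample_metadata()] with a `group` column.
#' @param nperm permutations per pair.
#' @param seed permutation seed (same for every pair sub-call).
#' @param p_adjust [stats::p.adjust()] method, default `"none"`.
#' @return data.frame with one row per group pair: `R2`, `F`, `p`,
#'   `p_adj`.
#' @export
pairwise_permanova <- function(dist, metadata, nperm = 9999, seed = 1,
                               p_adjust = "none") {
  dist <- as.matrix(dist)
  md <- metadata[match(rownames(dist), metadata$sample_id), , drop = FALSE]
  groups <- unique(md$group)
  pairs <- utils::combn(groups, 2)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- md$group %in% c(g1, g2)
    if (sum(md$group == g1) < 2 || sum(md$group == g2) < 2) {
      warning("skipping pair ", g1, " vs ", g2, ": a group has < 2 samples")
      next
    }
    res <- permanova(dist[sel, sel, drop = FALSE], md[sel, , drop = FALSE],
                     formula_terms = "group", nperm = nperm, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      group1 = g1, group2 = g2,
      R2 = res$table$R2[1], F = res$table$F[1], p = res$table$p[1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Centered log-ratio transform with multiplicative zero replacement
#'
#' Each sample's counts are closed to proportions; zeros are replaced by
#' the pseudo-proportion `delta = 0.5 / sample_total` (half a count) and
#' the non-zero proportions rescaled by `1 - n_zeros * delta` so the
#' composition still sums to one; then `clr(x)_i = log x_i - mean_j log
#' x_j`, so every transformed row sums to zero.
#'
#' @param table an [otu_table()] or samples x taxa count matrix.
#' @param zero_strategy only `"multiplicative"` is implemented.
#' @return real-valued samples x taxa matrix.
#' @export
clr_transform <- function(table, zero_strategy = "multiplicative") {
  stopifnot(zero_strategy == "multiplicative")
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero-total sample(s) cannot be transformed")
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(nrow(m))) {
    p <- m[j, ] / tot[j]
    z <- p == 0
    if (any(z)) {
      delta <- 0.5 / tot[j]
      p[z] <- delta
      p[!z] <- p[!z] * (1 - sum(z) * delta)
    }
    lp <- log(p)
    out[j, ] <- lp - mean(lp)
  }
  out
}

#' Collapse an OTU table to a taxonomic level
#'
#' Member OTU counts are summed within each distinct lineage truncated at
#' `level`. OTUs unannotated at `level` collapse into their truncated
#' lineage (e.g. a shared `g__` bucket within the same family).
#'
#' @param table an [otu_table()].
#' @param level one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @return samples x taxa count matrix with truncated-lineage column names.
#' @export
collapse_taxa <- function(table, level = "genus") {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  stopifnot(level %in% ranks)
  upto <- seq_len(match(level, ranks))
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")[upto]
  lab <- apply(table$taxonomy[, ranks[upto], drop = FALSE], 1,
               function(r) paste0(prefixes, r, collapse = ";"))
  groups <- factor(lab, levels = unique(lab))
  out <- t(rowsum(t(table$counts), groups))
  rownames(out) <- rownames(table$counts)
  out
}

#' Per-taxon CLR regressions on the 2x2 design at a taxonomic level
#'
#' OTUs are collapsed to `level` (raw counts summed), the collapsed table
#' is CLR-transformed, and each taxon's transformed abundance is regressed
#' on X1, X2 and their interaction by OLS. 95% confidence intervals use the
#' t distribution; Benjamini-Hochberg q-values are computed across taxa
#' within the level, separately per term.
#'
#' @param table an [otu_table()].
#' @param metadata [sample_metadata()].
#' @param level taxonomic level.
#' @param conf_level CI coverage.
#' @return data.frame of class `taxon_regressions`: one row per taxon and
#'   term with `estimate`, `ci_lo`, `ci_hi`, `p`, `q`.
#' @export
taxon_regressions <- function(table, metadata, level = "genus",
                              conf_level = 0.95) {
  collapsed <- collapse_taxa(table, level)
  clr <- clr_transform(collapsed)
  md <- metadata[match(rownames(clr), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  X <- design_2x2(md$X1, md$X2)
  if (nrow(X) <= ncol(X)) stop("fewer samples than model parameters")
  fit <- ols_multi(X, clr)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df)
  terms <- c("X1", "X2", "X1:X2")
  rows <- lapply(seq_along(terms), function(i) {
    r <- i + 1  # skip intercept row
    data.frame(taxon = colnames(clr), level = level, term = terms[i],
               estimate = fit$coef[r, ], se = fit$se[r, ],
               ci_lo = fit$coef[r, ] - tcrit * fit$se[r, ],
               ci_hi = fit$coef[r, ] + tcrit * fit$se[r, ],
               p = fit$p[r, ], q = bh_adjust(fit$p[r, ]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("taxon_regressions", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values (FDR q-values)
#' @param p numeric vector of p-values (NA allowed, passed through).
#' @return q-values, `q >= p` elementwise, monotone in the BH ordering.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Firmicutes-to-Bacteroidetes ratio per sample
#'
#' @param table an [otu_table()] with phylum annotations.
#' @return data.frame `sample_id`, `firmicutes`, `bacteroidetes`, `ratio`
#'   (`Inf` flagged with a warning when Bacteroidetes is absent).
#' @export
fb_ratio <- function(table) {
  ph <- tolower(table$taxonomy$phylum)
  if (all(ph == "")) stop("phylum annotations are required")
  f <- rowSums(table$counts[, ph == "firmicutes", drop = FALSE])
  b <- rowSums(table$counts[, ph == "bacteroidetes", drop = FALSE])
  ratio <- f / b
  if (any(b == 0))
    warning("sample(s) with zero Bacteroidetes reads: ratio flagged infinite: ",
            paste(rownames(table$counts)[b == 0], collapse = ", "))
  data.frame(sample_id = rownames(table$counts), firmicutes = f,
             bacteroidetes = b, ratio = ratio, row.names = NULL,
             stringsAsFactors = FALSE)
}
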