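# Cross-cohort correspondence: the microbiome and expression cohorts share
# the treatment design but not the animals, so gene-taxon association is
# probed through many random within-group sample pairings, and only
# associations stable across pairings (by an exact-binomial count
# threshold) are kept.

#' Build the abundant-taxa panel for correspondence analysis
#'
#' Collapses the OTU table to a taxonomic level, retains taxa whose mean
#' raw count exceeds `min_group_mean` in EVERY one of the four treatment
#' groups, and converts counts to per-sample percentages. Percentages are
#' computed on the full pre-filter taxa basis (each sample's collapsed
#' total), so the retained panel's percentages need not sum to 100.
#'
#' @param table an [otu_table()] (microbiome cohort, preprocessed).
#' @param metadata [sample_metadata()].
#' @param level taxonomic level for collapsing (default genus).
#' @param min_group_mean abundance filter: group mean count must exceed
#'   this value in all four groups (default 10).
#' @return object of class `abundant_taxa_panel`: `values` (samples x taxa
#'   percent matrix), `taxa`, `n_before`/`n_after`, `provenance`.
#' @export
build_taxa_panel <- function(table, metadata, level = "genus",
                             min_group_mean = 10) {
  collapsed <- collapse_taxa(table, level)
  md <- metadata[match(rownames(collapsed), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  grp <- factor(md$group)
  if (nlevels(grp) != 4) stop("all four treatment groups must be present")
  group_means <- rowsum(collapsed, grp) / as.vector(table(grp))
  keep <- apply(group_means > min_group_mean, 2, all)
  if (!any(keep)) stop("no taxon passes the abundance filter")
  pct <- collapsed / rowSums(collapsed) * 100
  structure(list(values = pct[, keep, drop = FALSE],
                 taxa = colnames(collapsed)[keep],
                 n_before = ncol(collapsed), n_after = sum(keep),
                 provenance = list(level = level,
                                   min_group_mean = min_group_mean)),
            class = "abundant_taxa_panel")
}

#' @export
print.abundant_taxa_panel <- function(x, ...) {
  cat(sprintf("abundant_taxa_panel: %d -> %d taxa at %s level (group mean > %g)\n",
              x$n_before, x$n_after, x$provenance$level,
              x$provenance$min_group_mean))
  invisible(x)
}

#' Build the filtered, standardized gene panel
#'
#' Removes genes with more than `max_zeros` zero records (default 1: a
#' gene may have at most one zero), then z-standardizes each retained gene
#' across the expression samples. Zero-variance genes are dropped with a
#' warning.
#'
#' @param matrix an [expression_matrix()] with raw values.
#' @param max_zeros maximum number of zero records a gene may have.
#' @return object of class `filtered_gene_panel`: `values` (samples x
#'   genes standardized), `raw` (same subset, untransformed), `genes`,
#'   `n_before`/`n_after`.
#' @export
build_gene_panel <- function(matrix, max_zeros = 1) {
  m <- if (inherits(matrix, "expression_matrix")) matrix$values else as.matrix(matrix)
  nz <- colSums(m == 0)
  keep <- nz <= max_zeros
  m2 <- m[, keep, drop = FALSE]
  sds <- apply(m2, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(colnames(m2)[sds == 0], collapse = ", "))
    m2 <- m2[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(m2)
  structure(list(values = z, raw = m2, genes = colnames(m2),
                 n_before = ncol(m), n_after = ncol(m2),
                 max_zeros = max_zeros),
            class = "filtered_gene_panel")
}

#' @export
print.filtered_gene_panel <- function(x, ...) {
  cat(sprintf("filtered_gene_panel: %d -> %d genes (<= %d zeros), standardized\n",
              x$n_before, x$n_after, x$max_zeros))
  invisible(x)
}

#' Draw random within-group pairings between the two cohorts
#'
#' Each realization is a uniform-random one-to-one matching of microbiome
#' to expression samples within every treatment group. When the cohorts'
#' group sizes differ, min(size) pairs are formed, sampling the larger
#' side without replacement anew in each realization.
#'
#' @param metadata [sample_metadata()] holding both cohorts.
#' @param R number of realizations (default 500).
#' @param seed master seed; the whole sequence is reproducible from it.
#' @return object of class `pairing_set`: list `realizations` of
#'   data.frames (`microbiome`, `expression`, `group`), plus `R`, `seed`.
#' @export
make_pairings <- function(metadata, R = 500, seed = 1) {
  mb <- metadata[metadata$cohort == "microbiome", ]
  ex <- metadata[metadata$cohort == "expression", ]
  g_mb <- split(mb$sample_id, mb$group)
  g_ex <- split(ex$sample_id, ex$group)
  only <- c(setdiff(names(g_mb), names(g_ex)), setdiff(names(g_ex), names(g_mb)))
  if (length(only) > 0)
    stop("group(s) present in one cohort only: ", paste(only, collapse = ", "))
  groups <- names(g_mb)
  set.seed(seed)
  realizations <- vector("list", R)
  for (r in seq_len(R)) {
    parts <- lapply(groups, function(g) {
      n_pair <- min(length(g_mb[[g]]), length(g_ex[[g]]))
      mb_sel <- if (length(g_mb[[g]]) == 1) g_mb[[g]] else
        sample(g_mb[[g]], n_pair)
      ex_sel <- if (length(g_ex[[g]]) == 1) g_ex[[g]] else
        sample(g_ex[[g]], n_pair)
      data.frame(microbiome = mb_sel, expression = ex_sel, group = g,
                 stringsAsFactors = FALSE)
    })
    realizations[[r]] <- do.call(rbind, parts)
  }
  structure(list(realizations = realizations, R = R, seed = seed),
            class = "pairing_set")
}

# per-realization row indices of panels (microbiome rows, expression rows)
pairing_indices <- function(pairing, taxa_panel, gene_panel, metadata) {
  mi <- match(pairing$microbiome, rownames(taxa_panel$values))
  ei <- match(pairing$expression, rownames(gene_panel$values))
  if (anyNA(mi) || anyNA(ei))
    stop("pairing references samples absent from a panel")
  md <- metadata[match(pairing$microbiome, metadata$sample_id), ]
  list(mi = mi, ei = ei, X1 = md$X1, X2 = md$X2)
}

#' Count per-(gene, taxon) significant associations across pairings
#'
#' For each pairing realization, each standardized gene is regressed on
#' each panel taxon's percent abundance (simple OLS; the slope t-test is
#' equivalent to the Pearson correlation test) and significance at
#' `alpha0` is recorded; counts accumulate over realizations. A pair is a
#' candidate when its count exceeds `count_threshold` (see
#' [count_threshold_from_bonferroni()]). With `adjust_for_treatment =
#' TRUE` both variables are residualized on the 2x2 design first (partial
#' correlation; 3 extra degrees of freedom are spent).
#'
#' @param gene_panel a [build_gene_panel()] result.
#' @param taxa_panel a [build_taxa_panel()] result.
#' @param pairings a [make_pairings()] result.
#' @param metadata [sample_metadata()].
#' @param alpha0 per-pair significance level (default 0.05).
#' @param count_threshold candidate count threshold (default 53: the
#'   "more than 53 out of 500" rule).
#' @param adjust_for_treatment adjust the per-pair test for the design.
#' @return object of class `pair_count_table`: `counts` (genes x taxa
#'   integer matrix), `candidate` (logical matrix, count > threshold),
#'   `R`, `alpha0`, `count_threshold`.
#' @export
count_pair_significance <- function(gene_panel, taxa_panel, pairings,
                                    metadata, alpha0 = 0.05,
                                    count_threshold = 53,
                                    adjust_for_treatment = FALSE) {
  G <- gene_panel$values; Tm <- taxa_panel$values
  counts <- matrix(0L, ncol(G), ncol(Tm),
                   dimnames = list(colnames(G), colnames(Tm)))
  for (pairing in pairings$realizations) {
    idx <- pairing_indices(pairing, taxa_panel, gene_panel, metadata)
    n <- length(idx$mi)
    if (n < 4) stop("fewer than 4 paired samples")
    g <- G[idx$ei, , drop = FALSE]
    t_ <- Tm[idx$mi, , drop = FALSE]
    if (adjust_for_treatment) {
      D <- design_2x2(idx$X1, idx$X2)
      qd <- qr(D)
      g <- qr.resid(qd, g)
      t_ <- qr.resid(qd, t_)
      df <- n - 2L - (qd$rank - 1L)
    } else {
      df <- n - 2L
    }
    gs <- scale(g); ts <- scale(t_)
    gs[, attr(gs, "scaled:scale") == 0] <- 0
    ts[, attr(ts, "scaled:scale") == 0] <- 0
    r <- crossprod(gs, ts) / (n - 1)
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df)
    counts <- counts + (p < alpha0 & is.finite(p))
  }
  structure(list(counts = counts, candidate = counts > count_threshold,
                 R = pairings$R, alpha0 = alpha0,
                 count_threshold = count_threshold,
                 adjust_for_treatment = adjust_for_treatment),
            class = "pair_count_table")
}

#' Exact-binomial Bonferroni count threshold
#'
#' Under the null, a (gene, taxon) pair is significant in each of R
#' pairings with probability `alpha0`, so its count is at most
#' Binomial(R, alpha0)-distributed. The threshold is the smallest k with
#' `P(X >= k) <= alpha / m` (Bonferroni over m pairs); the function
#' returns `k - 1`, the value counts must strictly exceed.
#'
#' @param R number of pairing realizations.
#' @param alpha0 per-pair significance level.
#' @param m Bonferroni multiplicity (number of tests).
#' @param alpha family-wise error target.
#' @return integer threshold ("count > threshold" qualifies).
#' @export
count_threshold_from_bonferroni <- function(R, alpha0, m, alpha = 0.05) {
  stopifnot(R >= 1, alpha0 > 0, alpha0 < 1, m >= 1, alpha > 0)
  if (alpha / m >= 1) return(0L)
  k <- 0:R
  tail <- stats::pbinom(k - 1, R, alpha0, lower.tail = FALSE)  # P(X >= k)
  ok <- which(tail <= alpha / m)
  if (length(ok) == 0)
    stop("no attainable count threshold: alpha/m below P(X = R)")
  as.integer(k[ok[1]] - 1L)
}

#' Count taxa-inclusion F-test rejections per gene across pairings
#'
#' For each pairing realization and each gene, tests whether adding a taxa
#' subset to the treatment model improves the fit
#' ([taxa_inclusion_ftest()]); rejections accumulate over realizations and
#' genes with count exceeding `selection_threshold` are selected.
#'
#' The taxa subset rule: `list(type = "all")` uses the whole panel for all
#' genes; `list(type = "candidates", pair_counts = <pair_count_table>)`
#' uses, per gene, that gene's candidate taxa from the counting step
#' (largest counts first). Either way the subset is truncated so the full
#' model keeps at least `min_resid_df` residual degrees of freedom —
#' necessary because a panel of ~34 taxa cannot be fit jointly on ~20
#' paired samples.
#'
#' @param gene_panel a [build_gene_panel()] result.
#' @param taxa_panel a [build_taxa_panel()] result.
#' @param pairings a [make_pairings()] result.
#' @param metadata [sample_metadata()].
#' @param alpha per-realization rejection level.
#' @param taxa_rule subset rule, see Details.
#' @param selection_threshold count needed (strictly exceeded) for gene
#'   selection (default 40: the "more than 40 out of 500" rule).
#' @param min_resid_df minimum residual df of the full model.
#' @return object of class `rejection_count_table`: data.frame `table`
#'   (gene, count, tested, selected) plus settings.
#' @export
count_ftest_rejections <- function(gene_panel, taxa_panel, pairings,
                                   metadata, alpha = 0.05,
                                   taxa_rule = list(type = "all"),
                                   selection_threshold = 40,
                                   min_resid_df = 3) {
  G <- gene_panel$values; Tm <- taxa_panel$values
  n_genes <- ncol(G)
  n_pair <- nrow(pairings$realizations[[1]])
  max_taxa <- n_pair - 4L - min_resid_df
  if (max_taxa < 1)
    stop("too few paired samples for any taxon predictor at min_resid_df = ",
         min_resid_df)

  # per-gene taxa subsets (column indices into the panel), shared map
  if (taxa_rule$type == "all") {
    ord <- order(colMeans(Tm), decreasing = TRUE)
    subset_all <- ord[seq_len(min(length(ord), max_taxa))]
    gene_subsets <- rep(list(subset_all), n_genes)
  } else if (taxa_rule$type == "candidates") {
    pc <- taxa_rule$pair_counts
    stopifnot(inherits(pc, "pair_count_table"))
    gene_subsets <- lapply(seq_len(n_genes), function(k) {
      cand <- which(pc$candidate[k, ])
      if (length(cand) == 0) return(integer(0))
      cand[order(pc$counts[k, cand], decreasing = TRUE)][
        seq_len(min(length(cand), max_taxa))]
    })
  } else stop("unknown taxa_rule type: ", taxa_rule$type)

  tested <- lengths(gene_subsets) > 0
  counts <- rep(0L, n_genes)
  subset_key <- vapply(gene_subsets, paste, character(1), collapse = ",")
  groups_of_genes <- split(seq_len(n_genes)[tested], subset_key[tested])

  for (pairing in pairings$realizations) {
    idx <- pairing_indices(pairing, taxa_panel, gene_panel, metadata)
    n <- length(idx$mi)
    reduced <- design_2x2(idx$X1, idx$X2)
    qr_red <- qr(reduced)
    rss_r <- colSums(qr.resid(qr_red, G[idx$ei, , drop = FALSE])^2)
    for (genes in groups_of_genes) {
      sub <- gene_subsets[[genes[1]]]
      full <- cbind(reduced, Tm[idx$mi, sub, drop = FALSE])
      qf <- qr(full)
      if (qf$rank < ncol(full) || n - ncol(full) < 1) next  # degenerate draw
      rss_f <- colSums(qr.resid(qf, G[idx$ei, genes, drop = FALSE])^2)
      df1 <- ncol(full) - 4L
      df2 <- n - ncol(full)
      fstat <- ((rss_r[genes] - rss_f) / df1) / (rss_f / df2)
      p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
      counts[genes] <- counts[genes] + (p < alpha & is.finite(p))
    }
  }
  tab <- data.frame(gene = colnames(G), count = counts, tested = tested,
                    selected = tested & counts > selection_threshold,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, R = pairings$R, alpha = alpha,
                 selection_threshold = selection_threshold,
                 taxa_rule = taxa_rule$type, min_resid_df = min_resid_df),
            class = "rejection_count_table")
}

#' Row-normalized group-mean matrix for heatmap display
#'
#' For each selected gene, the mean expression per treatment group is
#' divided by the mean of the four group means, so every row averages 1
#' and shows relative fold change across groups.
#'
#' @param values samples x genes numeric matrix (raw or normalized
#'   expression; not standardized, whose zero mean would be degenerate).
#' @param metadata [sample_metadata()].
#' @param genes optional subset of gene columns.
#' @return genes x groups matrix; rows with zero mean are dropped with a
#'   warning.
#' @export
heatmap_matrix <- function(values, metadata, genes = NULL) {
  m <- as.matrix(values)
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  if (ncol(m) == 0) stop("no genes to display")
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  grp <- factor(md$group)
  gm <- t(rowsum(m, grp) / as.vector(table(grp)))  # genes x groups
  rm_ <- rowMeans(gm)
  bad <- rm_ == 0
  if (any(bad)) {
    warning("dropping gene row(s) with zero mean: ",
            paste(rownames(gm)[bad], collapse = ", "))
    gm <- gm[!bad, , drop = FALSE]; rm_ <- rm_[!bad]
  }
  gm / rm_
}
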