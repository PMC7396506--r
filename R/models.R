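# Shared OLS machinery. All model fits in the package go through
# ols_multi(), which solves many responses against one design at once;
# tests compare it against a normal-equations oracle.

#' Design matrix for the 2x2 factorial: intercept, X1, X2, X1:X2
#' @param X1,X2 binary treatment indicators.
#' @return n x 4 numeric matrix.
#' @export
design_2x2 <- function(X1, X2) {
  cbind(`(Intercept)` = 1, X1 = as.numeric(X1), X2 = as.numeric(X2),
        `X1:X2` = as.numeric(X1) * as.numeric(X2))
}

#' Fit OLS for many response columns against one design matrix
#'
#' @param X n x p design matrix (full column rank required).
#' @param Y n x m response matrix.
#' @return list with `coef`, `se`, `t`, `p` (each p x m), `rss` (length m),
#'   `df` residual degrees of freedom, `sigma2`, and `fitted`/`residuals`.
#' @export
ols_multi <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p)
    stop("design matrix is rank deficient (rank ", qx$rank, " < ", p, ")")
  if (n <= p) stop("need more observations than parameters")
  coef <- qr.coef(qx, Y)
  fitted <- X %*% coef
  res <- Y - fitted
  df <- n - p
  rss <- colSums(res^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tstat <- coef / se
  # guard 0/0 for exactly-constant responses
  tstat[se == 0] <- 0
  pval <- 2 * stats::pt(-abs(tstat), df)
  dimnames(coef) <- dimnames(se) <- dimnames(tstat) <- dimnames(pval) <-
    list(colnames(X), colnames(Y))
  list(coef = coef, se = se, t = tstat, p = pval, rss = rss, df = df,
       sigma2 = sigma2, fitted = fitted, residuals = res)
}

# residual sums of squares of Y on design X, vectorized over columns of Y
rss_on <- function(X, Y) {
  qx <- qr(X)
  colSums(qr.resid(qx, Y)^2)
}

# type II two-way ANOVA of a single response (used by diversity_regression)
anova_2x2 <- function(y, X1, X2) {
  Y <- matrix(y, ncol = 1)
  n <- length(y)
  full <- design_2x2(X1, X2)
  rss_full <- rss_on(full, Y)
  rss_12 <- rss_on(full[, 1:3, drop = FALSE], Y)           # 1 + X1 + X2
  rss_2 <- rss_on(full[, c(1, 3), drop = FALSE], Y)        # 1 + X2
  rss_1 <- rss_on(full[, c(1, 2), drop = FALSE], Y)        # 1 + X1
  df_res <- n - 4L
  ms_res <- rss_full / df_res
  ss <- c(X1 = rss_2 - rss_12, X2 = rss_1 - rss_12, `X1:X2` = rss_12 - rss_full)
  fstat <- ss / ms_res
  p <- stats::pf(fstat, 1, df_res, lower.tail = FALSE)
  data.frame(term = c(names(ss), "Residual"), df = c(1L, 1L, 1L, df_res),
             SS = c(ss, rss_full), F = c(fstat, NA), p = c(p, NA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-feature two-way ANOVA across a feature matrix
#'
#' For every feature (gene or taxon) fits the 2x2 factorial by OLS and
#' reports type II F-tests for X1, X2 and the interaction, with
#' Benjamini-Hochberg q-values across features per term. Type II sums of
#' squares are used because the design may be mildly unbalanced after
#' sample exclusions. This is a simplified native stand-in for a
#' negative-binomial differential analysis: adequate on transformed counts,
#' not a replacement for dedicated RNA-seq machinery.
#'
#' @param values samples x features numeric matrix, or an
#'   [expression_matrix()].
#' @param metadata [sample_metadata()].
#' @param transform `"none"` or `"log1p"` applied before fitting.
#' @return data.frame per feature: F and p for each term plus `q_*`
#'   columns; constant features get p = 1 and `constant = TRUE`.
#' @export
two_way_anova_per_feature <- function(values, metadata,
                                      transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  m <- if (inherits(values, "expression_matrix")) values$values else as.matrix(values)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  counts <- table(factor(md$group, levels = group_label(c(0,0,1,1), c(0,1,0,1))))
  if (any(counts < 2)) stop("empty or singleton treatment cell: ",
                            paste(names(counts)[counts < 2], collapse = ", "))
  if (transform == "log1p") m <- log1p(m)
  n <- nrow(m)
  full <- design_2x2(md$X1, md$X2)
  rss_full <- rss_on(full, m)
  rss_12 <- rss_on(full[, 1:3, drop = FALSE], m)
  rss_2 <- rss_on(full[, c(1, 3), drop = FALSE], m)
  rss_1 <- rss_on(full[, c(1, 2), drop = FALSE], m)
  df_res <- n - 4L
  ms_res <- rss_full / df_res
  constant <- apply(m, 2, function(v) stats::var(v) == 0)
  fp <- function(ss) {
    f <- ss / ms_res
    p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
    f[constant] <- 0; p[constant] <- 1
    list(f = f, p = p)
  }
  t1 <- fp(pmax(rss_2 - rss_12, 0))
  t2 <- fp(pmax(rss_1 - rss_12, 0))
  t3 <- fp(pmax(rss_12 - rss_full, 0))
  data.frame(feature = colnames(m),
             F_X1 = t1$f, p_X1 = t1$p, q_X1 = bh_adjust(t1$p),
             F_X2 = t2$f, p_X2 = t2$p, q_X2 = bh_adjust(t2$p),
             F_int = t3$f, p_int = t3$p, q_int = bh_adjust(t3$p),
             constant = constant, row.names = NULL, stringsAsFactors = FALSE)
}

#' Model 1: per-taxon treatment regression and interaction selection
#'
#' Fits `M_t = b0 + b1 X1 + b2 X2 + b3 X1 X2 + e` for every taxon in the
#' abundant-taxa panel (percent abundances) and flags taxa whose
#' interaction coefficient b3 is significant (`p < alpha`) — the taxa whose
#' abundance responds to the combined treatment.
#'
#' @param taxa_values microbiome samples x taxa numeric matrix (percent
#'   abundances), or an `abundant_taxa_panel`.
#' @param metadata [sample_metadata()].
#' @param alpha selection threshold on the interaction p-value.
#' @return data.frame of class `model1_result`: per taxon b0..b3, standard
#'   errors, p-values, and `selected`.
#' @export
fit_model1 <- function(taxa_values, metadata, alpha = 0.05) {
  m <- if (inherits(taxa_values, "abundant_taxa_panel")) taxa_values$values
       else as.matrix(taxa_values)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  X <- design_2x2(md$X1, md$X2)
  fit <- tryCatch(ols_multi(X, m), error = function(e)
    stop("model 1 design failure for taxa panel: ", conditionMessage(e)))
  out <- data.frame(taxon = colnames(m),
                    beta0 = fit$coef[1, ], beta1 = fit$coef[2, ],
                    beta2 = fit$coef[3, ], beta3 = fit$coef[4, ],
                    se0 = fit$se[1, ], se1 = fit$se[2, ],
                    se2 = fit$se[3, ], se3 = fit$se[4, ],
                    p1 = fit$p[2, ], p2 = fit$p[3, ], p3 = fit$p[4, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$selected <- out$p3 < alpha
  class(out) <- c("model1_result", "data.frame")
  out
}

#' Model 2: gene on treatments, one taxon, and taxon x interaction
#'
#' Fits `Y_k = b0 + b1 X1 + b2 X2 + b3 X1 X2 + b4 M_t + b5 M_t X1 X2 + e`
#' for one (gene, taxon) combination under one pairing realization (gene
#' and taxon vectors already aligned sample-by-sample). A gene is
#' dual-significant when both the treatment interaction (b3) and the taxon
#' term (b4) reach `p < alpha`. b5 is estimated and reported but takes part
#' in no selection rule.
#'
#' @param gene_values numeric vector (standardized gene expression).
#' @param taxon_values numeric vector (taxon percent abundance), same
#'   length/order.
#' @param metadata [sample_metadata()] rows aligned to the vectors via
#'   `sample_ids`.
#' @param sample_ids ids aligning the vectors to metadata.
#' @param alpha significance threshold.
#' @param collinearity_tol minimum relative rank tolerance; if the taxon
#'   column is (numerically) collinear with the design the fit is skipped
#'   with `skipped = TRUE`.
#' @return one-row data.frame of class `model2_result`: beta0..beta5,
#'   p-values, `dual_significant`, `skipped`.
#' @export
fit_model2 <- function(gene_values, taxon_values, metadata, sample_ids,
                       alpha = 0.05, collinearity_tol = 1e-8) {
  md <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  X <- cbind(design_2x2(md$X1, md$X2), M = taxon_values,
             `M:X1:X2` = taxon_values * md$X1 * md$X2)
  skipped <- FALSE
  qx <- qr(X, tol = collinearity_tol)
  if (qx$rank < ncol(X)) {
    skipped <- TRUE
    out <- data.frame(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                      beta3 = NA_real_, beta4 = NA_real_, beta5 = NA_real_,
                      se3 = NA_real_, se4 = NA_real_,
                      p3 = NA_real_, p4 = NA_real_, p5 = NA_real_,
                      r_squared = NA_real_,
                      dual_significant = FALSE, skipped = TRUE,
                      stringsAsFactors = FALSE)
    class(out) <- c("model2_result", "data.frame")
    return(out)
  }
  fit <- ols_multi(X, matrix(gene_values, ncol = 1))
  tss <- sum((gene_values - mean(gene_values))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - fit$rss[1] / tss
  out <- data.frame(beta0 = fit$coef[1, 1], beta1 = fit$coef[2, 1],
                    beta2 = fit$coef[3, 1], beta3 = fit$coef[4, 1],
                    beta4 = fit$coef[5, 1], beta5 = fit$coef[6, 1],
                    se3 = fit$se[4, 1], se4 = fit$se[5, 1],
                    p3 = fit$p[4, 1], p4 = fit$p[5, 1], p5 = fit$p[6, 1],
                    r_squared = r2,
                    dual_significant = fit$p[4, 1] < alpha && fit$p[5, 1] < alpha,
                    skipped = skipped, stringsAsFactors = FALSE)
  class(out) <- c("model2_result", "data.frame")
  out
}

#' Partial F-test: do taxa add explanatory power over the treatments?
#'
#' Compares the reduced model (intercept + X1 + X2 + X1:X2) with the full
#' model adding the columns of a taxa panel subset, for one gene under one
#' pairing realization. Rejection of the null (no improvement) suggests
#' the taxa carry information about the gene beyond the treatments.
#'
#' @param gene_values numeric vector of the gene's (standardized) values.
#' @param taxa_values numeric matrix (aligned samples x taxa subset); must
#'   have at least one column.
#' @param metadata [sample_metadata()].
#' @param sample_ids ids aligning rows to metadata.
#' @param alpha rejection threshold.
#' @return one-row data.frame of class `ftest_result`: `F`, `df1`, `df2`,
#'   `p`, `rejected`.
#' @export
taxa_inclusion_ftest <- function(gene_values, taxa_values, metadata,
                                 sample_ids, alpha = 0.05) {
  taxa_values <- as.matrix(taxa_values)
  if (ncol(taxa_values) == 0)
    stop("taxa subset is empty: the partial F-test is undefined")
  md <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  reduced <- design_2x2(md$X1, md$X2)
  full <- cbind(reduced, taxa_values)
  n <- nrow(full)
  qf <- qr(full)
  if (qf$rank < ncol(full) || n - qf$rank < 1)
    stop("full model saturated or rank-deficient: shrink the taxa subset")
  Y <- matrix(gene_values, ncol = 1)
  rss_r <- rss_on(reduced, Y)
  rss_f <- colSums(qr.resid(qf, Y)^2)
  df1 <- ncol(full) - ncol(reduced)
  df2 <- n - ncol(full)
  fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  data.frame(F = fstat, df1 = df1, df2 = df2, p = p, rejected = p < alpha,
             stringsAsFactors = FALSE)
}
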