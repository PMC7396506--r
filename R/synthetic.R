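#' Describe the size and noise structure of a synthetic two-cohort dataset
#'
#' The defaults emulate the scale of a 2x2 mouse study measuring colonic
#' microbiota (16S OTU counts) in one cohort and colonic gene expression
#' (RNA-seq counts) in an independent second cohort: n = 5 mice per group,
#' a 200-taxon community sequenced to a mean depth of 43,000 reads, and a
#' 2,000-gene expression panel (a down-scaled stand-in for a genome-wide
#' matrix) at a mean depth of 5e5 counts.
#'
#' @param n_per_group mice per treatment group and cohort (>= 2).
#' @param n_taxa number of taxa in the community.
#' @param n_genes number of genes in the expression panel.
#' @param seed master seed; every random draw in [generate_dataset()] flows
#'   from it through per-table substreams.
#' @param library_size_taxa,library_size_genes mean sequencing depths.
#' @param taxa_sample_sd SD of per-sample log-abundance noise around the
#'   group-level latent (logistic-normal overdispersion).
#' @param gene_dispersion_range range of the per-gene negative-binomial
#'   dispersion phi (Var = mu + phi mu^2), drawn log-uniform.
#' @param base_abundance_sd SD of the baseline taxon log-abundances; larger
#'   values give a longer-tailed (more realistic) rank-abundance curve.
#' @param depth_sdlog lognormal SD of per-sample library sizes.
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_per_group = 5, n_taxa = 200, n_genes = 2000,
                             seed = 1, library_size_taxa = 43000,
                             library_size_genes = 5e5,
                             taxa_sample_sd = 0.5,
                             gene_dispersion_range = c(0.05, 0.5),
                             base_abundance_sd = 2,
                             depth_sdlog = 0.2) {
  stopifnot(n_per_group >= 2, n_taxa >= 2, n_genes >= 1,
            library_size_taxa > 0, library_size_genes > 0,
            taxa_sample_sd >= 0, all(gene_dispersion_range > 0),
            base_abundance_sd >= 0, depth_sdlog >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 seed = as.integer(seed),
                 library_size_taxa = library_size_taxa,
                 library_size_genes = library_size_genes,
                 taxa_sample_sd = taxa_sample_sd,
                 gene_dispersion_range = gene_dispersion_range,
                 base_abundance_sd = base_abundance_sd,
                 depth_sdlog = depth_sdlog),
            class = "synthetic_design")
}

#' Planted ground-truth effects for a synthetic dataset
#'
#' Effects act on the log scale. `taxa_effects` columns (`a1`, `a2`, `a3`)
#' shift a taxon's group-level log abundance by alcohol (X1), wrong-time
#' feeding (X2) and their interaction; `gene_effects` (`b1`, `b2`, `b3`) do
#' the same for a gene's log mean expression; `coupling[k, t]` multiplies
#' taxon t's centered group-level latent log-abundance in gene k's log mean
#' (group-level because the two cohorts are unmatched: only group structure
#' is shared).
#'
#' @param n_taxa,n_genes dimensions (must match the design used later).
#' @param taxa_effects numeric n_taxa x 3 matrix or NULL for all-zero.
#' @param gene_effects numeric n_genes x 3 matrix or NULL for all-zero.
#' @param coupling numeric n_genes x n_taxa matrix or NULL for all-zero.
#' @return list of class `synthetic_truth`, with `interaction_taxa`
#'   (indices with a3 != 0) and `coupled_genes` / `coupling_support`
#'   recorded for recovery tests.
#' @export
synthetic_truth <- function(n_taxa, n_genes, taxa_effects = NULL,
                            gene_effects = NULL, coupling = NULL) {
  if (is.null(taxa_effects)) taxa_effects <- matrix(0, n_taxa, 3)
  if (is.null(gene_effects)) gene_effects <- matrix(0, n_genes, 3)
  if (is.null(coupling)) coupling <- matrix(0, n_genes, n_taxa)
  taxa_effects <- as.matrix(taxa_effects); gene_effects <- as.matrix(gene_effects)
  coupling <- as.matrix(coupling)
  stopifnot(nrow(taxa_effects) == n_taxa, ncol(taxa_effects) == 3,
            nrow(gene_effects) == n_genes, ncol(gene_effects) == 3,
            nrow(coupling) == n_genes, ncol(coupling) == n_taxa)
  colnames(taxa_effects) <- c("a1", "a2", "a3")
  colnames(gene_effects) <- c("b1", "b2", "b3")
  support <- which(coupling != 0, arr.ind = TRUE)
  structure(list(n_taxa = n_taxa, n_genes = n_genes,
                 taxa_effects = taxa_effects, gene_effects = gene_effects,
                 coupling = coupling,
                 interaction_taxa = which(taxa_effects[, 3] != 0),
                 coupled_genes = sort(unique(support[, 1])),
                 coupling_support = support),
            class = "synthetic_truth")
}

#' Convenience constructor planting interaction taxa and coupled genes
#'
#' Taxa are indexed in decreasing baseline abundance by
#' [generate_dataset()], so planting on the first `n_interaction_taxa`
#' indices guarantees the planted taxa are abundant enough to survive the
#' abundance filter of the correspondence panel.
#'
#' @param design a [synthetic_design()].
#' @param n_interaction_taxa number of taxa given a non-zero interaction
#'   effect `a3` (on the most abundant taxa).
#' @param taxon_interaction_effect value of a3 on the log scale.
#' @param n_coupled_genes number of genes coupled to planted taxa (one
#'   planted taxon each, round-robin).
#' @param coupling_strength value of the coupling coefficient.
#' @return a [synthetic_truth()].
#' @export
planted_truth <- function(design, n_interaction_taxa = 0,
                          taxon_interaction_effect = 2,
                          n_coupled_genes = 0, coupling_strength = 1.5) {
  te <- matrix(0, design$n_taxa, 3)
  if (n_interaction_taxa > 0)
    te[seq_len(n_interaction_taxa), 3] <- taxon_interaction_effect
  cp <- matrix(0, design$n_genes, design$n_taxa)
  if (n_coupled_genes > 0) {
    if (n_interaction_taxa == 0)
      stop("coupled genes need at least one planted taxon")
    tx <- rep_len(seq_len(n_interaction_taxa), n_coupled_genes)
    cp[cbind(seq_len(n_coupled_genes), tx)] <- coupling_strength
  }
  synthetic_truth(design$n_taxa, design$n_genes, taxa_effects = te,
                  coupling = cp)
}

# 2x2 design skeleton in fixed group order
design_groups <- function() {
  data.frame(X1 = c(0L, 0L, 1L, 1L), X2 = c(0L, 1L, 0L, 1L))
}

synthetic_taxonomy <- function(n_taxa) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia", "TM7")
  p <- rep_len(phyla, n_taxa)
  id <- sprintf("OTU_%04d", seq_len(n_taxa))
  data.frame(otu_id = id,
             lineage = sprintf("k__Bacteria;p__%s;c__;o__;f__;g__Genus_%04d;s__",
                               p, seq_len(n_taxa)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-cohort dataset with planted ground truth
#'
#' Taxa counts follow a logistic-normal multinomial: each group g has a
#' latent log-abundance vector `lambda[g, t] = alpha_t + a1 X1 + a2 X2 +
#' a3 X1 X2` (alpha sorted decreasing, so taxon 1 is the most abundant);
#' a sample adds N(0, taxa_sample_sd) noise per taxon, the softmax gives
#' its composition and a multinomial draw at a lognormal library size gives
#' counts. Gene counts are negative binomial with log mean
#' `b0_k + b1 X1 + b2 X2 + b3 X1X2 + sum_t coupling[k,t] *
#' centered(lambda)[g,t]`, re-normalized within sample so library size is
#' meaningful. The two cohorts share only the group-level latents: sample
#' ids are disjoint and per-sample noise is independent.
#'
#' @param design a [synthetic_design()].
#' @param truth a [synthetic_truth()] of matching dimensions.
#' @return list with `otu` ([otu_table()], microbiome cohort), `expr`
#'   ([expression_matrix()], expression cohort), `metadata` (both cohorts),
#'   `latents` (4 groups x n_taxa group-level log abundances, for oracle
#'   checks) and `truth`.
#' @export
generate_dataset <- function(design, truth = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.null(truth))
    truth <- synthetic_truth(design$n_taxa, design$n_genes)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (truth$n_taxa != design$n_taxa || truth$n_genes != design$n_genes)
    stop("truth dimensions do not match design")
  if (nrow(truth$coupling_support) > 0 &&
      max(truth$coupling_support[, 2]) > design$n_taxa)
    stop("coupling references taxon index out of range")

  n <- design$n_per_group
  g4 <- design_groups()
  grp_of_sample <- rep(seq_len(4), each = n)
  X1 <- g4$X1[grp_of_sample]; X2 <- g4$X2[grp_of_sample]
  n_samp <- 4L * n

  set.seed(design$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4)

  # shared structure: baseline abundances and group latents
  set.seed(sub[1])
  alpha <- sort(stats::rnorm(design$n_taxa, 0, design$base_abundance_sd),
                decreasing = TRUE)
  lambda <- matrix(alpha, 4, design$n_taxa, byrow = TRUE) +
    as.matrix(g4) %*% t(truth$taxa_effects[, 1:2]) +
    (g4$X1 * g4$X2) %*% t(truth$taxa_effects[, 3, drop = FALSE])
  dimnames(lambda) <- list(group_label(g4$X1, g4$X2),
                           sprintf("OTU_%04d", seq_len(design$n_taxa)))
  lambda_c <- sweep(lambda, 2, colMeans(lambda))  # centered across groups

  # microbiome cohort
  set.seed(sub[2])
  depth_mb <- round(stats::rlnorm(n_samp, log(design$library_size_taxa) -
                                    design$depth_sdlog^2 / 2, design$depth_sdlog))
  eta <- lambda[grp_of_sample, , drop = FALSE] +
    matrix(stats::rnorm(n_samp * design$n_taxa, 0, design$taxa_sample_sd),
           n_samp, design$n_taxa)
  counts_mb <- matrix(0L, n_samp, design$n_taxa)
  for (j in seq_len(n_samp)) {
    p <- exp(eta[j, ] - max(eta[j, ]))
    counts_mb[j, ] <- stats::rmultinom(1, depth_mb[j], p / sum(p))
  }
  mb_ids <- sprintf("MB%03d", seq_len(n_samp))
  dimnames(counts_mb) <- list(mb_ids, sprintf("OTU_%04d", seq_len(design$n_taxa)))
  otu <- otu_table(counts_mb, synthetic_taxonomy(design$n_taxa))

  # expression cohort
  set.seed(sub[3])
  depth_ex <- round(stats::rlnorm(n_samp, log(design$library_size_genes) -
                                    design$depth_sdlog^2 / 2, design$depth_sdlog))
  b0 <- stats::rnorm(design$n_genes, 0, 1)
  phi <- exp(stats::runif(design$n_genes,
                          log(design$gene_dispersion_range[1]),
                          log(design$gene_dispersion_range[2])))
  design_fx <- cbind(g4$X1, g4$X2, g4$X1 * g4$X2) %*% t(truth$gene_effects)
  coupled_fx <- lambda_c %*% t(truth$coupling)       # 4 groups x n_genes
  loggrp <- sweep(design_fx + coupled_fx, 2, b0, "+") # 4 x n_genes
  counts_ex <- matrix(0L, n_samp, design$n_genes)
  for (j in seq_len(n_samp)) {
    w <- exp(loggrp[grp_of_sample[j], ])
    mu <- depth_ex[j] * w / sum(w)
    counts_ex[j, ] <- stats::rnbinom(design$n_genes, mu = mu, size = 1 / phi)
  }
  ex_ids <- sprintf("EX%03d", seq_len(n_samp))
  dimnames(counts_ex) <- list(ex_ids, sprintf("gene_%04d", seq_len(design$n_genes)))
  expr <- expression_matrix(counts_ex, "raw_count")

  md <- sample_metadata(c(mb_ids, ex_ids), c(X1, X1), c(X2, X2),
                        rep(c("microbiome", "expression"), each = n_samp))
  list(otu = otu, expr = expr, metadata = md, latents = lambda, truth = truth)
}

#' Generate a dataset under the global null (all planted effects zero)
#' @param design a [synthetic_design()].
#' @return as [generate_dataset()], with an all-zero truth.
#' @export
null_dataset <- function(design) {
  generate_dataset(design, synthetic_truth(design$n_taxa, design$n_genes))
}
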