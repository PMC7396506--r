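# Orchestration: one reproducible run from raw tables (or a simulated
# dataset) to community statistics, correspondence counting, two-step
# models and the heatmap, with every threshold echoed into a JSON
# manifest.

#' Build a validated pipeline run configuration
#'
#' All thresholds of the analysis live here and are echoed into the output
#' manifest. Defaults follow the reference protocol: rarefaction to the
#' minimum sample depth (43,000 at paper scale), rare-OTU grand-total
#' filter 5, genus-level abundant-taxa panel with group-mean > 10, gene
#' zero-filter (at most one zero), R = 500 pairings, all significance
#' levels 0.05, candidate count threshold 53, rejection selection
#' threshold 40.
#'
#' @param ... named overrides of the defaults listed above; unknown keys
#'   are rejected.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    # inputs: either file paths ...
    otu = NULL, taxonomy = NULL, expr = NULL, meta = NULL,
    # ... or simulation
    simulate = FALSE, n_per_group = 5, n_taxa = 200, n_genes = 2000,
    n_interaction_taxa = 0, taxon_interaction_effect = 2,
    n_coupled_genes = 0, coupling_strength = 1.5,
    # preprocessing
    rarefy_depth = "min", min_otu_total = 5,
    # community statistics
    nperm = 9999, posthoc_adjust = "tukey", taxa_levels = c("phylum", "genus"),
    # correspondence
    panel_level = "genus", min_group_mean = 10, max_gene_zeros = 1,
    R = 500, alpha0 = 0.05, alpha = 0.05,
    count_threshold = 53, rejection_threshold = 40,
    taxa_rule = "candidates", min_resid_df = 3,
    adjust_for_treatment = FALSE,
    # reproducibility
    seed = 1,
    stages = c("community", "correspond", "models"))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  stopifnot(cfg$R >= 1, cfg$alpha0 > 0, cfg$alpha0 < 1,
            cfg$count_threshold >= 0, cfg$rejection_threshold >= 0,
            cfg$min_resid_df >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat key-value file
#' @param path config file parsed by [read_config_file()].
#' @return [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- read_config_file(path)
  if (!is.null(raw$simulate))
    raw$simulate <- tolower(as.character(raw$simulate)) %in% c("true", "yes", "1")
  do.call(run_config, raw)
}

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes, in order: input loading or simulation; preprocessing
#' (lineage exclusion, rarefaction, rare-OTU filter); community statistics
#' (alpha diversity + regressions, Bray-Curtis + PERMANOVA + pairwise,
#' CLR taxon regressions, F/B ratio); panel construction, random pairings,
#' per-pair significance counting, F-test rejection counting and gene
#' selection; Model 1 taxon selection and Model 2 gene-taxon association
#' across pairings; the row-normalized heatmap matrix. Every stage writes
#' its table under `out_dir` and the manifest records config, seeds and
#' feature counts after every filter.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("chronolink")),
                   counts = list(), log = character())
  note <- function(...) {
    msg <- sprintf(...)
    manifest$log <<- c(manifest$log, msg)
    message("[chronolink] ", msg)
  }

  # ---- stage: inputs -------------------------------------------------------
  if (isTRUE(config$simulate)) {
    design <- synthetic_design(n_per_group = config$n_per_group,
                               n_taxa = config$n_taxa,
                               n_genes = config$n_genes, seed = config$seed)
    truth <- planted_truth(design,
                           n_interaction_taxa = config$n_interaction_taxa,
                           taxon_interaction_effect = config$taxon_interaction_effect,
                           n_coupled_genes = config$n_coupled_genes,
                           coupling_strength = config$coupling_strength)
    ds <- generate_dataset(design, truth)
    otu <- ds$otu; expr <- ds$expr; md <- ds$metadata
    write_otu_table(otu, file.path(out_dir, "otu.tsv"),
                    file.path(out_dir, "taxonomy.tsv"))
    write_expression_matrix(expr, file.path(out_dir, "expression.tsv"))
    write_metadata(md, file.path(out_dir, "metadata.tsv"))
    truth_json <- list(interaction_taxa = as.integer(truth$interaction_taxa),
                       coupled_genes = as.integer(truth$coupled_genes),
                       coupling_support = as.data.frame(truth$coupling_support),
                       taxon_interaction_effect = config$taxon_interaction_effect,
                       coupling_strength = config$coupling_strength)
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    note("simulated dataset: %d taxa, %d genes, %d samples/cohort",
         config$n_taxa, config$n_genes, 4 * config$n_per_group)
  } else {
    if (is.null(config$otu) || is.null(config$taxonomy) ||
        is.null(config$expr) || is.null(config$meta))
      stop("stage inputs: need otu, taxonomy, expr and meta paths (or simulate: true)")
    otu <- read_otu_table(config$otu, config$taxonomy)
    expr <- read_expression_matrix(config$expr)
    md <- read_metadata(config$meta)
    ds <- NULL
  }
  check_metadata_join(rownames(otu$counts), md)
  check_metadata_join(rownames(expr$values), md)

  # ---- stage: preprocessing ------------------------------------------------
  manifest$counts$otus_input <- ncol(otu$counts)
  otu <- exclude_lineages(otu)
  manifest$counts$otus_after_lineage_exclusion <- ncol(otu$counts)
  depth <- config$rarefy_depth
  if (identical(depth, "min")) depth <- min(rowSums(otu$counts))
  otu <- rarefy(otu, depth, seed = config$seed)
  manifest$counts$rarefy_depth <- depth
  otu <- filter_rare_otus(otu, config$min_otu_total)
  manifest$counts$otus_after_rare_filter <- ncol(otu$counts)
  note("preprocessing: %d -> %d OTUs (lineage exclusion, rarefied to %d, total < %d removed)",
       manifest$counts$otus_input, ncol(otu$counts), depth, config$min_otu_total)

  mb_md <- md[md$cohort == "microbiome", ]
  results <- list(otu = otu, expr = expr, metadata = md)

  # ---- stage: community ----------------------------------------------------
  if ("community" %in% config$stages) {
    div <- alpha_diversity(otu)
    write_tsv_df(div, file.path(out_dir, "diversity.tsv"))
    reg_rows <- list()
    for (metric in c("richness", "inv_simpson")) {
      dr <- diversity_regression(div, mb_md, metric = metric,
                                 posthoc_adjust = config$posthoc_adjust)
      reg_rows[[metric]] <- cbind(metric = metric, dr$coefficients,
                                  r_squared = dr$r_squared)
    }
    write_tsv_df(do.call(rbind, reg_rows),
                 file.path(out_dir, "diversity_regressions.tsv"))
    d <- bray_curtis(otu)
    pmv <- permanova(d, mb_md, nperm = config$nperm, seed = config$seed)
    write_tsv_df(pmv$table, file.path(out_dir, "permanova.tsv"))
    pw <- pairwise_permanova(d, mb_md, nperm = config$nperm, seed = config$seed)
    write_tsv_df(pw, file.path(out_dir, "pairwise_permanova.tsv"))
    pcoa <- stats::cmdscale(stats::as.dist(d), k = min(4, nrow(d) - 1))
    write_tsv_matrix(pcoa, file.path(out_dir, "pcoa_axes.tsv"))
    for (lev in config$taxa_levels) {
      tr <- taxon_regressions(otu, mb_md, level = lev)
      write_tsv_df(as.data.frame(tr),
                   file.path(out_dir, sprintf("taxa_regressions_%s.tsv", lev)))
    }
    fbr <- fb_ratio(otu)
    write_tsv_df(fbr, file.path(out_dir, "fb_ratio.tsv"))
    results$community <- list(diversity = div, permanova = pmv, pairwise = pw)
    note("community: PERMANOVA interaction R2 = %.3f (p = %.4g)",
         pmv$table$R2[3], pmv$table$p[3])
  }

  # ---- stage: correspondence -----------------------------------------------
  if ("correspond" %in% config$stages) {
    taxa_panel <- build_taxa_panel(otu, mb_md, level = config$panel_level,
                                   min_group_mean = config$min_group_mean)
    manifest$counts$taxa_panel <- list(before = taxa_panel$n_before,
                                       after = taxa_panel$n_after)
    note("taxa panel: %d -> %d taxa (%s, group mean > %g)",
         taxa_panel$n_before, taxa_panel$n_after, config$panel_level,
         config$min_group_mean)
    gene_panel <- build_gene_panel(expr, max_zeros = config$max_gene_zeros)
    manifest$counts$gene_panel <- list(before = gene_panel$n_before,
                                       after = gene_panel$n_after)
    note("gene panel: %d -> %d genes (<= %d zeros)", gene_panel$n_before,
         gene_panel$n_after, config$max_gene_zeros)
    write_tsv_matrix(taxa_panel$values, file.path(out_dir, "taxa_panel.tsv"))
    write_tsv_matrix(gene_panel$values, file.path(out_dir, "gene_panel.tsv"))

    pairings <- make_pairings(md, R = config$R, seed = config$seed)
    pc <- count_pair_significance(gene_panel, taxa_panel, pairings, md,
                                  alpha0 = config$alpha0,
                                  count_threshold = config$count_threshold,
                                  adjust_for_treatment = config$adjust_for_treatment)
    pc_df <- data.frame(gene = rep(rownames(pc$counts), ncol(pc$counts)),
                        taxon = rep(colnames(pc$counts), each = nrow(pc$counts)),
                        count = as.vector(pc$counts),
                        candidate = as.vector(pc$candidate),
                        stringsAsFactors = FALSE)
    write_tsv_df(pc_df[pc_df$count > 0, ], file.path(out_dir, "pair_counts.tsv"))

    # which Bonferroni multiplicity would reproduce the configured threshold
    m_grid <- c(1, taxa_panel$n_after, gene_panel$n_after,
                taxa_panel$n_after * gene_panel$n_after)
    thr <- vapply(m_grid, function(m)
      count_threshold_from_bonferroni(config$R, config$alpha0, m, config$alpha),
      integer(1))
    manifest$threshold_derivation <- data.frame(m = m_grid, threshold = thr)
    hit <- m_grid[thr == config$count_threshold]
    note("exact-binomial thresholds for m = {%s}: {%s}; configured threshold %d %s",
         paste(m_grid, collapse = ", "), paste(thr, collapse = ", "),
         config$count_threshold,
         if (length(hit)) paste0("reproduced by m = ",
                                 paste(hit, collapse = ", "))
         else "not reproduced by any of these m")

    rule <- if (config$taxa_rule == "candidates")
      list(type = "candidates", pair_counts = pc) else list(type = "all")
    rc <- count_ftest_rejections(gene_panel, taxa_panel, pairings, md,
                                 alpha = config$alpha, taxa_rule = rule,
                                 selection_threshold = config$rejection_threshold,
                                 min_resid_df = config$min_resid_df)
    write_tsv_df(rc$table, file.path(out_dir, "rejection_counts.tsv"))
    sel <- rc$table[rc$table$selected, , drop = FALSE]
    write_tsv_df(sel, file.path(out_dir, "selected_genes.tsv"))
    manifest$counts$genes_with_candidate <- sum(rowSums(pc$candidate) > 0)
    manifest$counts$selected_genes <- nrow(sel)
    note("correspondence: %d/%d genes with >= 1 candidate taxon; %d genes selected (count > %d)",
         manifest$counts$genes_with_candidate, gene_panel$n_after,
         nrow(sel), config$rejection_threshold)
    results$correspond <- list(taxa_panel = taxa_panel, gene_panel = gene_panel,
                               pairings = pairings, pair_counts = pc,
                               rejections = rc)
  }

  # ---- stage: two-step models + heatmap ------------------------------------
  if ("models" %in% config$stages && "correspond" %in% config$stages) {
    m1 <- fit_model1(taxa_panel, mb_md, alpha = config$alpha)
    write_tsv_df(as.data.frame(m1), file.path(out_dir, "model1_taxa.tsv"))
    manifest$counts$model1_selected_taxa <- sum(m1$selected)
    note("model 1: %d/%d taxa selected on the interaction term",
         sum(m1$selected), nrow(m1))

    sel_genes <- results$correspond$rejections$table$gene[
      results$correspond$rejections$table$selected]
    sel_taxa <- m1$taxon[m1$selected]
    if (length(sel_genes) > 0 && length(sel_taxa) > 0) {
      m2 <- model2_dual_counts(gene_panel, taxa_panel, pairings, md,
                               sel_genes, sel_taxa, alpha = config$alpha)
      write_tsv_df(m2, file.path(out_dir, "model2_gene_taxon.tsv"))
      dual <- m2[m2$dual_fraction > 0.5, , drop = FALSE]
      manifest$counts$dual_significant_axes <- nrow(dual)
      manifest$counts$explained_genes <- length(unique(dual$gene))
      note("model 2: %d dual-significant gene-taxon axes over %d genes",
           nrow(dual), length(unique(dual$gene)))
    } else {
      write_tsv_df(data.frame(gene = character(), taxon = character(),
                              dual_fraction = numeric()),
                   file.path(out_dir, "model2_gene_taxon.tsv"))
      manifest$counts$dual_significant_axes <- 0L
      manifest$counts$explained_genes <- 0L
      note("model 2: no selected genes and/or taxa; nothing to fit")
    }
    if (length(sel_genes) > 0) {
      hm <- heatmap_matrix(gene_panel$raw, md, genes = sel_genes)
      write_tsv_matrix(hm, file.path(out_dir, "heatmap.tsv"), id_col = "gene")
    }
  }

  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  results$manifest <- manifest
  invisible(results)
}

# Model 2 across pairings: per (selected gene, selected taxon), the
# fraction of realizations in which both the treatment interaction (b3)
# and the taxon term (b4) are significant.
model2_dual_counts <- function(gene_panel, taxa_panel, pairings, metadata,
                               sel_genes, sel_taxa, alpha = 0.05) {
  G <- gene_panel$values[, sel_genes, drop = FALSE]
  dual <- matrix(0L, length(sel_genes), length(sel_taxa),
                 dimnames = list(sel_genes, sel_taxa))
  b3 <- b4 <- matrix(0, length(sel_genes), length(sel_taxa),
                     dimnames = list(sel_genes, sel_taxa))
  n_ok <- 0L
  for (pairing in pairings$realizations) {
    idx <- pairing_indices(pairing, taxa_panel, gene_panel, metadata)
    D <- design_2x2(idx$X1, idx$X2)
    g <- G[idx$ei, , drop = FALSE]
    n_ok <- n_ok + 1L
    for (t_i in seq_along(sel_taxa)) {
      mt <- taxa_panel$values[idx$mi, sel_taxa[t_i]]
      X <- cbind(D, M = mt, `M:X1:X2` = mt * idx$X1 * idx$X2)
      if (qr(X)$rank < ncol(X)) next
      fit <- ols_multi(X, g)
      dual[, t_i] <- dual[, t_i] +
        (fit$p[4, ] < alpha & fit$p[5, ] < alpha)
      b3[, t_i] <- b3[, t_i] + fit$coef[4, ]
      b4[, t_i] <- b4[, t_i] + fit$coef[5, ]
    }
  }
  data.frame(gene = rep(sel_genes, length(sel_taxa)),
             taxon = rep(sel_taxa, each = length(sel_genes)),
             dual_count = as.vector(dual), R = pairings$R,
             dual_fraction = as.vector(dual) / n_ok,
             mean_beta3 = as.vector(b3) / n_ok,
             mean_beta4 = as.vector(b4) / n_ok,
             stringsAsFactors = FALSE)
}

#' Summarize a completed pipeline run
#'
#' Recomputes the headline numbers from the run directory's TSVs (not from
#' the manifest): fraction of genes with at least one candidate taxon,
#' number of interaction-selected taxa, number of selected genes, number
#' of dual-significant gene-taxon axes and of genes they explain.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list of class `chronolink_report` with the summary numbers.
#' @export
report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("incomplete run: no manifest.json in ", run_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  need <- c("pair_counts.tsv", "rejection_counts.tsv", "model1_taxa.tsv",
            "model2_gene_taxon.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0)
    stop("incomplete run: missing ", paste(missing, collapse = ", "))
  pc <- utils::read.delim(file.path(run_dir, "pair_counts.tsv"))
  rc <- utils::read.delim(file.path(run_dir, "rejection_counts.tsv"))
  m1 <- utils::read.delim(file.path(run_dir, "model1_taxa.tsv"))
  m2 <- utils::read.delim(file.path(run_dir, "model2_gene_taxon.tsv"))
  n_genes <- nrow(rc)
  genes_with_candidate <- if (nrow(pc) > 0)
    length(unique(pc$gene[pc$candidate])) else 0L
  dual <- m2[!is.na(m2$dual_fraction) & m2$dual_fraction > 0.5, , drop = FALSE]
  out <- list(
    n_genes = n_genes,
    genes_with_candidate = genes_with_candidate,
    frac_genes_with_candidate = if (n_genes > 0)
      genes_with_candidate / n_genes else 0,
    model1_selected_taxa = sum(m1$selected),
    selected_genes = sum(rc$selected),
    dual_significant_axes = nrow(dual),
    explained_genes = length(unique(dual$gene)),
    manifest = manifest)
  class(out) <- "chronolink_report"
  out
}

#' @export
print.chronolink_report <- function(x, ...) {
  cat("chronolink run summary\n")
  cat(sprintf("  genes tested:                   %d\n", x$n_genes))
  cat(sprintf("  genes with >= 1 candidate taxon: %d (%.1f%%)\n",
              x$genes_with_candidate, 100 * x$frac_genes_with_candidate))
  cat(sprintf("  interaction-selected taxa:      %d\n", x$model1_selected_taxa))
  cat(sprintf("  selected genes (F-test counts): %d\n", x$selected_genes))
  cat(sprintf("  dual-significant axes:          %d (%d genes)\n",
              x$dual_significant_axes, x$explained_genes))
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `community`, `correspond`, `model`, `run`,
#' `report`. Flags are `--key value` pairs matching [run_config()] names;
#' `--config FILE` loads a flat key-value file first, with flags
#' overriding. `--out DIR` names the output directory.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status (0 success, 2 validation error, 3 statistical
#'   degeneracy), invisibly.
#' @export
chronolink_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    cat("usage: chronolink <simulate|community|correspond|model|run|report> [--config FILE] [--key value ...] --out DIR\n")
    return(invisible(2L))
  }
  cmd <- args[1]; rest <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    val <- if (i + 1 <= length(rest)) rest[i + 1] else stop("missing value for --", key)
    num <- suppressWarnings(as.numeric(val))
    opts[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
    i <- i + 2
  }
  out_dir <- opts$out; opts$out <- NULL
  cfg_list <- if (!is.null(opts$config)) unclass(read_run_config(opts$config)) else list()
  opts$config <- NULL
  cfg_list <- utils::modifyList(cfg_list, opts, keep.null = TRUE)

  status <- tryCatch({
    if (cmd == "report") {
      print(report(out_dir))
      0L
    } else {
      stages <- switch(cmd,
        simulate = character(0),
        community = "community",
        correspond = "correspond",
        model = c("correspond", "models"),
        run = c("community", "correspond", "models"),
        stop("unknown subcommand: ", cmd))
      if (cmd == "simulate") cfg_list$simulate <- TRUE
      cfg_list$stages <- stages
      cfg <- do.call(run_config, cfg_list)
      if (is.null(out_dir)) stop("--out DIR is required")
      run_pipeline(cfg, out_dir)
      0L
    }
  }, error = function(e) {
    message("chronolink error: ", conditionMessage(e))
    if (grepl("rank|saturated|degrees of freedom|degenera", conditionMessage(e)))
      3L else 2L
  })
  invisible(status)
}
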