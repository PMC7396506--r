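# Small in-code fixtures shared across test files.

# a hand-built 3-sample x 4-OTU table with assorted lineages
tiny_otu <- function() {
  counts <- matrix(c(10L, 0L, 5L, 3L,
                     2L, 8L, 0L, 7L,
                     6L, 6L, 6L, 6L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"),
                                   c("OTU1", "OTU2", "OTU3", "OTU4")))
  tax <- data.frame(
    otu_id = c("OTU1", "OTU2", "OTU3", "OTU4"),
    lineage = c(
      "k__Bacteria;p__Firmicutes;c__Clostridia;o__;f__;g__Blautia;s__",
      "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__Bacteroides;s__",
      "k__Archaea;p__Euryarchaeota;c__;o__;f__;g__;s__",
      "k__Bacteria;p__Proteobacteria;c__Chloroplast;o__;f__Mitochondria;g__;s__"),
    stringsAsFactors = FALSE)
  otu_table(counts, tax)
}

# balanced 2x2 metadata for one cohort
meta_2x2 <- function(n_per_group, cohort = "microbiome", prefix = "S") {
  n <- 4 * n_per_group
  X1 <- rep(c(0, 0, 1, 1), each = n_per_group)
  X2 <- rep(c(0, 1, 0, 1), each = n_per_group)
  sample_metadata(sprintf("%s%02d", prefix, seq_len(n)), X1, X2,
                  rep(cohort, n))
}

# metadata holding both cohorts with matched group sizes
meta_two_cohorts <- function(n_per_group) {
  rbind(meta_2x2(n_per_group, "microbiome", "MB"),
        meta_2x2(n_per_group, "expression", "EX"))
}

# small synthetic dataset wrapper used by many tests
small_dataset <- function(seed = 1, n_per_group = 5, n_taxa = 30,
                          n_genes = 100, truth = NULL) {
  d <- synthetic_design(n_per_group = n_per_group, n_taxa = n_taxa,
                        n_genes = n_genes, seed = seed,
                        library_size_taxa = 10000,
                        library_size_genes = 1e5)
  if (is.null(truth)) generate_dataset(d) else generate_dataset(d, truth)
}
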