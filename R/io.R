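#' Construct a validated OTU count table
#'
#' An `otu_table` couples a samples x OTUs matrix of non-negative integer
#' counts with a per-OTU taxonomy lineage (Greengenes-style
#' `k__;p__;c__;o__;f__;g__;s__` strings, parsed into ranks; empty ranks are
#' allowed).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; both
#'   dimensions must carry unique names.
#' @param taxonomy data.frame with one row per OTU and columns
#'   `otu_id`, `lineage`; rank columns (`kingdom` ... `species`) are derived
#'   if absent.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (data.frame keyed by `otu_id`).
#' @export
otu_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(taxonomy)))
    stop("taxonomy needs columns 'otu_id' and 'lineage'")
  missing_tax <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(missing_tax) > 0)
    stop("taxonomy missing for OTU(s): ", paste(missing_tax, collapse = ", "))
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), , drop = FALSE]
  rank_cols <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  if (!all(rank_cols %in% names(taxonomy)))
    taxonomy <- cbind(taxonomy[c("otu_id", "lineage")], parse_lineage(taxonomy$lineage))
  rownames(taxonomy) <- taxonomy$otu_id
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' Parse Greengenes-style lineage strings into rank columns
#'
#' @param lineage character vector of `k__...;p__...;...` strings.
#' @return data.frame with columns kingdom, phylum, class, order, family,
#'   genus, species (empty string where the rank is unannotated).
#' @export
parse_lineage <- function(lineage) {
  ranks <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- matrix("", nrow = length(lineage), ncol = length(ranks),
                dimnames = list(NULL, unname(ranks)))
  pieces <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(pieces)) {
    for (p in trimws(pieces[[i]])) {
      m <- regmatches(p, regexec("^([kpcofgs])__(.*)$", p))[[1]]
      if (length(m) == 3 && m[2] %in% names(ranks))
        out[i, ranks[[m[2]]]] <- m[3]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Construct a validated expression matrix
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param value_kind `"raw_count"` (non-negative integers enforced) or
#'   `"standardized"` (real-valued, e.g. after z-scoring).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, value_kind = c("raw_count", "standardized")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample row names and gene column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (value_kind == "raw_count") {
    if (any(!is.finite(values) | values < 0))
      stop("raw counts must be finite and non-negative")
  }
  structure(list(values = values, value_kind = value_kind),
            class = "expression_matrix")
}

#' Construct sample metadata for the 2x2 alcohol x feeding-time design
#'
#' `X1` is the alcohol indicator (1 = alcohol, 0 = water); `X2` is the
#' wrong-time-feeding indicator (1 = WTF, food during the rest phase;
#' 0 = RTF). The group label is derived deterministically from (X1, X2).
#'
#' @param sample_id character vector of unique sample ids.
#' @param X1,X2 binary vectors (0/1) of the two treatment factors.
#' @param cohort `"microbiome"` or `"expression"` per sample.
#' @return data.frame of class `sample_metadata` with columns
#'   `sample_id`, `X1`, `X2`, `group`, `cohort`.
#' @export
sample_metadata <- function(sample_id, X1, X2, cohort) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id in metadata: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  X1 <- as.integer(X1); X2 <- as.integer(X2)
  if (!all(X1 %in% 0:1) || !all(X2 %in% 0:1))
    stop("X1 and X2 must be coded 0/1")
  cohort <- as.character(cohort)
  if (!all(cohort %in% c("microbiome", "expression")))
    stop("cohort must be 'microbiome' or 'expression'")
  md <- data.frame(sample_id = sample_id, X1 = X1, X2 = X2,
                   group = group_label(X1, X2), cohort = cohort,
                   stringsAsFactors = FALSE)
  rownames(md) <- md$sample_id
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Derive the treatment-group label from the two binary factors
#' @param X1,X2 binary treatment indicators.
#' @return character vector among `water+RTF`, `water+WTF`, `alcohol+RTF`,
#'   `alcohol+WTF`.
#' @export
group_label <- function(X1, X2) {
  paste0(ifelse(X1 == 1, "alcohol", "water"), "+", ifelse(X2 == 1, "WTF", "RTF"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, total reads %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d samples x %d genes\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---- readers / writers -----------------------------------------------------

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read an OTU count table and its taxonomy map from TSV files
#'
#' The count file has one header row; the first column holds row labels.
#' Orientation is normalized to samples x OTUs: if the row labels are the
#' OTU ids known to the taxonomy file the matrix is transposed (and a
#' message is emitted).
#'
#' @param path count TSV.
#' @param taxonomy_path two-column TSV mapping `otu_id` to `lineage`.
#' @return validated [otu_table()].
#' @export
read_otu_table <- function(path, taxonomy_path) {
  m <- read_tsv_matrix(path)
  tax <- utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tax)[1:2] <- c("otu_id", "lineage")
  n_row_hit <- sum(rownames(m) %in% tax$otu_id)
  n_col_hit <- sum(colnames(m) %in% tax$otu_id)
  if (n_row_hit > n_col_hit) {
    message("read_otu_table: row labels look like OTU ids; transposing to samples x OTUs")
    m <- t(m)
  }
  otu_table(m, tax)
}

#' Write an OTU table (counts + taxonomy) as TSV
#' @param x an [otu_table()].
#' @param path count TSV destination.
#' @param taxonomy_path taxonomy TSV destination.
#' @return invisibly, `x`.
#' @export
write_otu_table <- function(x, path, taxonomy_path) {
  write_tsv_matrix(x$counts, path, id_col = "sample_id")
  utils::write.table(x$taxonomy[, c("otu_id", "lineage")], taxonomy_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

write_tsv_matrix <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene expression matrix from TSV
#' @param path TSV with header; first column sample ids (or gene ids, in
#'   which case the matrix is transposed based on a heuristic: gene axes are
#'   usually much longer than sample axes only when rows are genes).
#' @param value_kind passed to [expression_matrix()].
#' @param transpose set `TRUE` if the file stores genes in rows.
#' @return validated [expression_matrix()].
#' @export
read_expression_matrix <- function(path, value_kind = "raw_count", transpose = FALSE) {
  m <- read_tsv_matrix(path)
  if (transpose) m <- t(m)
  expression_matrix(m, value_kind)
}

#' Write an expression matrix as TSV
#' @param x an [expression_matrix()].
#' @param path destination.
#' @return invisibly, `x`.
#' @export
write_expression_matrix <- function(x, path) {
  write_tsv_matrix(x$values, path)
  invisible(x)
}

#' Read sample metadata from TSV
#'
#' Factors may be pre-coded 0/1 in columns `X1`, `X2`, or given as named
#' levels in columns `alcohol` and `feeding` translated through
#' `factor_map` — coding is never inferred silently.
#'
#' @param path TSV with a `sample_id` column and a `cohort` column.
#' @param factor_map list with elements `alcohol` and `feeding`, each a
#'   named 0/1 vector, e.g. `list(alcohol = c(water = 0, alcohol = 1),
#'   feeding = c(RTF = 0, WTF = 1))`. Ignored when X1/X2 are present.
#' @return [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path, factor_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a 'sample_id' column")
  if (!"cohort" %in% names(df)) stop("metadata needs a 'cohort' column")
  if (all(c("X1", "X2") %in% names(df))) {
    X1 <- df$X1; X2 <- df$X2
  } else {
    if (is.null(factor_map))
      stop("metadata has named factor levels; supply factor_map to code X1/X2")
    if (!all(c("alcohol", "feeding") %in% names(df)))
      stop("metadata needs X1/X2 or alcohol/feeding columns")
    unk1 <- setdiff(unique(df$alcohol), names(factor_map$alcohol))
    unk2 <- setdiff(unique(df$feeding), names(factor_map$feeding))
    if (length(unk1) || length(unk2))
      stop("factor level(s) not in factor_map: ",
           paste(c(unk1, unk2), collapse = ", "))
    X1 <- unname(factor_map$alcohol[df$alcohol])
    X2 <- unname(factor_map$feeding[df$feeding])
  }
  sample_metadata(df$sample_id, X1, X2, df$cohort)
}

#' Write sample metadata as TSV
#' @param md a [sample_metadata()] data.frame.
#' @param path destination.
#' @return invisibly, `md`.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(as.data.frame(md), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(md)
}

#' Check that every sample in a data table has exactly one metadata row
#' @param sample_ids sample ids present in a data table.
#' @param md metadata.
#' @return invisibly TRUE; errors otherwise.
#' @export
check_metadata_join <- function(sample_ids, md) {
  missing <- setdiff(sample_ids, md$sample_id)
  if (length(missing) > 0)
    stop("sample(s) with no metadata row: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Parse a flat YAML-style key-value config file
#'
#' Supports the subset `key: value` with `#` comments and blank lines;
#' values are coerced to numeric when they parse as numbers, and comma
#' separated values become vectors. Nested structure is not supported.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num) && length(parts) > 0) num else parts
  }
  out
}
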