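# Internal helpers shared across modules.

# Convert an OTU tibble (sample_id + one numeric column per OTU) to a matrix
# with sample ids as rownames. Accepts a matrix unchanged.
otu_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(rownames(table))) {
      rownames(table) <- paste0("S", seq_len(nrow(table)))
    }
    return(table)
  }
  stopifnot(is.data.frame(table))
  id_col <- if ("sample_id" %in% names(table)) "sample_id" else names(table)[1]
  ids <- as.character(table[[id_col]])
  m <- as.matrix(table[setdiff(names(table), id_col)])
  if (!is.numeric(m)) {
    abort("OTU table must contain only numeric columns besides 'sample_id'.")
  }
  rownames(m) <- ids
  m
}

otu_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

validate_otu_table <- function(table, require_integer = TRUE) {
  m <- otu_matrix(table)
  if (anyDuplicated(rownames(m))) abort("Duplicate sample ids in OTU table.")
  if (anyDuplicated(colnames(m))) abort("Duplicate OTU ids in OTU table.")
  if (any(!is.finite(m))) abort("OTU counts must be finite.")
  if (any(m < 0)) abort("OTU counts must be non-negative.")
  if (require_integer && any(abs(m - round(m)) > 1e-8)) {
    abort("OTU counts must be integers.")
  }
  invisible(m)
}

# Permutation p-value with the add-one estimator.
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.")
  }
  as.integer(seed)
}

# midrank transform, column-wise, for Spearman machinery
rank_cols <- function(m) {
  apply(m, 2, rank, ties.method = "average")
}
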