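# Readers for the pipeline's tabular inputs.

#' Read an OTU count table
#'
#' TSV with the first column holding sample ids (or, with
#' `transposed = TRUE`, the first column holding OTU ids and one column per
#' sample). Cells must be non-negative integers.
#'
#' @param path path to the TSV file.
#' @param transposed table is OTUs x samples (default `FALSE`).
#' @return OTU tibble (`sample_id` + one integer column per OTU).
#' @export
read_otu_table <- function(path, transposed = FALSE) {
  if (!file.exists(path)) abort(paste("OTU table not found:", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(raw[-1])
  rownames(m) <- as.character(raw[[1]])
  if (transposed) m <- t(m)
  storage.mode(m) <- "numeric"
  validate_otu_table(m)
  out <- otu_tibble(m)
  names(out)[1] <- "sample_id"
  out
}

#' Read a sample metadata table
#'
#' TSV with a `sample_id` column, a group column and environmental
#' covariates.
#'
#' @param path path to the TSV file.
#' @return metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste("Metadata file not found:", path))
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(meta)) {
    names(meta)[1] <- "sample_id"
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) abort("Duplicate sample ids in metadata.")
  meta
}

#' Read an OTU taxonomy table
#'
#' Two-column TSV `otu_id<TAB>lineage`.
#'
#' @param path path to the TSV file.
#' @return tibble `otu_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_names = c("otu_id", "lineage"), skip = 0)
  if (identical(raw$otu_id[1], "otu_id")) raw <- raw[-1, ]
  raw
}

# distance matrix as a square TSV with ids
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  readr::write_tsv(as_tibble(m, rownames = "sample_id"), path)
}
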