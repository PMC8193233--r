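# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

# Build a plate-series tibble from per-substrate differential absorbances.
# `diffs` is a named vector (substrate_id -> intended A590 - A750 per well);
# `control` is the same for the water wells. One value per timepoint can be
# given as a function diffs_at(t) instead.
plate_from_diffs <- function(diffs, control = 0.3, times = 72,
                             sample_id = "S1", layout = eco_layout(),
                             base750 = 0.2) {
  stopifnot(all(names(diffs) %in% layout$substrate_id))
  well_map <- tibble::tibble(
    substrate_id = rep(layout$substrate_id, lengths(layout$wells)),
    is_control = rep(layout$is_control, lengths(layout$wells)),
    well = unlist(layout$wells)
  )
  rows <- lapply(times, function(t) {
    d <- ifelse(well_map$is_control, control,
                unname(diffs[well_map$substrate_id]))
    d[is.na(d)] <- 0
    tibble::tibble(
      sample_id = sample_id, time_h = t,
      wavelength = rep(c(590L, 750L), each = nrow(well_map)),
      well = rep(well_map$well, 2),
      od = c(base750 + d, rep(base750, nrow(well_map)))
    )
  })
  plate_series(dplyr::bind_rows(rows), layout = layout)
}

# A color_response tibble for a single sample, straight from clamped values.
response_from_values <- function(values, sample_id = "S1", time_h = 72) {
  ids <- names(values) %||% sprintf("sub%02d", seq_along(values))
  out <- tibble::tibble(
    sample_id = sample_id, time_h = time_h, substrate_id = ids,
    guild = NA_character_, raw_ci = values + 0.3, control_value = 0.3,
    value = pmax(values, 0)
  )
  class(out) <- c("color_response", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small OTU tibble from a counts matrix.
otu_tbl <- function(m, samples = NULL, otus = NULL) {
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- otus %||% paste0("OTU", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "sample_id")
}

# Exhaustive betweenness by enumerating all shortest paths between every
# vertex pair (independent of igraph::betweenness).
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  b <- numeric(n)
  dmat <- igraph::distances(g)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(dmat[s, t]) || dmat[s, t] == 0) next
      paths <- igraph::all_simple_paths(g, from = s, to = t,
                                        cutoff = dmat[s, t])
      short <- Filter(function(p) length(p) - 1 == dmat[s, t], paths)
      if (!length(short)) next
      inner <- lapply(short, function(p) setdiff(as.integer(p), c(s, t)))
      counts <- table(unlist(inner))
      if (length(counts)) {
        idx <- as.integer(names(counts))
        b[idx] <- b[idx] + as.numeric(counts) / length(short)
      }
    }
  }
  b
}

# Random simple graph with n nodes; guarantees at least one edge.
random_small_graph <- function(n, p = 0.5) {
  repeat {
    m <- matrix(stats::rbinom(n * n, 1, p), n, n)
    m[lower.tri(m, diag = TRUE)] <- 0
    g <- igraph::graph_from_adjacency_matrix(m + t(m), mode = "undirected")
    if (igraph::ecount(g) > 0) return(g)
  }
}

# Tiny scenario used by the pipeline tests: fast but exercises every stage.
tiny_scenario <- function(seed = 11) {
  scenario_config(
    n_groups = 3, samples_per_group = 6, n_otus = 120, depth_mean = 2000,
    n_modules = 2, module_size = 6, module_correlation = 0.9,
    n_indicators_per_group = 2, indicator_fold = 8, seed = seed
  )
}
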