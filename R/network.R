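# Spearman/FDR co-occurrence network over abundant OTUs and environmental
# variables: construction, topology, Erdos-Renyi null ensemble, keystones.

#' Filter OTUs by relative abundance
#'
#' Keeps OTUs whose relative abundance across samples exceeds
#' `threshold_fraction` (default 0.1%). The default rule compares the MEAN
#' per-sample relative abundance; `"all"` and `"any"` require the threshold
#' in every / at least one sample.
#'
#' @param table OTU tibble or matrix of counts.
#' @param threshold_fraction abundance threshold in `(0, 1)`, default 0.001.
#' @param rule `"mean"` (default), `"all"` or `"any"`.
#' @return filtered OTU tibble (same sample rows, fewer OTU columns).
#' @export
filter_abundant <- function(table, threshold_fraction = 0.001,
                            rule = c("mean", "all", "any")) {
  rule <- match.arg(rule)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must be in (0, 1).")
  }
  m <- validate_otu_table(table, require_integer = FALSE)
  rel <- m / rowSums(m)
  keep <- switch(rule,
    mean = colMeans(rel) > threshold_fraction,
    all = apply(rel, 2, function(x) all(x > threshold_fraction)),
    any = apply(rel, 2, function(x) any(x > threshold_fraction))
  )
  if (!any(keep)) {
    abort(sprintf(
      "No OTU passes the %s relative-abundance threshold %g; max observed %.3g.",
      rule, threshold_fraction, max(colMeans(rel))))
  }
  otu_tibble(m[, keep, drop = FALSE])
}

#' Relative abundances
#'
#' Per-sample closure of an OTU count table to relative abundances.
#'
#' @param table OTU tibble or matrix of counts.
#' @return tibble of relative abundances.
#' @export
relative_abundance <- function(table) {
  m <- validate_otu_table(table, require_integer = FALSE)
  otu_tibble(m / rowSums(m))
}

#' Spearman correlation screen over OTU and environmental columns
#'
#' Computes Spearman rho and its t-approximation p-value for every unordered
#' pair of columns (OTU-OTU, OTU-environment and environment-environment),
#' then Benjamini-Hochberg q-values over ALL tested pairs as one family.
#' Constant columns are excluded with a warning before testing.
#'
#' @param table OTU tibble of relative abundances (or counts; Spearman is
#'   rank-based).
#' @param env optional samples x environmental-variables tibble/matrix,
#'   aligned with `table` by `sample_id` when both carry ids.
#' @return object of class `cor_screen`: list with matrices `rho`, `p`, `q`
#'   and a `kind` vector (`"otu"`/`"env"`) over the screened columns.
#' @export
correlation_screen <- function(table, env = NULL) {
  m <- otu_matrix(table)
  if (nrow(m) < 5) abort("Correlation screen needs >= 5 samples.")
  kind <- rep("otu", ncol(m))
  if (!is.null(env)) {
    e <- otu_matrix(env)
    if (!is.null(rownames(e)) && !is.null(rownames(m)) &&
        all(rownames(m) %in% rownames(e))) {
      e <- e[rownames(m), , drop = FALSE]
    } else if (nrow(e) != nrow(m)) {
      abort("`env` rows do not match the OTU table samples.")
    }
    m <- cbind(m, e)
    kind <- c(kind, rep("env", ncol(e)))
  }
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    warn(paste("Excluding constant column(s):",
               paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
    kind <- kind[!const]
  }
  if (ncol(m) < 2) abort("Fewer than 2 usable columns to correlate.")
  n <- nrow(m)
  r <- rank_cols(m)
  rho <- cor(r)
  p <- spearman_p(rho, n)
  diag(p) <- 1
  ut <- upper.tri(rho)
  q <- matrix(1, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  q[ut] <- bh_fdr(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(
    list(rho = rho, p = p, q = q,
         kind = setNames(kind, colnames(m)), n_samples = n),
    class = "cor_screen"
  )
}

#' Build the thresholded co-occurrence network
#'
#' Draws an undirected edge between two nodes iff `|rho| > r_threshold` AND
#' `q < q_threshold` (both strict). Nodes left without any edge are dropped
#' from the graph but counted in the graph attribute `n_isolated`.
#'
#' @param screen a `cor_screen` object (or a plain rho matrix, then `q` must
#'   be supplied).
#' @param q optional q-value matrix when `screen` is a plain matrix.
#' @param r_threshold absolute-correlation threshold (default 0.7).
#' @param q_threshold FDR threshold (default 0.01).
#' @return an `igraph` graph with node attributes `name`, `kind` and edge
#'   attributes `rho`, `q`, `sign`; thresholds and isolated-node count are
#'   graph attributes.
#' @export
build_network <- function(screen, q = NULL, r_threshold = 0.7,
                          q_threshold = 0.01) {
  if (inherits(screen, "cor_screen")) {
    rho <- screen$rho; qm <- screen$q
    kind <- screen$kind
  } else {
    rho <- screen; qm <- q
    if (is.null(qm)) abort("Supply a q-value matrix with a plain rho matrix.")
    kind <- setNames(rep("otu", ncol(rho)),
                     colnames(rho) %||% paste0("V", seq_len(ncol(rho))))
  }
  stopifnot(all(dim(rho) == dim(qm)))
  ids <- names(kind)
  ut <- which(upper.tri(rho) & abs(rho) > r_threshold & qm < q_threshold,
              arr.ind = TRUE)
  if (nrow(ut) == 0) {
    near <- which(upper.tri(rho), arr.ind = TRUE)
    best <- near[which.max(abs(rho[near]) - qm[near]), , drop = FALSE]
    abort(sprintf(
      "No edge passes |rho| > %g and q < %g (closest pair: %s-%s, rho = %.3f, q = %.3g).",
      r_threshold, q_threshold, ids[best[1]], ids[best[2]],
      rho[best], qm[best]))
  }
  rho_e <- rho[ut]
  edges <- tibble(
    source = ids[ut[, 1]], target = ids[ut[, 2]],
    rho = rho_e, q = qm[ut],
    sign = ifelse(rho_e > 0, "positive", "negative")
  ) |>
    arrange(.data$source, .data$target)
  connected <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble(name = connected, kind = unname(kind[connected]))
  )
  g <- igraph::set_graph_attr(g, "r_threshold", r_threshold)
  g <- igraph::set_graph_attr(g, "q_threshold", q_threshold)
  g <- igraph::set_graph_attr(g, "n_isolated", length(ids) - length(connected))
  g
}

#' Node-level topology
#'
#' Degree, betweenness (Brandes, unnormalised pair counts on unweighted
#' shortest paths), closeness (Wasserman-Faust, computed within connected
#' components and scaled by component reach) and eigenvector centrality
#' (power iteration on the largest component, max-normalised; zero
#' elsewhere).
#'
#' @param g an `igraph` graph from [build_network()].
#' @return tibble `node`, `kind`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
node_topology <- function(g) {
  if (igraph::vcount(g) == 0) abort("Empty graph.")
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  dmat <- igraph::distances(g)
  closeness <- vapply(seq_len(n), function(v) {
    members <- which(comp$membership == comp$membership[v])
    k <- length(members)
    if (k < 2) return(0)
    tot <- sum(dmat[v, members])
    ((k - 1) / max(n - 1, 1)) * ((k - 1) / tot)
  }, numeric(1))
  eig <- numeric(n)
  giant <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, giant)
  eig[giant] <- power_iteration_centrality(sub)
  kind <- igraph::vertex_attr(g, "kind") %||% rep("otu", n)
  tibble(
    node = igraph::V(g)$name,
    kind = kind,
    degree = as.integer(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = FALSE)),
    closeness = closeness,
    eigenvector = eig
  )
}

# deterministic power iteration for eigenvector centrality, max-normalised
power_iteration_centrality <- function(g, tol = 1e-12, max_iter = 10000) {
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  nv <- nrow(a)
  if (nv == 1) return(1)
  v <- rep(1 / sqrt(nv), nv)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(a %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(rep(0, nv))  # no edges
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v / max(v)
}

# mean local clustering over nodes with degree >= 2; in G(n, m) its
# expectation is the edge probability m / (n(n-1)/2)
local_clustering <- function(g) {
  lc <- igraph::transitivity(g, type = "local")
  lc <- lc[is.finite(lc)]
  if (!length(lc)) return(0)
  mean(lc)
}

#' Graph-level topology
#'
#' Average degree, graph density, mean local clustering coefficient over
#' nodes of degree >= 2, average path length and diameter over the
#' largest connected component, and the modularity of the (deterministic)
#' greedy agglomerative partition.
#'
#' @param g an `igraph` graph.
#' @param modules logical; compute the greedy modularity partition
#'   (default `TRUE`).
#' @return object of class `graph_topology`: list with the scalar metrics,
#'   `n_nodes`, `n_edges`, `n_modules`, `module_of` (named integer vector)
#'   and `component_coverage` (fraction of nodes in the largest component).
#' @export
graph_topology <- function(g, modules = TRUE) {
  n <- igraph::vcount(g)
  if (n == 0) abort("Empty graph.")
  m <- igraph::ecount(g)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  path_ok <- igraph::vcount(giant) > 1
  part <- NULL
  modv <- NA_real_
  module_of <- setNames(rep(NA_integer_, n), igraph::V(g)$name)
  if (modules && m > 0) {
    part <- igraph::cluster_fast_greedy(g)
    modv <- igraph::modularity(part)
    module_of <- setNames(igraph::membership(part), igraph::V(g)$name)
  }
  structure(
    list(
      n_nodes = n,
      n_edges = m,
      avg_degree = 2 * m / n,
      graph_density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
      clustering_coefficient = local_clustering(g),
      avg_path_length = if (path_ok) igraph::mean_distance(giant) else NA_real_,
      diameter = if (path_ok) igraph::diameter(giant) else NA_real_,
      modularity = modv,
      n_modules = if (!is.null(part)) length(unique(module_of)) else NA_integer_,
      module_of = module_of,
      component_coverage = max(comp$csize) / n
    ),
    class = "graph_topology"
  )
}

#' @export
print.graph_topology <- function(x, ...) {
  cat(sprintf(
    "Graph: %d nodes, %d edges | avg degree %.2f, density %.3f\n",
    x$n_nodes, x$n_edges, x$avg_degree, x$graph_density))
  cat(sprintf(
    "clustering %.3f, path length %.3f, diameter %s, modularity %.3f (%s modules)\n",
    x$clustering_coefficient, x$avg_path_length, format(x$diameter),
    x$modularity, format(x$n_modules)))
  invisible(x)
}

#' @method glance graph_topology
#' @export
glance.graph_topology <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges, avg_degree = x$avg_degree,
    graph_density = x$graph_density,
    clustering_coefficient = x$clustering_coefficient,
    avg_path_length = x$avg_path_length, diameter = x$diameter,
    modularity = x$modularity, n_modules = x$n_modules,
    component_coverage = x$component_coverage
  )
}

#' Erdos-Renyi null ensemble for graph topology
#'
#' Compares the observed graph against `n_reps` G(n, m) random graphs with
#' identical node and edge counts: every replicate has exactly the observed
#' number of edges. Reports the null mean, SD and the z-score of each
#' observed metric.
#'
#' @param g observed `igraph` graph.
#' @param n_reps number of random replicates (default 1000; >= 100 for
#'   stable z-scores).
#' @param seed integer seed.
#' @param modules also compare modularity (default `TRUE`; the costliest
#'   metric).
#' @return object of class `null_ensemble`: tibble `summary` with columns
#'   `metric`, `observed`, `null_mean`, `null_sd`, `z`, plus `n_reps`,
#'   `seed`.
#' @export
er_null_ensemble <- function(g, n_reps = 1000, seed = 1, modules = TRUE) {
  seed <- check_seed(seed)
  if (n_reps < 100) warn("Fewer than 100 replicates; z-scores will be noisy.")
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m > n * (n - 1) / 2) abort("More edges than a simple graph allows.")
  metrics <- c("avg_degree", "avg_path_length", "clustering_coefficient",
               "graph_density", "diameter",
               if (modules) "modularity")
  topo_vec <- function(gr) {
    t <- graph_topology(gr, modules = modules)
    vapply(metrics, function(k) as.numeric(t[[k]]), numeric(1))
  }
  obs <- topo_vec(g)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(b) {
      topo_vec(igraph::sample_gnm(n, m, directed = FALSE))
    }, numeric(length(metrics)))
  })
  nulls <- matrix(nulls, nrow = length(metrics),
                  dimnames = list(metrics, NULL))
  mu <- rowMeans(nulls, na.rm = TRUE)
  sdv <- apply(nulls, 1, sd, na.rm = TRUE)
  structure(
    list(
      summary = tibble(
        metric = metrics,
        observed = unname(obs),
        null_mean = unname(mu),
        null_sd = unname(sdv),
        z = unname(ifelse(sdv > 0, (obs - mu) / sdv, NA_real_))
      ),
      n_reps = n_reps, seed = seed
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Erdos-Renyi null ensemble (", x$n_reps, " replicates)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) x$summary

#' Power-law check of the degree distribution
#'
#' Least-squares fit of `log(frequency)` against `log(degree)` over the
#' positive-frequency, positive-degree part of the degree histogram.
#'
#' @param g an `igraph` graph with at least 3 distinct positive degrees.
#' @return tibble with `exponent` (the negated slope), `slope`, `r2`,
#'   `n_points`.
#' @export
degree_powerlaw_check <- function(g) {
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(k) < 3) {
    abort("Fewer than 3 distinct positive degrees; power-law fit meaningless.")
  }
  fit <- lm(log(freq) ~ log(k))
  tibble(
    exponent = -unname(coef(fit)[2]),
    slope = unname(coef(fit)[2]),
    r2 = summary(fit)$r.squared,
    n_points = length(k)
  )
}

#' Keystone nodes by betweenness centrality
#'
#' OTU nodes ranked by betweenness (descending), ties broken by degree then
#' lexicographic node id; environmental nodes are excluded from the ranking.
#'
#' @param topo a node topology tibble from [node_topology()].
#' @param k number of keystones to return (default 10).
#' @return tibble of the top `k` OTU nodes with `rank` prepended.
#' @export
keystones <- function(topo, k = 10) {
  if (k < 1) abort("`k` must be >= 1.")
  otus <- filter(topo, .data$kind == "otu")
  if (k > nrow(otus)) {
    warn(sprintf("Only %d OTU nodes available; returning all.", nrow(otus)))
    k <- nrow(otus)
  }
  otus |>
    arrange(desc(.data$betweenness), desc(.data$degree), .data$node) |>
    head(k) |>
    mutate(rank = dplyr::row_number(), .before = 1)
}
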