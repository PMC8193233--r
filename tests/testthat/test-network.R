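# Abundance filter, correlation screen, network construction and topology,
# Erdos-Renyi nulls, power-law check, keystones.

test_that("abundance filter applies the mean/all/any rules correctly", {
  tbl <- otu_tbl(rbind(c(500, 499, 1), c(500, 499, 1)))
  kept <- filter_abundant(tbl, 0.001)
  expect_setequal(names(kept)[-1], c("OTU1", "OTU2"))

  # all-zero OTU removed; dominant OTU retained
  tbl2 <- otu_tbl(rbind(c(50, 0, 50), c(60, 0, 40)))
  expect_false("OTU2" %in% names(filter_abundant(tbl2, 0.001)))

  # 3-sample toy straddling 0.1%: mean decides (hand oracle)
  m <- rbind(c(3, 997), c(1, 999), c(1, 999)) * 1
  colnames(m) <- c("lo", "hi")
  rel_mean <- colMeans(m / rowSums(m))   # lo: ~0.00167 > 0.001
  tbl3 <- otu_tbl(m, otus = c("lo", "hi"))
  expect_true(all(c("lo", "hi") %in% names(filter_abundant(tbl3, 0.001))))
  expect_true(rel_mean["lo"] > 0.001)
  # the "all" rule drops it (one sample at 0.1% exactly is not > 0.1%)
  expect_false("lo" %in% names(filter_abundant(tbl3, 0.001, rule = "all")))
  expect_true("lo" %in% names(filter_abundant(tbl3, 0.002, rule = "any")))
  expect_error(filter_abundant(tbl3, 0.999), "No OTU passes")
})

test_that("correlation screen computes Spearman over all pairs, one FDR family", {
  set.seed(20)
  m <- matrix(rpois(8 * 3, 20), 8, 3)
  m <- cbind(m, m[, 1])  # duplicated column
  tbl <- otu_tbl(m)
  sc <- suppressWarnings(correlation_screen(tbl))
  expect_equal(sc$rho["OTU1", "OTU4"], 1)

  # 6-sample pair equals the exact rank formula (no ties)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  d2 <- sum((rank(x) - rank(y))^2)
  sc2 <- correlation_screen(otu_tbl(cbind(x, y, rnorm(6)),
                                    otus = c("x", "y", "z")))
  expect_equal(sc2$rho["x", "y"], 1 - 6 * d2 / (6 * 35), tolerance = 1e-12)

  # constant columns are excluded with a warning
  expect_warning(
    sc3 <- correlation_screen(otu_tbl(cbind(rnorm(6), rep(2, 6), rnorm(6)))),
    "constant")
  expect_equal(ncol(sc3$rho), 2)

  # env columns aligned by sample id and tagged
  env <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(paste0("S", 1:8),
                                                    c("WT", "PWT")))
  sce <- correlation_screen(tbl, env = env)
  expect_equal(unname(sce$kind[c("OTU1", "WT")]), c("otu", "env"))
  expect_error(correlation_screen(otu_tbl(matrix(rnorm(8), 4, 2))), ">= 5")
})

test_that("null correlation screen p-values are calibrated", {
  set.seed(21)
  m <- matrix(rnorm(30 * 60), 30, 60)
  sc <- correlation_screen(otu_tbl(m))
  p <- sc$p[upper.tri(sc$p)]
  # ~1% of raw p below 0.01 under independence
  expect_lt(abs(mean(p < 0.01) - 0.01), 0.01)
})

test_that("network edges require |rho| > r AND q < q, strictly", {
  ids <- c("a", "b", "c")
  rho <- matrix(0, 3, 3, dimnames = list(ids, ids))
  q <- matrix(1, 3, 3, dimnames = list(ids, ids))
  rho[1, 2] <- rho[2, 1] <- 0.71; q[1, 2] <- q[2, 1] <- 0.005  # edge
  rho[1, 3] <- rho[3, 1] <- 0.70; q[1, 3] <- q[3, 1] <- 0.001  # rho at bound
  rho[2, 3] <- rho[3, 2] <- 0.90; q[2, 3] <- q[3, 2] <- 0.02   # q fails
  g <- build_network(rho, q)
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::as_data_frame(g)
  expect_setequal(unlist(e[c("from", "to")]), c("a", "b"))
  expect_equal(e$rho, 0.71)
  expect_equal(e$sign, "positive")
  expect_equal(igraph::graph_attr(g, "n_isolated"), 1)

  q[2, 3] <- q[3, 2] <- 1
  q[1, 2] <- q[2, 1] <- 1
  expect_error(build_network(rho, q), "No edge passes")
})

test_that("network construction is invariant to node input order", {
  set.seed(22)
  m <- matrix(rnorm(20 * 6), 20, 6)
  m[, 2] <- m[, 1] + rnorm(20, sd = 0.1)
  m[, 4] <- m[, 3] + rnorm(20, sd = 0.1)
  tbl <- otu_tbl(m)
  edge_key <- function(g) {
    e <- igraph::as_data_frame(g)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  g1 <- build_network(correlation_screen(tbl), r_threshold = 0.6,
                      q_threshold = 0.05)
  perm <- tbl[, c(1, sample(2:7))]
  g2 <- build_network(correlation_screen(perm), r_threshold = 0.6,
                      q_threshold = 0.05)
  expect_identical(edge_key(g1), edge_key(g2))
})

test_that("node topology: path, star and the degree-sum identity", {
  path <- igraph::make_graph(~ a - b, b - c)
  nt <- node_topology(path)
  expect_equal(nt$betweenness[nt$node == "b"], 1)
  expect_equal(nt$betweenness[nt$node == "a"], 0)
  expect_equal(sum(nt$degree), 2 * igraph::ecount(path))

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  ns <- node_topology(star)
  expect_equal(ns$degree[ns$node == "hub"], 5)
  expect_true(all(ns$betweenness[ns$node != "hub"] == 0))
  expect_equal(ns$eigenvector[ns$node == "hub"], 1)  # max-normalised
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(23)
  for (i in 1:20) {
    g <- random_small_graph(sample(4:7, 1))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    nt <- node_topology(g)
    expect_equal(nt$betweenness, brute_betweenness(g), tolerance = 1e-10)
  }
})

test_that("graph topology closed forms: triangle, path, planted modules", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  gt <- graph_topology(tri)
  expect_equal(gt$graph_density, 1)
  expect_equal(gt$clustering_coefficient, 1)
  expect_equal(gt$diameter, 1)

  path <- igraph::make_graph(~ a - b, b - c)
  gp <- graph_topology(path)
  expect_equal(gp$avg_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(gp$diameter, 2)
  expect_equal(gp$graph_density, 2 / 3, tolerance = 1e-12)
  expect_equal(gp$avg_degree, 4 / 3, tolerance = 1e-12)

  # two 4-cliques joined by one bridge: greedy modularity separates them
  k4a <- igraph::make_full_graph(4)
  k4b <- igraph::make_full_graph(4)
  g2 <- igraph::disjoint_union(k4a, k4b)
  g2 <- igraph::add_edges(g2, c(1, 5))
  igraph::V(g2)$name <- paste0("n", 1:8)
  gm <- graph_topology(g2)
  expect_equal(gm$n_modules, 2)
  expect_gt(gm$modularity, 0.3)
  expect_equal(unname(gm$module_of["n1"]), unname(gm$module_of["n4"]))
  expect_false(gm$module_of[["n1"]] == gm$module_of[["n5"]])
})

test_that("Erdos-Renyi ensemble conserves edges and matches ER expectations", {
  g <- igraph::sample_gnm(40, 80)
  igraph::V(g)$name <- paste0("v", 1:40)
  ne <- suppressWarnings(er_null_ensemble(g, n_reps = 150, seed = 4))
  s <- ne$summary
  expect_equal(s$null_sd[s$metric == "avg_degree"], 0)     # fixed m
  expect_equal(s$null_mean[s$metric == "avg_degree"], 2 * 80 / 40)
  expect_equal(s$null_mean[s$metric == "graph_density"],
               s$observed[s$metric == "graph_density"])

  # planted modular graph scores a high modularity z
  k <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  k <- igraph::add_edges(k, c(1, 7, 7, 13))
  igraph::V(k)$name <- paste0("v", 1:18)
  nz <- er_null_ensemble(k, n_reps = 150, seed = 5)
  z_mod <- nz$summary$z[nz$summary$metric == "modularity"]
  expect_gt(z_mod, 2)
  expect_error(er_null_ensemble(igraph::make_full_graph(3), n_reps = 100),
               NA)
})

test_that("degree power-law fit recovers a constructed k^-2 histogram", {
  # degree frequencies 36:9:4 for degrees 1:2:3 (exact k^-2 ratios)
  degs <- c(rep(1, 36), rep(2, 9), rep(3, 4))
  g <- igraph::realize_degseq(degs)
  pl <- suppressWarnings(degree_powerlaw_check(g))  # exact fit warns in summary.lm
  expect_equal(pl$slope, -2, tolerance = 1e-10)
  expect_equal(pl$r2, 1, tolerance = 1e-10)

  ring <- igraph::make_ring(10)
  expect_error(degree_powerlaw_check(ring), "distinct positive degrees")

  # scale-free graph fits the log-log line better than an ER graph
  set.seed(24)
  pa <- igraph::sample_pa(200, m = 2, directed = FALSE)
  er <- igraph::sample_gnm(200, igraph::ecount(pa))
  expect_gt(degree_powerlaw_check(pa)$r2, degree_powerlaw_check(er)$r2)
})

test_that("keystones rank OTU nodes by betweenness with stated tie-breaks", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  ks <- keystones(node_topology(star), k = 1)
  expect_equal(ks$node, "hub")

  path5 <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  kp <- keystones(node_topology(path5), k = 1)
  expect_equal(kp$node, "c")

  # tie on betweenness broken by degree, then id; env nodes excluded
  tri <- igraph::make_full_graph(3)       # all betweenness 0
  g <- igraph::add_vertices(tri, 1)
  g <- igraph::add_edges(g, c(1, 4))      # node 1: degree 3
  igraph::V(g)$name <- c("b_node", "a_node", "c_node", "d_env")
  nt <- node_topology(g)
  nt$kind <- c("otu", "otu", "otu", "env")
  nt$betweenness <- c(0, 0, 0, 0)
  ks2 <- keystones(nt, k = 3)
  expect_equal(ks2$node[1], "b_node")              # highest degree
  expect_equal(ks2$node[2:3], c("a_node", "c_node"))  # then lexicographic
  expect_false("d_env" %in% ks2$node)
  expect_warning(keystones(nt, k = 10), "returning all")
})
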