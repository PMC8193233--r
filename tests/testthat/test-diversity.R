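# Rarefaction, alpha/beta diversity, PCoA, PERMANOVA, regressions.

test_that("rarefaction subsamples without replacement to exact depth", {
  tbl <- otu_tbl(rbind(c(10, 0), c(3, 9), c(7, 7)))
  r <- rarefy(tbl, 5, seed = 1)
  m <- as.matrix(r[-1])
  expect_true(all(rowSums(m) == 5))
  expect_equal(unlist(r[r$sample_id == "S1", -1], use.names = FALSE), c(5, 0))

  # depth == total: returned unchanged
  one <- otu_tbl(matrix(c(4, 6), 1))
  expect_equal(as.matrix(rarefy(one, 10, seed = 2)[-1]),
               matrix(c(4, 6), 1), ignore_attr = TRUE)

  # determinism and sub-depth samples dropped with a warning
  expect_identical(rarefy(tbl, 5, seed = 7), rarefy(tbl, 5, seed = 7))
  expect_warning(r2 <- rarefy(tbl, 11, seed = 1), "Dropping")
  expect_equal(nrow(r2), 2)
  expect_error(suppressWarnings(rarefy(tbl, 100, seed = 1)), "exceeds")
})

test_that("rarefaction matches the hypergeometric expectation", {
  tbl <- otu_tbl(matrix(c(5, 5), 1))
  draws <- vapply(1:2000, function(i) {
    as.integer(rarefy(tbl, 4, seed = i)[[2]])
  }, integer(1))
  # E = 2, Var = 4 * .5 * .5 * (10-4)/(10-1)
  se <- sqrt(4 * 0.25 * 6 / 9 / 2000)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("expected richness is nondecreasing in rarefaction depth", {
  set.seed(10)
  tbl <- otu_tbl(matrix(rpois(40, 3), 2, 20))
  obs_at <- function(depth) {
    mean(vapply(1:60, function(i) {
      mean(alpha_diversity(rarefy(tbl, depth, seed = i))$observed_otus)
    }, numeric(1)))
  }
  expect_lt(obs_at(5), obs_at(25))
})

test_that("alpha diversity closed forms: observed, Chao1, Shannon, Faith", {
  tbl <- otu_tbl(matrix(c(1, 1, 1), 1))
  a <- alpha_diversity(tbl)
  expect_equal(a$observed_otus, 3)
  expect_equal(a$shannon, log(3))

  # S = 10, F1 = 4, F2 = 2 -> chao1 = 10 + 16/4 = 14
  counts <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  a2 <- alpha_diversity(otu_tbl(matrix(counts, 1)))
  expect_equal(a2$chao1, 14)

  # F2 = 0 -> bias-corrected form S + F1(F1-1)/2
  counts3 <- c(rep(1, 3), rep(4, 2))
  expect_equal(alpha_diversity(otu_tbl(matrix(counts3, 1)))$chao1,
               5 + 3 * 2 / 2)
  # chao1 == observed when no singletons
  expect_equal(alpha_diversity(otu_tbl(matrix(c(3, 4, 5), 1)))$chao1, 3)

  # star tree with unit branches: PD of 3 present OTUs = 3
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tbl4 <- otu_tbl(matrix(c(2, 1, 5, 0), 1), otus = c("A", "B", "C", "D"))
  a4 <- alpha_diversity(tbl4, tree = tree)
  expect_equal(a4$faith_pd, 3)
  # full OTU set: PD equals the tree's total branch length
  tbl5 <- otu_tbl(matrix(c(2, 1, 5, 3), 1), otus = c("A", "B", "C", "D"))
  expect_equal(alpha_diversity(tbl5, tree = tree)$faith_pd,
               sum(tree$edge.length))
  # tree missing a present OTU errors with its name
  tbl6 <- otu_tbl(matrix(c(1, 1), 1), otus = c("A", "Zmissing"))
  expect_error(alpha_diversity(tbl6, tree = tree), "Zmissing")
  expect_error(alpha_diversity(otu_tbl(matrix(c(0, 0), 1))), "Empty sample")
})

test_that("beta distances match their closed forms", {
  tbl <- otu_tbl(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 1, 0)))
  bc <- as.matrix(beta_distance(tbl, "bray_curtis"))
  jc <- as.matrix(beta_distance(tbl, "jaccard"))
  expect_equal(bc[1, 2], 0.5)
  expect_equal(jc[1, 2], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(bc[1, 3], 0)
  expect_equal(jc[1, 3], 0)

  disjoint <- otu_tbl(rbind(c(3, 2, 0, 0), c(0, 0, 4, 1)))
  expect_equal(as.matrix(beta_distance(disjoint, "bray_curtis"))[1, 2], 1)
  expect_equal(as.matrix(beta_distance(disjoint, "jaccard"))[1, 2], 1)

  eu <- as.matrix(beta_distance(otu_tbl(rbind(c(0, 0), c(3, 4))), "euclidean"))
  expect_equal(eu[1, 2], 5)

  w <- capture_warnings(
    z <- beta_distance(otu_tbl(rbind(c(0, 0), c(0, 0), c(1, 2))),
                       "bray_curtis"))
  expect_true(any(grepl("All-zero", w)))
  expect_equal(as.matrix(z)[1, 2], 0)
})

test_that("PCoA reconstructs planar configurations up to rotation", {
  set.seed(11)
  pts <- matrix(rnorm(2 * 12), 12, 2)
  rownames(pts) <- paste0("S", 1:12)
  d <- beta_distance(pts, "euclidean")
  ord <- pcoa(d, k = 2)
  got <- as.matrix(ord$coordinates[-1])
  proc <- vegan::procrustes(pts, got, symmetric = FALSE)
  expect_lt(sum(proc$residuals^2), 1e-8)
  # Euclidean-embeddable: no meaningfully negative eigenvalues
  expect_true(all(ord$eigenvalues > -1e-10 * max(ord$eigenvalues)))

  # three equidistant samples: two equal positive eigenvalues
  dm <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  e <- pcoa(dm)$eigenvalues
  pos <- e[e > 1e-12]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-12)

  # duplicated samples: coincident coordinates
  dup <- otu_tbl(rbind(c(5, 1, 0), c(5, 1, 0), c(0, 3, 3)))
  co <- as.matrix(pcoa(beta_distance(dup, "bray_curtis"))$coordinates[-1])
  expect_lt(sqrt(sum((co[1, ] - co[2, ])^2)), 1e-7)
  expect_error(pcoa(dm, k = 0), ">= 1")
})

test_that("PERMANOVA separates planted clusters and matches vegan's F and R2", {
  set.seed(12)
  x <- rbind(matrix(rnorm(10 * 3), 10, 3),
             matrix(rnorm(10 * 3, mean = 10), 10, 3))
  rownames(x) <- paste0("S", 1:20)
  groups <- rep(c("a", "b"), each = 10)
  d <- beta_distance(x, "euclidean")
  pv <- permanova(d, groups, n_perm = 999, seed = 1)
  expect_equal(pv$p, 0.001)  # minimum achievable at 999 perms
  expect_gt(pv$R2, 0.9)

  # identical samples across groups: R2 ~ 0
  same <- otu_tbl(rbind(c(1, 2), c(2, 1), c(1, 2), c(2, 1)))
  d0 <- beta_distance(same, "euclidean")
  pv0 <- permanova(d0, c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_lt(pv0$R2, 0.35)
  expect_gt(pv0$p, 0.5)

  # independent oracle: vegan::adonis2 on a noisy dataset
  set.seed(13)
  y <- matrix(rnorm(18 * 4), 18, 4)
  rownames(y) <- paste0("S", 1:18)
  g3 <- rep(c("a", "b", "c"), each = 6)
  d3 <- beta_distance(abs(y), "bray_curtis")
  mine <- permanova(d3, g3, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(d3 ~ g3, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)

  expect_error(permanova(d0, c("a", "b", "b", "b"), n_perm = 99), ">= 2")
  expect_error(permanova(stats::as.dist(matrix(1, 4, 4) - diag(4)),
                         c("a", "a", "b", "b"), n_perm = 99),
               "Constant distance")
})

test_that("PERMANOVA p-values are reproducible and seed-sensitive", {
  set.seed(14)
  x <- matrix(rnorm(12 * 3), 12, 3)
  rownames(x) <- paste0("S", 1:12)
  d <- beta_distance(x, "euclidean")
  g <- rep(c("a", "b", "c"), each = 4)
  p1 <- permanova(d, g, n_perm = 199, seed = 5)$p
  p2 <- permanova(d, g, n_perm = 199, seed = 5)$p
  expect_identical(p1, p2)
})

test_that("OLS regression returns exact and calibrated estimates", {
  x <- 1:10
  fit <- suppressWarnings(regress_on_covariate(2 * x + 1, x))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)

  # orthogonalised residuals: slope 0
  set.seed(15)
  xx <- rnorm(30)
  yy <- rnorm(30)
  y_perp <- yy - coef(lm(yy ~ xx))[2] * xx
  expect_equal(regress_on_covariate(y_perp, xx)$slope, 0, tolerance = 1e-12)

  # n = 20 with known slope 0.5: estimate within 3 SE
  set.seed(16)
  x20 <- rnorm(20, sd = 2)
  y20 <- 0.5 * x20 + rnorm(20, sd = 1)
  f20 <- regress_on_covariate(y20, x20)
  se <- 1 / sqrt(sum((x20 - mean(x20))^2))
  expect_lt(abs(f20$slope - 0.5), 3 * se)

  expect_error(regress_on_covariate(1:5, rep(2, 5)), "Constant covariate")
  expect_error(regress_on_covariate(1:2, 1:2), ">= 3")
})
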