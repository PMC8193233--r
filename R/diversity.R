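# OTU-table diversity analysis: rarefaction, alpha/beta diversity, PCoA,
# PERMANOVA, diversity-covariate regressions.

#' Rarefy an OTU table to even depth
#'
#' Draws, for each sample, a uniform subsample WITHOUT replacement of exactly
#' `depth` reads (a single draw, not an average over draws). Samples whose
#' total count is below `depth` are dropped with a warning.
#'
#' @param table OTU tibble (`sample_id` + integer counts) or matrix.
#' @param depth target depth (reads per sample), >= 1.
#' @param seed integer seed controlling the subsampling.
#' @return rarefied OTU tibble; the seed and depth are attached as
#'   attributes `rarefaction_seed` / `rarefaction_depth`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  seed <- check_seed(seed)
  m <- validate_otu_table(table)
  if (depth < 1) abort("`depth` must be >= 1.")
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) abort("`depth` exceeds every sample total.")
  if (any(!keep)) {
    warn(sprintf("Dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth,
                 paste(rownames(m)[!keep], collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  r <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      # vegan advises when no singleton counts are present; not actionable here
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- otu_tibble(r)
  attr(out, "rarefaction_seed") <- seed
  attr(out, "rarefaction_depth") <- depth
  out
}

chao1_estimate <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2  # bias-corrected form with F2 = 0
}

#' Per-sample alpha diversity
#'
#' Observed OTUs, Chao1 richness, Shannon diversity (natural log by default)
#' and, when a tree is supplied, Faith's phylogenetic diversity (rooted:
#' includes the path to the root).
#'
#' Chao1 is `S + F1^2 / (2 F2)`; when no doubletons exist the bias-corrected
#' form `S + F1 (F1 - 1) / (2 (F2 + 1))` is used to avoid division by zero.
#'
#' @param table OTU tibble or matrix of integer counts.
#' @param tree optional `ape::phylo` tree whose tips cover every OTU present
#'   in each sample.
#' @param log_base base of the Shannon logarithm (default `exp(1)`).
#' @return tibble `sample_id`, `observed_otus`, `chao1`, `shannon`, and
#'   `faith_pd` when a tree is given.
#' @export
alpha_diversity <- function(table, tree = NULL, log_base = exp(1)) {
  m <- validate_otu_table(table)
  if (any(rowSums(m) == 0)) {
    abort(paste("Empty sample(s):",
                paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  }
  out <- tibble(
    sample_id = rownames(m),
    observed_otus = unname(rowSums(m > 0)),
    chao1 = unname(apply(m, 1, chao1_estimate)),
    shannon = unname(apply(m, 1, function(x) {
      p <- x[x > 0] / sum(x)
      -sum(p * log(p, base = log_base))
    }))
  )
  if (!is.null(tree)) {
    present <- colnames(m)[colSums(m) > 0]
    missing <- setdiff(present, tree$tip.label)
    if (length(missing)) {
      abort(paste("Tree is missing OTU(s) present in the table:",
                  paste(head(missing, 5), collapse = ", ")))
    }
    # rooted PD (path to the root included); trees with a basal polytomy are
    # unrooted in ape's sense, where the spanning-subtree form coincides
    pd <- picante::pd(m, tree, include.root = ape::is.rooted(tree))
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  out
}

#' Between-sample distance matrix
#'
#' Bray-Curtis (`sum |x - y| / sum (x + y)`), binary Jaccard
#' (`1 - |A intersect B| / |A union B|` on presence/absence) or Euclidean
#' distances between sample rows.
#'
#' @param table OTU tibble or numeric matrix (counts or any sample-by-variable
#'   data for `euclidean`).
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"euclidean"`.
#' @return a `dist` object with attribute `metric`.
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "jaccard",
                                            "euclidean")) {
  metric <- match.arg(metric)
  m <- otu_matrix(table)
  if (nrow(m) < 2) abort("Beta diversity needs >= 2 samples.")
  d <- switch(metric,
    bray_curtis = vegan::vegdist(m, method = "bray"),
    jaccard = vegan::vegdist(m, method = "jaccard", binary = TRUE),
    euclidean = stats::dist(m)
  )
  if (any(is.nan(d))) {
    warn("All-zero sample pair(s): distance set to 0.")
    d[is.nan(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of the squared distances
#' followed by eigendecomposition. Negative eigenvalues are reported, not
#' dropped; explained fractions are taken over the positive eigenvalues only
#' (no Lingoes/Cailliez correction).
#'
#' @param d a `dist` object (e.g. from [beta_distance()]).
#' @param k number of axes to return (default `n - 1`).
#' @return object of class `pcoa_result`: list with `coordinates` (tibble),
#'   `eigenvalues` (all, including negative) and `explained` (per returned
#'   axis, over positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  k <- k %||% (n - 1)
  if (k < 1) abort("`k` must be >= 1.")
  k <- min(k, n - 1)
  fit <- cmdscale(d, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  coords <- fit$points
  kk <- ncol(coords)
  colnames(coords) <- paste0("PCo", seq_len(kk))
  ids <- attr(d, "Labels") %||% paste0("S", seq_len(n))
  structure(
    list(
      coordinates = as_tibble(coords) |>
        mutate(sample_id = ids, .before = 1),
      eigenvalues = fit$eig,
      explained = fit$eig[seq_len(kk)] / sum(pos),
      metric = attr(d, "metric") %||% "unknown"
    ),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA (", x$metric, "): ", nrow(x$coordinates), " samples\n", sep = "")
  k <- min(2, length(x$explained))
  cat("Explained:",
      paste0(sprintf("PCo%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

# among/within decomposition of squared distances for one labelling
permanova_F <- function(dm2, groups, n, g_sizes) {
  ss_total <- sum(dm2) / (2 * n)  # dm2 is the full square matrix
  ss_within <- 0
  for (lev in names(g_sizes)) {
    idx <- which(groups == lev)
    ss_within <- ss_within + sum(dm2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  g <- length(g_sizes)
  f <- (ss_among / (g - 1)) / (ss_within / (n - g))
  c(f = f, r2 = ss_among / ss_total)
}

#' PERMANOVA (one-way ADONIS)
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from the among/within decomposition of squared distances, with
#' unrestricted permutation of the sample labels and the
#' `(count + 1) / (n_perm + 1)` p-value estimator.
#'
#' @param d a `dist` object.
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @return object of class `permanova_result` with `pseudo_F`, `R2`, `p`,
#'   `df`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  seed <- check_seed(seed)
  if (n_perm < 99) abort("`n_perm` must be >= 99.")
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) abort("One group label per sample required.")
  g_sizes <- table(groups)
  if (length(g_sizes) < 2) abort("Need >= 2 groups.")
  if (any(g_sizes < 2)) abort("Every group needs >= 2 samples.")
  dm2 <- as.matrix(d)^2
  offd <- dm2[upper.tri(dm2)]
  if (diff(range(offd)) < 1e-15) {
    abort("Constant distance matrix; PERMANOVA is degenerate.")
  }
  obs <- permanova_F(dm2, groups, n, g_sizes)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      permanova_F(dm2, sample(groups), n, g_sizes)["f"]
    }, numeric(1)) >= obs["f"])
  })
  structure(
    list(pseudo_F = unname(obs["f"]), R2 = unname(obs["r2"]),
         p = perm_pvalue(hits, n_perm),
         df = c(among = length(g_sizes) - 1L, within = n - length(g_sizes)),
         n_perm = n_perm, metric = attr(d, "metric") %||% "unknown",
         seed = seed),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$metric, x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(term = "groups", pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p,
         df_among = x$df[["among"]], df_within = x$df[["within"]])
}

#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p, n_perm = x$n_perm,
         metric = x$metric)
}

#' Ordinary least-squares regression on a covariate
#'
#' Simple linear regression of a per-sample quantity (an alpha-diversity
#' index, a pairwise dissimilarity, ...) on a covariate, with the t-test on
#' the slope.
#'
#' @param y response values.
#' @param x covariate values, non-constant, paired with `y`.
#' @return tibble with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
regress_on_covariate <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need >= 3 paired observations.")
  if (length(unique(x)) == 1) abort("Constant covariate; regression undefined.")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared,
    p = sm$coefficients[2, 4],
    n = length(x)
  )
}
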