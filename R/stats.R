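# Shared statistical machinery: group tests, FDR, Spearman, RDA.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) abort("`groups` must be a list of numeric vectors.")
  if (!is.list(groups)) abort("`groups` must be a list of numeric vectors.")
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on
#' `length(groups) - 1` degrees of freedom. When every observation is
#' identical the test is degenerate; `H = 0, p = 1` is returned with a
#' warning.
#'
#' @param groups list of numeric vectors, one per group.
#' @return tibble with `statistic`, `df`, `p`, `method`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("Need >= 2 non-empty groups.")
  }
  x <- unlist(groups)
  if (length(x) < 3) abort("Need a total of >= 3 observations.")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    warn("All observations identical; Kruskal-Wallis is degenerate.")
    return(tibble(statistic = 0, df = length(groups) - 1L, p = 1,
                  method = "Kruskal-Wallis rank sum test"))
  }
  kt <- stats::kruskal.test(x, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on the pooled mid-ranks with tie correction,
#' two-sided p from the normal approximation, and (by default)
#' Benjamini-Hochberg q-values across all pairs of the family.
#'
#' @param groups list of numeric vectors, one per group; names are used as
#'   group labels.
#' @param correction `"bh"` (default) or `"none"`.
#' @return tibble with `group1`, `group2`, `z`, `p`, `q`.
#' @export
dunn_posthoc <- function(groups, correction = c("bh", "none")) {
  correction <- match.arg(correction)
  groups <- as_group_list(groups)
  if (length(groups) < 2) abort("Need >= 2 groups.")
  if (any(lengths(groups) == 0)) abort("Empty group in Dunn test.")
  labels <- names(groups) %||% as.character(seq_along(groups))
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_g <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    c(z = unname(z), p = 2 * pnorm(-abs(unname(z))))
  })
  out <- tibble(
    group1 = labels[pairs[1, ]],
    group2 = labels[pairs[2, ]],
    z = unname(res["z", ]),
    p = pmin(unname(res["p", ]), 1)
  )
  out$q <- if (correction == "bh") bh_fdr(out$p) else out$p
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; returns q-values in the input
#' order, clipped at 1 and monotone in p.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03))
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks (ties handled); the two-sided
#' p-value uses the t approximation with `n - 2` degrees of freedom, which
#' scales to the tens of thousands of pairs screened for the co-occurrence
#' network.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return tibble with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("Spearman needs >= 4 complete pairs.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Degenerate pair: constant input; Spearman rho undefined.")
  }
  rho <- cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  tibble(rho = rho, p = p, n = n)
}

spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Redundancy analysis with a Monte-Carlo permutation test
#'
#' Centres the response matrix `Y`, standardises the predictors `X` to zero
#' mean and unit variance (environmental variables come in mixed units), and
#' fits `Yhat = X (X'X)^-1 X' Y` by least squares. A PCA of the fitted
#' values gives the constrained axes; the fraction of the total variance of
#' `Y` captured by `Yhat` is the constrained fraction. The overall p-value
#' permutes the rows of `X` against the constrained-trace statistic; each
#' per-predictor p-value permutes only that predictor's column. Permutation
#' p-values use the `(count + 1) / (n_perm + 1)` estimator.
#'
#' @param Y samples x responses data frame or matrix (a `sample_id` column
#'   is honoured).
#' @param X samples x predictors data frame or matrix.
#' @param n_perm number of Monte-Carlo permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `rda_result`: list with `constrained_fractions`,
#'   `total_constrained_fraction`, `site_scores`, `variable_scores`,
#'   `predictor_scores`, `p_overall`, `p_per_predictor`, `n_perm`.
#' @export
rda <- function(Y, X, n_perm = 999, seed = 1) {
  seed <- check_seed(seed)
  Ym <- otu_matrix(Y)
  Xm <- otu_matrix(X)
  if (nrow(Ym) != nrow(Xm)) abort("Y and X must have the same number of rows.")
  if (any(!is.finite(Ym)) || any(!is.finite(Xm))) {
    abort("RDA requires complete, finite matrices.")
  }
  n <- nrow(Ym)
  if (n <= ncol(Xm) + 1) abort("Need n_samples > n_predictors + 1.")
  Yc <- scale(Ym, center = TRUE, scale = FALSE)
  Xs <- scale(Xm, center = TRUE, scale = TRUE)
  if (any(!is.finite(Xs))) abort("Constant predictor column(s) in X.")
  qr_x <- qr(Xs)
  if (qr_x$rank < ncol(Xs)) {
    dep <- colnames(Xs)[qr_x$pivot[(qr_x$rank + 1):ncol(Xs)]]
    abort(paste("Collinear predictor column(s):", paste(dep, collapse = ", ")))
  }

  trace_fit <- function(Xp) {
    f <- qr.fitted(qr(Xp), Yc)
    sum(f^2)
  }
  total <- sum(Yc^2)
  Yhat <- qr.fitted(qr_x, Yc)
  tr_obs <- sum(Yhat^2)

  sv <- svd(Yhat)
  k <- sum(sv$d > max(sv$d) * 1e-9)
  axes <- paste0("RDA", seq_len(k))
  eig <- sv$d[seq_len(k)]^2 / (n - 1)
  site <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(site) <- list(rownames(Ym), axes)
  vscores <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(vscores) <- list(colnames(Ym), axes)
  pscores <- suppressWarnings(cor(Xs, site))
  pscores[!is.finite(pscores)] <- 0
  dimnames(pscores) <- list(colnames(Xm), axes)

  perm <- withr::with_seed(seed, {
    p_overall_hits <- 0L
    p_pred_hits <- integer(ncol(Xs))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      if (trace_fit(Xs[idx, , drop = FALSE]) >= tr_obs) {
        p_overall_hits <- p_overall_hits + 1L
      }
      for (j in seq_len(ncol(Xs))) {
        Xj <- Xs
        Xj[, j] <- Xs[sample.int(n), j]
        if (trace_fit(Xj) >= tr_obs) p_pred_hits[j] <- p_pred_hits[j] + 1L
      }
    }
    list(overall = p_overall_hits, pred = p_pred_hits)
  })

  structure(
    list(
      constrained_fractions = (sv$d[seq_len(k)]^2) / total,
      total_constrained_fraction = tr_obs / total,
      eigenvalues = eig,
      site_scores = as_tibble(site, rownames = "sample_id"),
      variable_scores = as_tibble(vscores, rownames = "variable"),
      predictor_scores = as_tibble(pscores, rownames = "predictor"),
      p_overall = perm_pvalue(perm$overall, n_perm),
      p_per_predictor = setNames(perm_pvalue(perm$pred, n_perm), colnames(Xm)),
      n_perm = n_perm,
      seed = seed
    ),
    class = "rda_result"
  )
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "RDA: constrained fraction %.3f (overall p = %.4g, %d permutations)\n",
    x$total_constrained_fraction, x$p_overall, x$n_perm))
  k <- min(2, length(x$constrained_fractions))
  cat("Axis variance fractions:",
      paste0(sprintf("%.3f", x$constrained_fractions[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy rda_result
#' @export
tidy.rda_result <- function(x, ...) {
  tibble(predictor = names(x$p_per_predictor),
         p = unname(x$p_per_predictor))
}

#' @method glance rda_result
#' @export
glance.rda_result <- function(x, ...) {
  tibble(
    total_constrained_fraction = x$total_constrained_fraction,
    axis1_fraction = x$constrained_fractions[1],
    axis2_fraction = if (length(x$constrained_fractions) > 1)
      x$constrained_fractions[2] else NA_real_,
    p_overall = x$p_overall,
    n_perm = x$n_perm
  )
}
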