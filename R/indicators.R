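# Indicator species analysis (IndVal): specificity x fidelity with a
# group-label permutation test and BH-FDR selection.

# A, B, indval matrices for a counts matrix (samples x OTUs) and a grouping.
# A uses the group-MEAN form (the group-size-corrected "IndVal.g" variant),
# robust to unequal group sizes. Returns g x p matrices.
indval_matrices <- function(m, groups) {
  g <- factor(groups)
  n_g <- as.vector(table(g))
  means <- rowsum(m, g) / n_g                      # g x p group means
  colsum_means <- colSums(means)
  A <- sweep(means, 2, pmax(colsum_means, .Machine$double.eps), "/")
  pres <- rowsum((m > 0) + 0, g) / n_g             # fidelity
  list(A = A, B = pres, indval = sqrt(A * pres))
}

#' IndVal statistic for one OTU
#'
#' For each group g: specificity `A_g` = mean abundance in g divided by the
#' sum of group means (the group-size-corrected form); fidelity `B_g` =
#' fraction of samples of g where the OTU is present; `indval_g` =
#' `sqrt(A_g * B_g)`.
#'
#' @param abundances per-sample abundances of one OTU (non-negative).
#' @param groups group label per sample (>= 2 groups of >= 2 samples).
#' @return tibble `group`, `A`, `B`, `indval`, with the best group first.
#' @export
#' @examples
#' indval_statistic(c(4, 2, 0, 0, 0, 1), rep(c("g1", "g2"), each = 3))
indval_statistic <- function(abundances, groups) {
  if (any(abundances < 0)) abort("Abundances must be non-negative.")
  check_grouping(groups)
  if (sum(abundances) == 0) {
    warn("OTU absent everywhere; IndVal undefined.")
    return(tibble(group = character(), A = numeric(), B = numeric(),
                  indval = numeric()))
  }
  iv <- indval_matrices(matrix(abundances, ncol = 1), groups)
  tibble(
    group = rownames(iv$A),
    A = as.vector(iv$A),
    B = as.vector(iv$B),
    indval = as.vector(iv$indval)
  ) |>
    arrange(desc(.data$indval))
}

check_grouping <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2) abort("Need >= 2 groups.")
  if (any(tab < 2)) abort("Every group needs >= 2 samples.")
  invisible(tab)
}

#' Permutation test for indicator OTUs
#'
#' For every OTU, the observed statistic is its maximum IndVal over groups,
#' i.e. its association with its best group. The null permutes the group
#' labels over samples and recomputes the IndVal of that same (observed)
#' best group; `p = (count of permuted >= observed + 1) / (n_perm + 1)`.
#' q-values are Benjamini-Hochberg over OTUs, and an OTU is selected when
#' `indval > indval_threshold` and `q < q_threshold`.
#'
#' @param table OTU tibble or matrix (counts or relative abundances).
#' @param groups group label per sample.
#' @param n_perm number of label permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @param indval_threshold selection threshold on the IndVal statistic
#'   (default 0.85).
#' @param q_threshold selection threshold on the FDR-corrected p (default
#'   0.05).
#' @return object of class `indval_result`: a tibble with one row per OTU
#'   (`otu_id`, `best_group`, `A`, `B`, `indval`, `p`, `q`, `selected`),
#'   ordered by decreasing IndVal, with the test settings as attributes.
#' @export
indval_test <- function(table, groups, n_perm = 999, seed = 1,
                        indval_threshold = 0.85, q_threshold = 0.05) {
  seed <- check_seed(seed)
  if (n_perm < 99) abort("`n_perm` must be >= 99.")
  m <- otu_matrix(table)
  if (nrow(m) != length(groups)) abort("One group label per sample required.")
  check_grouping(groups)
  absent <- colSums(m) == 0
  if (any(absent)) {
    warn(paste("Skipping OTU(s) absent everywhere:",
               paste(colnames(m)[absent], collapse = ", ")))
    m <- m[, !absent, drop = FALSE]
  }
  if (ncol(m) == 0) abort("No OTU with non-zero abundance.")

  iv <- indval_matrices(m, groups)
  best_i <- apply(iv$indval, 2, which.max)
  obs <- iv$indval[cbind(best_i, seq_len(ncol(m)))]

  hits <- withr::with_seed(seed, {
    h <- integer(ncol(m))
    sel <- cbind(best_i, seq_len(ncol(m)))
    for (b in seq_len(n_perm)) {
      perm_iv <- indval_matrices(m, sample(groups))
      h <- h + (perm_iv$indval[sel] >= obs)
    }
    h
  })
  p <- perm_pvalue(hits, n_perm)
  q <- bh_fdr(p)

  out <- tibble(
    otu_id = colnames(m),
    best_group = rownames(iv$indval)[best_i],
    A = iv$A[cbind(best_i, seq_len(ncol(m)))],
    B = iv$B[cbind(best_i, seq_len(ncol(m)))],
    indval = obs,
    p = p,
    q = q,
    selected = obs > indval_threshold & q < q_threshold
  ) |>
    arrange(desc(.data$indval), .data$otu_id)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "indval_threshold") <- indval_threshold
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("indval_result", class(out))
  out
}

#' @method glance indval_result
#' @export
glance.indval_result <- function(x, ...) {
  tibble(
    n_otus = nrow(x),
    n_selected = sum(x$selected),
    indval_threshold = attr(x, "indval_threshold"),
    q_threshold = attr(x, "q_threshold"),
    n_perm = attr(x, "n_perm")
  )
}
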