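# ggplot2 graphics for the main result types.

#' Plot AWCD kinetics
#'
#' Average well-colour development against incubation time, one line per
#' sample, optionally coloured by group.
#'
#' @param curve tibble from [awcd_curve()].
#' @param groups optional named vector mapping sample ids to group labels.
#' @return a ggplot object.
#' @export
plot_awcd_curve <- function(curve, groups = NULL) {
  if (!is.null(groups)) curve$group <- unname(groups[curve$sample_id])
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$time_h, .data$awcd,
                                           group = .data$sample_id))
  p <- if (!is.null(groups)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$group), alpha = 0.7)
  } else {
    p + ggplot2::geom_line(alpha = 0.7)
  }
  p + ggplot2::labs(x = "Incubation time (h)", y = "AWCD",
                    colour = "Group") +
    ggplot2::theme_minimal()
}

#' @describeIn clpp_pca Score plot of the first two principal components.
#' @param object a `clpp_pca` object.
#' @param groups optional named vector of group labels per sample id.
#' @param ... ignored.
#' @method autoplot clpp_pca
#' @export
autoplot.clpp_pca <- function(object, groups = NULL, ...) {
  sc <- object$scores
  if (!is.null(groups)) sc$group <- unname(groups[sc$sample_id])
  aes <- if (!is.null(groups)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)
  } else ggplot2::aes(.data$PC1, .data$PC2)
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = "Group") +
    ggplot2::theme_minimal()
}

#' @describeIn pcoa Ordination plot of the first two axes.
#' @param object a `pcoa_result` object.
#' @param groups optional named vector of group labels per sample id.
#' @param ... ignored.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  co <- object$coordinates
  if (!is.null(groups)) co$group <- unname(groups[co$sample_id])
  aes <- if (!is.null(groups)) {
    ggplot2::aes(.data$PCo1, .data$PCo2, colour = .data$group)
  } else ggplot2::aes(.data$PCo1, .data$PCo2)
  ggplot2::ggplot(co, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$explained[2]),
      colour = "Group", title = paste("PCoA,", object$metric)) +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout with nodes coloured by module (or kind) and
#' edges drawn by correlation sign.
#'
#' @param g an `igraph` graph from [build_network()].
#' @param module_of optional named vector of module ids per node.
#' @param seed layout seed for reproducibility.
#' @return a ggplot object.
#' @export
plot_network <- function(g, module_of = NULL, seed = 1) {
  xy <- withr::with_seed(check_seed(seed),
                         igraph::layout_with_fr(g))
  nodes <- tibble(
    node = igraph::V(g)$name,
    kind = igraph::vertex_attr(g, "kind") %||% "otu",
    x = xy[, 1], y = xy[, 2],
    degree = as.integer(igraph::degree(g))
  )
  nodes$module <- if (!is.null(module_of)) {
    factor(unname(module_of[nodes$node]))
  } else factor(nodes$kind)
  el <- igraph::as_data_frame(g, what = "edges")
  ei <- match(el$from, nodes$node); ej <- match(el$to, nodes$node)
  edges <- tibble(x = nodes$x[ei], y = nodes$y[ei],
                  xend = nodes$x[ej], yend = nodes$y[ej],
                  sign = el$sign %||% "positive")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign),
      colour = "grey60", linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$module,
                   size = .data$degree, shape = .data$kind)) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Module", shape = "Node kind",
                  linetype = "Correlation")
}

#' @describeIn rda Triplot of sites and predictor arrows on the first two
#'   constrained axes.
#' @param object an `rda_result` object.
#' @param groups optional named vector of group labels per sample id.
#' @param ... ignored.
#' @method autoplot rda_result
#' @export
autoplot.rda_result <- function(object, groups = NULL, ...) {
  st <- object$site_scores
  if (ncol(st) < 3) abort("Need at least two constrained axes to plot.")
  if (!is.null(groups)) st$group <- unname(groups[st$sample_id])
  pr <- object$predictor_scores
  scale_arrow <- max(abs(st$RDA1), abs(st$RDA2)) * 0.9
  aes <- if (!is.null(groups)) {
    ggplot2::aes(.data$RDA1, .data$RDA2, colour = .data$group)
  } else ggplot2::aes(.data$RDA1, .data$RDA2)
  ggplot2::ggplot(st, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(
      data = pr, inherit.aes = FALSE,
      ggplot2::aes(x = 0, y = 0, xend = .data$RDA1 * scale_arrow,
                   yend = .data$RDA2 * scale_arrow),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
    ggplot2::geom_text(
      data = pr, inherit.aes = FALSE,
      ggplot2::aes(x = .data$RDA1 * scale_arrow * 1.08,
                   y = .data$RDA2 * scale_arrow * 1.08,
                   label = .data$predictor),
      colour = "firebrick", size = 3) +
    ggplot2::labs(
      x = sprintf("RDA1 (%.1f%%)", 100 * object$constrained_fractions[1]),
      y = sprintf("RDA2 (%.1f%%)", 100 * object$constrained_fractions[2]),
      colour = "Group") +
    ggplot2::theme_minimal()
}
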