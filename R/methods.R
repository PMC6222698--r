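# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname aqp_tidiers
#' @method tidy aqp_network
#' @param x An `aqp_network`, `aqp_kaks` or `aqp_groups` object.
#' @param ... Unused.
#' @export
tidy.aqp_network <- function(x, ...) x$edges

#' Tidy and summarize pipeline result objects
#'
#' `tidy()` returns the per-element table (edges, per-pair Ka/Ks rows, gene
#' group labels); `glance()` returns a one-row summary.
#'
#' @name aqp_tidiers
#' @method glance aqp_network
#' @export
glance.aqp_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "positive"),
    n_negative = sum(x$edges$sign == "negative"),
    abs_r = unname(x$thresholds["abs_r"])
  )
}

#' @rdname aqp_tidiers
#' @method tidy aqp_kaks
#' @export
tidy.aqp_kaks <- function(x, ...) as_tibble(x)

#' @rdname aqp_tidiers
#' @method glance aqp_kaks
#' @export
glance.aqp_kaks <- function(x, ...) {
  ok <- !is.na(x$omega)
  tibble(
    n_pairs = nrow(x),
    n_defined = sum(ok),
    n_negative = sum(x$verdict == "negative", na.rm = TRUE),
    n_positive = sum(x$verdict == "positive", na.rm = TRUE),
    mean_omega = if (any(ok)) mean(x$omega[ok]) else NA_real_,
    all_negative = isTRUE(attr(x, "all_negative"))
  )
}

#' @rdname aqp_tidiers
#' @method tidy aqp_groups
#' @export
tidy.aqp_groups <- function(x, ...) tibble(gene_id = x$gene_id, group = x$group)

#' @rdname aqp_tidiers
#' @method glance aqp_groups
#' @export
glance.aqp_groups <- function(x, ...) {
  tibble(k = attr(x, "k"), n_genes = nrow(x),
         largest_group = max(table(x$group)))
}

#' Plot a co-expression network
#'
#' Fruchterman-Reingold layout (seeded, deterministic); edge colour encodes
#' correlation sign, width encodes |r|.
#'
#' @param object An `aqp_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aqp_network
#' @export
autoplot.aqp_network <- function(object, seed = 1, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(gene_id = object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(object$edges,
                            setNames(nodes, c("gene_a", "xa", "ya")), by = "gene_a")
  edges <- dplyr::left_join(edges,
                            setNames(nodes, c("gene_b", "xb", "yb")), by = "gene_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   colour = .data$sign, linewidth = abs(.data$r))
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "grey20", negative = "seagreen")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "correlation")
}

#' Plot Ka versus Ks for a selection scan
#'
#' @param object An `aqp_kaks` result.
#' @param ... Unused.
#' @return A ggplot object; the dashed line is omega = 1 (neutrality).
#' @method autoplot aqp_kaks
#' @export
autoplot.aqp_kaks <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$omega), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$ks, .data$ka, colour = .data$verdict)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Ks (synonymous rate)", y = "Ka (nonsynonymous rate)") +
    ggplot2::theme_minimal()
}

#' Heat-map of expression values with group annotation
#'
#' Genes ordered by the clustering dendrogram; tile fill is the (log-scale)
#' expression value.
#'
#' @param object An `aqp_groups` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aqp_groups
#' @export
autoplot.aqp_groups <- function(object, ...) {
  v <- attr(object, "values")
  hc <- attr(object, "hclust")
  long <- as_tibble(v, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = rownames(v)[hc$order])
  grp <- setNames(object$group, object$gene_id)
  long$group <- factor(grp[as.character(long$gene_id)])
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
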