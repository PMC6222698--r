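# Signed co-expression network: Pearson correlations, percentile-rank
# thresholds, absolute-correlation filter, connectivity ranking.

#' Pairwise Pearson correlation matrix over samples
#'
#' @param m An `aqp_expr` (log2(FPKM+1) recommended) with >= 3 samples.
#' @return List: `r` (gene x gene Pearson matrix, unit diagonal) and
#'   `excluded` (ids of constant genes, for which r is undefined).
#' @export
correlation_matrix <- function(m) {
  v <- expr_values(m)
  if (ncol(v) < 3) stop("need at least 3 samples for correlation")
  sds <- apply(v, 1, stats::sd)
  excluded <- rownames(v)[sds == 0]
  keep <- v[sds > 0, , drop = FALSE]
  r <- cor(t(keep), method = "pearson")
  list(r = r, excluded = excluded)
}

#' Build the thresholded co-expression network
#'
#' A gene pair becomes an edge when its correlation lies in the lower
#' `lower_percentile` or upper `upper_percentile` tail of the off-diagonal r
#' distribution AND `|r| >= abs_r`. Both conditions are applied
#' conjunctively. Nodes with no surviving edge are retained as isolates.
#'
#' @param r_grid Output of [correlation_matrix()] (or a bare correlation
#'   matrix).
#' @param lower_percentile,upper_percentile Percentile ranks (0-100) on the
#'   off-diagonal r distribution.
#' @param abs_r Absolute-correlation filter.
#' @return An `aqp_network` object: list with `nodes`, `edges` (tibble
#'   `gene_a` < `gene_b`, `r`, `sign`), `thresholds`, `degree`.
#' @export
build_network <- function(r_grid, lower_percentile = 5, upper_percentile = 95,
                          abs_r = 0.75) {
  r <- if (is.list(r_grid) && !is.data.frame(r_grid)) r_grid$r else r_grid
  if (is.null(dim(r)) || nrow(r) < 2) stop("correlation grid must cover >= 2 genes")
  if (all(!is.finite(r[upper.tri(r)]))) stop("all correlations undefined")
  ids <- rownames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  # percentile ranks 0 / 100 disable the respective tail cut, so thresholds
  # (0, 100, abs_r) reduce to the pure |r| filter
  keep_lo <- if (lower_percentile <= 0) FALSE else {
    rv <= quantile(rv, lower_percentile / 100, na.rm = TRUE)
  }
  keep_hi <- if (upper_percentile >= 100) FALSE else {
    rv >= quantile(rv, upper_percentile / 100, na.rm = TRUE)
  }
  if (lower_percentile <= 0 && upper_percentile >= 100) {
    keep_lo <- TRUE
  }
  keep <- is.finite(rv) & (keep_lo | keep_hi) & abs(rv) >= abs_r
  a <- ids[ut[keep, 1]]
  b <- ids[ut[keep, 2]]
  edges <- tibble(
    gene_a = pmin(a, b),
    gene_b = pmax(a, b),
    r = rv[keep],
    sign = ifelse(rv[keep] >= 0, "positive", "negative")
  )
  edges <- edges[order(-abs(edges$r)), ]
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = ids))
  structure(
    list(
      nodes = ids,
      edges = edges,
      thresholds = c(lower_percentile = lower_percentile,
                     upper_percentile = upper_percentile, abs_r = abs_r),
      degree = setNames(as.integer(deg), ids)
    ),
    class = "aqp_network"
  )
}

#' @export
print.aqp_network <- function(x, ...) {
  cat(sprintf("Co-expression network: %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Rank genes by network connectivity
#'
#' Nodes sorted by degree descending, ties by summed `|r|` of incident edges
#' descending, then id.
#'
#' @param net An `aqp_network`.
#' @return Tibble: `gene_id`, `degree`, `sum_abs_r`, in rank order.
#' @export
connectivity_ranking <- function(net) {
  strength <- setNames(numeric(length(net$nodes)), net$nodes)
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    strength[e$gene_a] <- strength[e$gene_a] + abs(e$r)
    strength[e$gene_b] <- strength[e$gene_b] + abs(e$r)
  }
  out <- tibble(gene_id = net$nodes,
                degree = unname(net$degree[net$nodes]),
                sum_abs_r = unname(strength[net$nodes]))
  out[order(-out$degree, -out$sum_abs_r, out$gene_id), ]
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param net An `aqp_network`.
#' @param tsv_path,graphml_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(net$edges, tsv_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(tsv_path, graphml_path))
}
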