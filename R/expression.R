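# Expression processing: FPKM, log2(FPKM+1), 2^-ddCt, expression grouping.

#' FPKM normalization of a count matrix
#'
#' FPKM = count * 1e9 / (column total * transcript length in bp). The read
#' mapping that produces counts is upstream of this package; the FPKM stage
#' starts at a count matrix plus per-gene lengths.
#'
#' @param counts An `aqp_expr` with unit `"counts"`.
#' @param lengths Named numeric vector (bp per gene) or tibble with
#'   `gene_id`, `length_bp`.
#' @return An `aqp_expr` with unit `"fpkm"`.
#' @export
fpkm <- function(counts, lengths) {
  if (expr_unit(counts) != "counts") stop("fpkm() expects unit 'counts'")
  if (is.data.frame(lengths)) lengths <- setNames(lengths$length_bp, lengths$gene_id)
  m <- expr_values(counts)
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing) > 0) stop("missing transcript length for gene ", missing[1])
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("transcript lengths must be positive")
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("zero column total in sample ", colnames(m)[tot == 0][1])
  }
  out <- sweep(m, 2, tot, "/") * 1e9 / len
  new_expr_from_values(out, unit = "fpkm")
}

#' log2(FPKM + 1) transform
#'
#' @param m An `aqp_expr` with unit `"fpkm"`.
#' @return An `aqp_expr` with unit `"log2fpkm1"`.
#' @export
log_transform <- function(m) {
  if (expr_unit(m) != "fpkm") stop("log_transform() expects unit 'fpkm'")
  v <- expr_values(m)
  if (any(v < 0)) stop("negative FPKM value")
  new_expr_from_values(log2(v + 1), unit = "log2fpkm1")
}

#' Relative quantification by the comparative Ct (2^-ddCt) method
#'
#' Replicate Ct values are averaged per (gene, sample); dCt is the target
#' mean minus the reference-gene mean in the same sample; ddCt subtracts the
#' calibrator sample's dCt; the relative quantity is `2^-ddCt`, so the
#' calibrator column is exactly 1 for every gene.
#'
#' @param ct Tibble with `gene_id`, `sample_id`, `replicate`, `ct`.
#' @param reference_gene Internal reference gene id (must be present in every
#'   sample).
#' @param calibrator Calibrator sample id (default: first sample).
#' @return An `aqp_expr` with unit `"relative"` (reference gene excluded).
#' @export
ddct <- function(ct, reference_gene, calibrator = NULL) {
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct > 45)) stop("Ct values must lie in (0, 45]")
  samples <- unique(ct$sample_id)
  if (is.null(calibrator)) calibrator <- samples[1]
  means <- ct |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- means[means$gene_id == reference_gene, ]
  if (!all(samples %in% ref$sample_id)) {
    stop("reference gene ", reference_gene, " missing in sample ",
         setdiff(samples, ref$sample_id)[1])
  }
  ref_ct <- setNames(ref$ct, ref$sample_id)
  tgt <- means[means$gene_id != reference_gene, ]
  tgt$dct <- tgt$ct - ref_ct[tgt$sample_id]
  cal <- tgt[tgt$sample_id == calibrator, ]
  cal_dct <- setNames(cal$dct, cal$gene_id)
  tgt$rel <- unname(2^(-(tgt$dct - cal_dct[tgt$gene_id])))
  wide <- tidyr::pivot_wider(tgt[, c("gene_id", "sample_id", "rel")],
                             names_from = "sample_id", values_from = "rel")
  wide <- wide[, c("gene_id", samples)]
  expression_matrix(wide, unit = "relative")
}

#' Group genes by hierarchical clustering of expression profiles
#'
#' Agglomerative clustering (Euclidean distance on gene row vectors, average
#' linkage), tree cut into `k` clusters. Relative values are log2-transformed
#' first. Group labels 1..k are ordered by descending cluster mean, so group
#' 1 is the highest-expressed group.
#'
#' @param m An `aqp_expr` with unit `"log2fpkm1"` or `"relative"`.
#' @param k Number of groups.
#' @return An `aqp_groups` object: tibble `gene_id`, `group`; attributes
#'   `hclust` (the linkage record) and `k`.
#' @export
group_genes <- function(m, k = 3) {
  unit <- expr_unit(m)
  if (!unit %in% c("log2fpkm1", "relative")) {
    stop("group_genes() expects unit 'log2fpkm1' or 'relative'")
  }
  v <- expr_values(m)
  if (unit == "relative") v <- log2(v + 1)
  if (k > nrow(v)) stop("k exceeds the number of genes")
  hc <- hclust(dist(v, method = "euclidean"), method = "average")
  raw <- cutree(hc, k = k)
  cl_mean <- tapply(rowMeans(v), raw, mean)
  relabel <- setNames(rank(-cl_mean, ties.method = "first"), names(cl_mean))
  out <- tibble(gene_id = rownames(v),
                group = as.integer(relabel[as.character(raw)]))
  structure(out, hclust = hc, k = k, values = v,
            class = c("aqp_groups", class(out)))
}
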