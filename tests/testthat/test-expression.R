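counts_fixture <- function() {
  expression_matrix(
    tibble::tibble(gene_id = c("g1", "g2"),
                   s1 = c(10, 999990), s2 = c(0, 1e6)),
    unit = "counts"
  )
}

test_that("FPKM follows the definition and is depth-invariant", {
  lens <- c(g1 = 1000, g2 = 500)
  f <- fpkm(counts_fixture(), lens)
  expect_equal(expr_unit(f), "fpkm")
  # count 10, length 1000 bp, library 1e6 -> FPKM 10
  expect_equal(f$s1[f$gene_id == "g1"], 10)
  expect_equal(f$s2[f$gene_id == "g1"], 0)
  # doubling every count in a column leaves FPKM unchanged
  doubled <- expression_matrix(
    dplyr::mutate(tibble::as_tibble(counts_fixture()),
                  s1 = s1 * 2, s2 = s2 * 2), unit = "counts")
  expect_equal(as.data.frame(fpkm(doubled, lens)), as.data.frame(f))
  expect_error(fpkm(counts_fixture(), c(g1 = 1000)), "missing transcript length")
  expect_error(fpkm(f, lens), "unit 'counts'")
})

test_that("log transform maps 0/1/7 to 0/1/3 and guards its domain", {
  m <- expression_matrix(
    tibble::tibble(gene_id = c("a", "b", "c"), s1 = c(0, 1, 7),
                   s2 = c(7, 0, 1)), unit = "fpkm")
  lg <- log_transform(m)
  expect_equal(lg$s1, c(0, 1, 3))
  expect_equal(lg$s2, c(3, 0, 1))
  expect_equal(expr_unit(lg), "log2fpkm1")
  expect_error(log_transform(lg), "unit 'fpkm'")
})

test_that("ddct returns 1 at the calibrator and 2 for ddCt = -1", {
  ct <- tidyr::expand_grid(gene_id = c("ref", "t1"),
                           sample_id = c("cal", "s2"),
                           replicate = 1:3)
  ct$ct <- ifelse(ct$gene_id == "ref", 20,
                  ifelse(ct$sample_id == "cal", 25, 24)) # ddCt = -1
  rel <- ddct(ct, reference_gene = "ref")
  expect_equal(rel$cal, 1)
  expect_equal(rel$s2, 2)
  # a target tracking the reference everywhere stays at 1
  ct2 <- dplyr::mutate(ct, ct = 20)
  expect_equal(unlist(ddct(ct2, "ref")[-1]), c(cal = 1, s2 = 1))
  expect_error(ddct(ct[ct$gene_id != "ref" | ct$sample_id != "s2", ], "ref"),
               "missing in sample")
})

test_that("fold changes recovered from a noisy Ct table stay within 15%", {
  genes <- paste0("g", 1:6)
  set.seed(99)
  fc <- cbind(1, matrix(2^runif(18, -2, 2), 6, 3))
  ctt <- make_ct_table(genes, paste0("s", 1:4), fold_changes = fc, seed = 14)
  rel <- ddct(ctt$ct, reference_gene = ctt$reference_gene)
  est <- as.matrix(rel[-1])
  rownames(est) <- rel$gene_id
  for (g in seq_along(genes)) {
    for (j in 2:4) {
      expect_lt(abs(est[genes[g], j] / fc[g, j] - 1), 0.15)
    }
  }
})

test_that("grouping recovers planted high/low/mixed profiles", {
  v <- rbind(
    high1 = rep(8, 6), high2 = rep(7.8, 6),
    low1 = rep(0.5, 6), low2 = rep(0.4, 6),
    mix1 = c(8, 0.5, 8, 0.5, 8, 0.5), mix2 = c(7.9, 0.6, 7.9, 0.6, 7.9, 0.6)
  )
  colnames(v) <- paste0("s", 1:6)
  m <- expression_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(v)),
                     tibble::as_tibble(v)), unit = "log2fpkm1")
  g <- group_genes(m, k = 3)
  grp <- setNames(g$group, g$gene_id)
  expect_equal(length(unique(grp[c("high1", "high2")])), 1)
  expect_equal(length(unique(grp[c("low1", "low2")])), 1)
  expect_equal(length(unique(grp[c("mix1", "mix2")])), 1)
  # labels ordered by descending cluster mean: high group is 1, low is 3
  expect_equal(unname(grp[["high1"]]), 1L)
  expect_equal(unname(grp[["low1"]]), 3L)
  expect_equal(max(tidyr::replace_na(g$group, 0L)), 3L)
})

test_that("grouping edge cases: k = 1, duplicated rows, invariances", {
  me <- make_expression(12, 8, modules = list(1:4), seed = 3)
  lg <- log_transform(me$expr)
  g1 <- group_genes(lg, k = 1)
  expect_true(all(g1$group == 1))
  expect_error(group_genes(lg, k = 40), "exceeds")
  # duplicating a gene row keeps the twin in the same group
  dup <- dplyr::bind_rows(tibble::as_tibble(lg),
                          dplyr::mutate(tibble::as_tibble(lg)[1, ], gene_id = "twin"))
  gd <- group_genes(expression_matrix(dup, "log2fpkm1"), k = 3)
  expect_equal(gd$group[gd$gene_id == "twin"], gd$group[1])
  # sample order does not matter
  shuf <- expression_matrix(tibble::as_tibble(lg)[, c(1, 5, 3, 2, 8, 4, 9, 6, 7)],
                            "log2fpkm1")
  expect_equal(tidy(group_genes(shuf, k = 3)), tidy(group_genes(lg, k = 3)))
})

test_that("tidy/glance/autoplot work on expression groups", {
  me <- make_expression(15, 8, modules = list(1:5), seed = 6)
  g <- group_genes(log_transform(me$expr), k = 3)
  expect_equal(nrow(tidy(g)), 15)
  expect_equal(glance(g)$k, 3)
  p <- ggplot2::autoplot(g)
  expect_s3_class(p, "ggplot")
})
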