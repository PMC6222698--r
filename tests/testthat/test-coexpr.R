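standard_fixture <- function(seed, noise_sd = 0.3) {
  make_expression(
    n_genes = 30, n_samples = 11,
    modules = list(1:5, 6:10),
    negative_pairs = list(c(11, 12), c(13, 14), c(15, 16), c(17, 18)),
    noise_sd = noise_sd, seed = seed
  )
}

test_that("correlation matrix matches the two-pass formula oracle", {
  me <- standard_fixture(seed = 2)
  lg <- log_transform(me$expr)
  r <- correlation_matrix(lg)$r
  v <- as.matrix(tibble::as_tibble(lg)[-1])
  rownames(v) <- lg$gene_id
  set.seed(8)
  for (k in 1:20) {
    ij <- sample(nrow(v), 2)
    expect_equal(r[ij[1], ij[2]],
                 two_pass_pearson(v[ij[1], ], v[ij[2], ]), tolerance = 1e-12)
  }
  expect_equal(unname(diag(r)), rep(1, 30))
  expect_error(correlation_matrix(expression_matrix(
    tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 2), s2 = c(2, 3)), "fpkm")),
    "3 samples")
})

test_that("constant genes are excluded and reported, not propagated", {
  df <- tibble::tibble(gene_id = c("a", "b", "flat"),
                       s1 = c(1, 2, 5), s2 = c(2, 1, 5), s3 = c(3, 4, 5))
  cm <- correlation_matrix(expression_matrix(df, "log2fpkm1"))
  expect_equal(cm$excluded, "flat")
  expect_equal(dim(cm$r), c(2, 2))
  expect_false(anyNA(cm$r))
})

test_that("planted modules become cliques and negative pairs single edges", {
  # a lone 3-gene module at zero noise: a triangle of r = 1 edges
  mod <- make_expression(3, 8, modules = list(1:3), noise_sd = 0, seed = 6)
  net <- build_network(correlation_matrix(log_transform(mod$expr)),
                       lower_percentile = 0, upper_percentile = 100)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$sign, rep("positive", 3))
  expect_equal(net$edges$r, rep(1, 3))
  expect_equal(unname(net$degree), rep(2L, 3))

  # a lone anti-correlated pair at zero noise: exactly one negative edge
  np <- make_expression(2, 8, negative_pairs = list(c(1, 2)), noise_sd = 0,
                        seed = 6)
  net2 <- build_network(correlation_matrix(log_transform(np$expr)),
                        lower_percentile = 0, upper_percentile = 100)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$sign, "negative")
  expect_equal(net2$edges$r, -1)

  # edge invariants on a mixed fixture
  me <- standard_fixture(seed = 6)
  net3 <- build_network(correlation_matrix(log_transform(me$expr)))
  expect_true(all(net3$edges$gene_a < net3$edges$gene_b))
  expect_true(all(abs(net3$edges$r) >= 0.75))
  expect_equal(net3$edges$sign, ifelse(net3$edges$r >= 0, "positive", "negative"))
})

test_that("degenerate percentiles reduce to the pure |r| filter", {
  me <- standard_fixture(seed = 3)
  cm <- correlation_matrix(log_transform(me$expr))
  net <- build_network(cm, lower_percentile = 0, upper_percentile = 100)
  rv <- cm$r[upper.tri(cm$r)]
  expect_equal(nrow(net$edges), sum(abs(rv) >= 0.75))
  # conjunctive thresholds can only remove edges
  net2 <- build_network(cm)
  expect_lte(nrow(net2$edges), nrow(net$edges))
})

test_that("module edges are recovered with high precision and recall", {
  for (sd in 1:10) {
    me <- standard_fixture(seed = sd)
    net <- build_network(correlation_matrix(log_transform(me$expr)))
    truth_pos <- me$truth[me$truth$sign == "positive", ]
    got_pos <- net$edges[net$edges$sign == "positive", ]
    precision <- mean(edge_key(got_pos) %in% edge_key(truth_pos))
    recall <- mean(edge_key(truth_pos) %in% edge_key(got_pos))
    expect_gte(precision, 0.9)
    expect_gte(recall, 0.9)
    # all four planted negative pairs survive the thresholds
    truth_neg <- me$truth[me$truth$sign == "negative", ]
    got_neg <- net$edges[net$edges$sign == "negative", ]
    expect_gte(mean(edge_key(truth_neg) %in% edge_key(got_neg)), 0.9)
  }
})

test_that("connectivity ranking puts hubs first and breaks ties by id", {
  # star: hub correlates with three satellites through one latent profile
  me <- make_expression(8, 8, modules = list(1:4), noise_sd = 0, seed = 2)
  net <- build_network(correlation_matrix(log_transform(me$expr)),
                       lower_percentile = 0, upper_percentile = 100)
  rk <- connectivity_ranking(net)
  expect_equal(sort(rk$gene_id[1:4]), sprintf("G%03d", 1:4))
  # edgeless network: all degree zero, id order
  m2 <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m2) <- 1
  flat2 <- build_network(m2, abs_r = 0.99)
  expect_equal(nrow(flat2$edges), 0)
  rk2 <- connectivity_ranking(flat2)
  expect_equal(rk2$gene_id, letters[1:4])
  expect_true(all(rk2$degree == 0))
})

test_that("module members outrank background genes in connectivity", {
  me <- standard_fixture(seed = 7)
  net <- build_network(correlation_matrix(log_transform(me$expr)))
  rk <- connectivity_ranking(net)
  members <- sprintf("G%03d", 1:10)
  background <- sprintf("G%03d", 19:30)
  expect_lt(max(match(members, rk$gene_id)),
            min(match(background, rk$gene_id)))
})

test_that("network export writes a valid edge list and GraphML", {
  me <- standard_fixture(seed = 4)
  net <- build_network(correlation_matrix(log_transform(me$expr)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, tsv_path = tsv, graphml_path = gml)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 30)
  expect_equal(igraph::gsize(g), nrow(net$edges))
  # tidiers and plot
  expect_equal(nrow(tidy(net)), nrow(net$edges))
  expect_s3_class(ggplot2::autoplot(net), "ggplot")
  expect_equal(glance(net)$n_nodes, 30)
})
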