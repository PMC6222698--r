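test_that("generators are pure functions of parameters and seed", {
  expect_identical(make_protein("PIP2", 4), make_protein("PIP2", 4))
  expect_false(identical(make_protein("PIP2", 4)$protein$sequence,
                         make_protein("PIP2", 5)$protein$sequence))
  expect_identical(make_cds_pair(60, 0.5, 0.2, 9), make_cds_pair(60, 0.5, 0.2, 9))
  expect_identical(make_expression(12, 8, list(1:3), seed = 2),
                   make_expression(12, 8, list(1:3), seed = 2))
  expect_identical(make_ct_table("g1", c("a", "b"), 2, seed = 3),
                   make_ct_table("g1", c("a", "b"), 2, seed = 3))
  expect_identical(simulate_proteome(5, n_allele_pairs = 2),
                   simulate_proteome(5, n_allele_pairs = 2))
})

test_that("generated proteins respect the architecture contract", {
  for (sg in c("PIP1", "TIP5", "SIP1", "XIP1")) {
    mp <- make_protein(sg, seed = 13)
    len <- nchar(mp$protein$sequence)
    expect_true(len >= 230 && len <= 340)
    chars <- strsplit(mp$protein$sequence, "")[[1]]
    # planted anchors really sit at the recorded coordinates
    expect_equal(paste(chars[mp$truth$arr_pos[[1]]], collapse = ","),
                 mp$truth$arr)
    expect_equal(paste(chars[mp$truth$froger_pos[[1]]], collapse = ","),
                 mp$truth$froger)
    expect_equal(mp$truth$le_start - mp$truth$lb_start, mp$truth$inter_npa)
  }
  expect_error(make_protein("PIP1", 1, inter_npa = 60), "incompatible")
  expect_error(make_protein("nope", 1), "unknown subgroup")
})

test_that("CDS pairs carry exactly the planted substitution counts", {
  cp <- make_cds_pair(200, omega = 0.5, ks_target = 0.3, seed = 6)
  expect_equal(nchar(cp$cds$sequence[1]), 600)
  # no stops anywhere in frame
  for (s in cp$cds$sequence) {
    aa <- aquascan:::translate_cds(s)
    expect_false(grepl("\\*", aa))
  }
  # each mutated codon has exactly one changed base: planted counts are exact
  al <- global_align(aquascan:::translate_cds(cp$cds$sequence[1]),
                     aquascan:::translate_cds(cp$cds$sequence[2]))
  res <- kaks_ng86(backtranslate(al, cp$cds$sequence[1], cp$cds$sequence[2]))
  expect_equal(res$Sd, cp$truth$sd_planted)
  expect_equal(res$Nd, cp$truth$nd_planted)

  # omega = 0 plants no nonsynonymous change at all
  cp0 <- make_cds_pair(100, omega = 0, ks_target = 0.2, seed = 2)
  expect_equal(cp0$truth$nd_planted, 0)
  # ks_target = 0 yields an identical pair
  cpid <- make_cds_pair(80, omega = 1, ks_target = 0, seed = 2)
  expect_equal(cpid$cds$sequence[1], cpid$cds$sequence[2])
  expect_error(make_cds_pair(30, 0.5, 0.2, 1), ">= 50")
})

test_that("expression generator plants exact correlations at zero noise", {
  me <- make_expression(10, 8, modules = list(1:3),
                        negative_pairs = list(c(4, 5)), noise_sd = 0, seed = 4)
  lg <- log_transform(me$expr)
  r <- correlation_matrix(lg)$r
  expect_equal(r["G001", "G002"], 1.0)
  expect_equal(r["G002", "G003"], 1.0)
  expect_equal(r["G004", "G005"], -1.0)
  expect_true(all(as.matrix(me$expr[-1]) >= 0))
  expect_lt(max(as.matrix(me$expr[-1])), 600) # FPKM-like scale
  expect_error(make_expression(10, 8, modules = list(1:3, 3:5), seed = 1),
               "disjoint")
  expect_error(make_expression(10, 4, seed = 1), ">= 8")
})

test_that("Ct generator encodes fold changes as cycle shifts", {
  ctt <- make_ct_table("g1", c("cal", "s2"), fold_changes = cbind(1, 2),
                       noise_sd = 0, seed = 1)
  m <- dplyr::summarise(dplyr::group_by(ctt$ct, gene_id, sample_id),
                        ct = mean(ct), .groups = "drop")
  g <- m[m$gene_id == "g1", ]
  # doubling halves the Ct distance to the reference by one cycle
  expect_equal(g$ct[g$sample_id == "s2"] - g$ct[g$sample_id == "cal"], -1)
  rel <- ddct(ctt$ct, reference_gene = "GADPH")
  expect_equal(unname(unlist(rel[rel$gene_id == "g1", c("cal", "s2")])),
               c(1, 2))
  expect_error(make_ct_table("g1", c("a", "b"), fold_changes = -1, seed = 1),
               "positive")
})

test_that("the simulated proteome matches the study composition", {
  sp <- simulate_proteome(seed = 21, n_allele_pairs = 3)
  expect_equal(nrow(sp$proteins), 33)
  expect_equal(nrow(sp$truth), 30)
  expect_equal(sum(sp$truth$subfamily == "PIP"), 9)
  expect_equal(sum(sp$truth$subfamily == "TIP"), 11)
  expect_equal(nrow(sp$allele_truth), 3)
  # allele partners stay near-identical to their primaries
  for (k in 1:3) {
    pa <- sp$proteins$sequence[sp$proteins$id == sp$allele_truth$id_a[k]]
    pb <- sp$proteins$sequence[sp$proteins$id == sp$allele_truth$id_b[k]]
    expect_gte(global_align(pa, pb)$identity, 0.95)
  }
})
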