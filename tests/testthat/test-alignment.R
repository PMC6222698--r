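test_that("identity follows the column-match definition on loop-B boxes", {
  expect_equal(global_align("NPA", "NPA")$identity, 1.0)
  # hand count: the two 10-mer loop-B boxes differ at 2 of 10 columns
  expect_equal(global_align("SGGHINPAVT", "SGAHFNPAVT")$identity, 0.8)
  # symmetry and self-identity on generated proteins
  a <- make_protein("PIP1", 5)$protein$sequence
  b <- make_protein("TIP2", 5)$protein$sequence
  expect_equal(global_align(a, a)$identity, 1.0)
  expect_equal(global_align(a, b)$identity, global_align(b, a)$identity)
  expect_error(global_align("", "NPA"), "non-empty")
})

test_that("gaps removed from an alignment recover the inputs", {
  a <- make_protein("NIP5", 2)$protein$sequence
  b <- make_protein("SIP1", 3)$protein$sequence
  al <- global_align(a, b)
  expect_equal(gsub("-", "", al$aligned_a), a)
  expect_equal(gsub("-", "", al$aligned_b), b)
  expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
})

test_that("alignment scores match exhaustive enumeration on short sequences", {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  set.seed(404)
  # all ordered pairs of length 1-2 words over ACGT
  words <- c("A", "C", "G", "T",
             apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                   1, paste, collapse = ""))
  for (a in words) {
    for (b in words) {
      expect_equal(global_align(a, b, sub)$score,
                   nw_oracle_score(a, b, sub), info = paste(a, b))
    }
  }
  # random longer pairs
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b, sub)$score,
                 nw_oracle_score(a, b, sub), info = paste(a, b))
  }
})

test_that("backtranslation expands residues to codons and round-trips", {
  cp <- make_cds_pair(60, omega = 0.5, ks_target = 0.2, seed = 4)
  pa <- gsub("\\*$", "", aquascan:::translate_cds(cp$cds$sequence[1]))
  pb <- gsub("\\*$", "", aquascan:::translate_cds(cp$cds$sequence[2]))
  al <- global_align(pa, pb)
  ca <- backtranslate(al, cp$cds$sequence[1], cp$cds$sequence[2])
  expect_equal(length(ca$codons_a), nchar(al$aligned_a))
  # gapless identical pair: codon alignment is the concatenated codons
  expect_equal(paste(ca$codons_a, collapse = ""), cp$cds$sequence[1])
  # translating the codon alignment reproduces the protein alignment
  aa <- vapply(ca$codons_a, function(cd) {
    if (cd == "---") "-" else unname(Biostrings::GENETIC_CODE[cd])
  }, character(1))
  expect_equal(paste(aa, collapse = ""), al$aligned_a)
  # mismatched CDS is refused with the offending codon named
  expect_error(backtranslate(al, cp$cds$sequence[2], cp$cds$sequence[2]),
               "mismatch")
})

test_that("gap columns become --- at the corresponding codon slot", {
  al <- structure(list(aligned_a = "MK-V", aligned_b = "MKLV",
                       score = 0, identity = 0.75), class = "aqp_alignment")
  ca <- backtranslate(al, "ATGAAAGTT", "ATGAAACTGGTT")
  expect_equal(ca$codons_a, c("ATG", "AAA", "---", "GTT"))
  expect_equal(ca$codons_b, c("ATG", "AAA", "CTG", "GTT"))
})

test_that("neighbor joining recovers an additive four-taxon tree exactly", {
  # hand-drawn tree: ((A:2,B:3):1,C:4,D:5)
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-10)
  # permuting taxon order leaves the topology unchanged
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(tr, tr2), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("p-distance is symmetric with a zero diagonal", {
  prots <- dplyr::bind_rows(
    make_protein("PIP1", 1)$protein,
    make_protein("PIP2", 1)$protein,
    make_protein("TIP1", 1)$protein
  )
  d <- p_distance(prots)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d[upper.tri(d)] > 0))
})
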