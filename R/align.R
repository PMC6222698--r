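#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch alignment under a substitution matrix with affine gap
#' costs (a gap of length k costs `gap_open + k * gap_extend`). Ties are
#' broken deterministically: diagonal over gap-in-a over gap-in-b. Identity is
#' the fraction of alignment columns in which both sequences carry the same
#' residue (gap columns count as non-matches).
#'
#' @param a,b Residue strings (non-empty).
#' @param substitution Substitution matrix with residue dimnames; defaults to
#'   BLOSUM62.
#' @param gap_open,gap_extend Non-positive gap penalties (Clustal-like
#'   defaults -10 / -0.5).
#' @return An object of class `aqp_alignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `identity`.
#' @export
global_align <- function(a, b, substitution = blosum62(),
                         gap_open = -10, gap_extend = -0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be non-positive")
  res <- .nw_align_cpp(a, b, substitution, rownames(substitution),
                       gap_open, gap_extend)
  structure(res, class = "aqp_alignment")
}

#' @export
print.aqp_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: %d columns, score %.1f, identity %.3f\n",
              nchar(x$aligned_a), x$score, x$identity))
  invisible(x)
}

gapless <- function(s) gsub("-", "", s, fixed = TRUE)

# map: for each position of the ungapped first sequence, the position in the
# ungapped second sequence it is aligned to (NA where aligned to a gap)
alignment_map <- function(aligned_from, aligned_to) {
  fa <- strsplit(aligned_from, "")[[1]]
  ta <- strsplit(aligned_to, "")[[1]]
  from_pos <- cumsum(fa != "-")
  to_pos <- cumsum(ta != "-")
  keep <- fa != "-"
  out <- ifelse(ta[keep] == "-", NA_integer_, to_pos[keep])
  as.integer(out)
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Each amino-acid alignment column becomes the source codon (or `"---"` in
#' gap columns), producing a codon alignment three times the protein
#' alignment length. Both coding sequences must translate exactly to their
#' ungapped aligned proteins.
#'
#' @param alignment An `aqp_alignment` of the two protein sequences.
#' @param cds_a,cds_b In-frame coding sequences (strings, length divisible by
#'   3, optionally ending in a stop codon which is trimmed).
#' @return List of class `aqp_codon_alignment` with `codons_a`, `codons_b`
#'   (equal-length character vectors of 3-mers or `"---"`).
#' @export
backtranslate <- function(alignment, cds_a, cds_b) {
  prot_a <- gapless(alignment$aligned_a)
  prot_b <- gapless(alignment$aligned_b)
  codon_split <- function(nt, prot, tag) {
    nt <- toupper(nt)
    if (nchar(nt) %% 3 != 0) stop("CDS ", tag, " length not divisible by 3")
    cod <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    aa <- unname(genetic_code()[cod])
    if (length(aa) == nchar(prot) + 1 && aa[length(aa)] == "*") {
      cod <- cod[-length(cod)]
      aa <- aa[-length(aa)]
    }
    if (length(aa) != nchar(prot)) {
      stop(sprintf("CDS %s has %d codons but protein has %d residues",
                   tag, length(aa), nchar(prot)))
    }
    mism <- which(aa != strsplit(prot, "")[[1]])
    if (length(mism) > 0) {
      stop(sprintf("translation mismatch in CDS %s at codon %d (%s -> %s, protein has %s)",
                   tag, mism[1], cod[mism[1]], aa[mism[1]],
                   substring(prot, mism[1], mism[1])))
    }
    cod
  }
  ca <- codon_split(cds_a, prot_a, "a")
  cb <- codon_split(cds_b, prot_b, "b")
  expand <- function(aligned, codons) {
    chars <- strsplit(aligned, "")[[1]]
    out <- rep("---", length(chars))
    out[chars != "-"] <- codons
    out
  }
  structure(list(codons_a = expand(alignment$aligned_a, ca),
                 codons_b = expand(alignment$aligned_b, cb)),
            class = "aqp_codon_alignment")
}

#' Pairwise p-distance matrix from global alignments
#'
#' Aligns every pair with [global_align()] and records the p-distance
#' (fraction of mismatching columns among columns with no gap in either
#' sequence).
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param ... Passed to [global_align()].
#' @return A symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
p_distance <- function(proteins, ...) {
  n <- nrow(proteins)
  d <- matrix(0, n, n, dimnames = list(proteins$id, proteins$id))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- global_align(proteins$sequence[i], proteins$sequence[j], ...)
      ca <- strsplit(al$aligned_a, "")[[1]]
      cb <- strsplit(al$aligned_b, "")[[1]]
      keep <- ca != "-" & cb != "-"
      d[i, j] <- d[j, i] <- if (any(keep)) mean(ca[keep] != cb[keep]) else 1
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}) with branch
#' lengths floored at zero. Taxa are processed in lexicographic id order so
#' the output is invariant to input permutation.
#'
#' @param d Symmetric distance matrix with id dimnames (>= 3 taxa).
#' @param path Optional path; when given the tree is also written as newick.
#' @return An \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(d, path = NULL) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  if (!is.null(path)) ape::write.tree(tree, file = path)
  tree
}
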