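# Candidate screening and putative-allele-ORF pairing.

#' Screen proteins for aquaporin candidacy
#'
#' A sequence passes when it has a complete MIP-like architecture,
#' operationalized as: length within `length_range`, at least two NPA-like
#' boxes (degenerate variants included), and at least `min_tm` predicted
#' transmembrane segments. Every failed criterion is listed. A precomputed
#' domain table (e.g. from an HMM search against the MIP profile) can be
#' supplied to override the architecture heuristic: ids present in it are
#' treated as having a complete MIP domain regardless of length and TM count.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param length_range Accepted length window (residues).
#' @param min_tm Minimum predicted TM segments.
#' @param domain_table Optional tibble with an `id` column of proteins with a
#'   verified complete MIP domain.
#' @return Tibble: `id`, `passed`, `reasons` (";"-joined failed criteria),
#'   `n_npa_boxes`, `n_tm`, `length`.
#' @export
screen_candidates <- function(proteins, length_range = c(200, 400),
                              min_tm = 5, domain_table = NULL) {
  has_domain <- if (is.null(domain_table)) character() else domain_table$id
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    len <- nchar(s)
    boxes <- if (len >= 50) find_npa_boxes(s) else tibble(loop = character())
    n_boxes <- sum(boxes$flag %in% c("", "clamped"))
    if (nrow(boxes) == 1) n_boxes <- 1L
    n_tm <- if (len >= 19) nrow(predict_tm(s)) else 0L
    reasons <- character()
    domain_ok <- proteins$id[i] %in% has_domain
    if (!domain_ok && (len < length_range[1] || len > length_range[2])) {
      reasons <- c(reasons, sprintf("length %d outside [%d, %d]", len,
                                    length_range[1], length_range[2]))
    }
    if (n_boxes < 2) reasons <- c(reasons, "two NPA motifs")
    if (!domain_ok && n_tm < min_tm) {
      reasons <- c(reasons, sprintf("fewer than %d TM segments", min_tm))
    }
    tibble(
      id = proteins$id[i],
      passed = length(reasons) == 0,
      reasons = paste(reasons, collapse = "; "),
      n_npa_boxes = as.integer(n_boxes),
      n_tm = as.integer(n_tm),
      length = as.integer(len)
    )
  })
}

#' Pair putative allele ORFs
#'
#' Greedy reciprocal-best pairing on global-alignment identity. A pair is
#' accepted when both members are each other's best match, their identity is
#' at least `min_identity` (alleles are near-identical copies), and both are
#' classified into the same subfamily. Each protein joins at most one pair;
#' pairs are returned sorted by identity descending.
#'
#' @param proteins Tibble with `id`, `sequence` (>= 2 rows).
#' @param panel Reference panel used for the subfamily check.
#' @param min_identity Pairing identity threshold (default 0.95).
#' @return Tibble: `id_a`, `id_b`, `identity` (id_a < id_b).
#' @export
pair_alleles <- function(proteins, panel = reference_panel(), min_identity = 0.95) {
  n <- nrow(proteins)
  if (n < 2) stop("need at least two proteins")
  ident <- matrix(0, n, n, dimnames = list(proteins$id, proteins$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ident[i, j] <- ident[j, i] <-
        global_align(proteins$sequence[i], proteins$sequence[j])$identity
    }
  }
  calls <- assign_subfamily(proteins, panel)
  fam <- setNames(calls$subfamily, calls$id)
  best <- apply(ident, 1, which.max)
  cand <- tibble(i = seq_len(n), j = as.integer(best))
  cand <- cand[cand$i < cand$j & best[cand$j] == cand$i, , drop = FALSE]
  cand$identity <- ident[cbind(cand$i, cand$j)]
  cand <- cand[cand$identity >= min_identity, , drop = FALSE]
  cand <- cand[fam[proteins$id[cand$i]] == fam[proteins$id[cand$j]], , drop = FALSE]
  cand <- cand[order(-cand$identity), , drop = FALSE]
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      keep[k] <- TRUE
      used[c(cand$i[k], cand$j[k])] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  ids <- proteins$id
  tibble(
    id_a = pmin(ids[cand$i], ids[cand$j]),
    id_b = pmax(ids[cand$i], ids[cand$j]),
    identity = cand$identity
  )
}
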