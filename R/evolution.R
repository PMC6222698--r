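# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Site counting: at each codon position the synonymous fraction is the
# proportion of the three possible single-nucleotide changes that preserve
# the amino acid; changes producing a stop codon count as nonsynonymous, so
# N + S = 3 per codon. Pairwise differences at multi-hit codons are averaged
# with equal weights over all minimal mutational pathways that avoid stop
# intermediates (all pathways if every one is blocked).

NT <- c("A", "C", "G", "T")

.codon_site_counts <- function(codon, gc) {
  aa <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(NT, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (gc[[alt]] == aa) s <- s + 1
    }
  }
  c(syn = s / 3, nonsyn = 3 - s / 3)
}

.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

.codon_pair_diffs <- function(ca, cb, gc) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  open_paths <- list()
  all_paths <- list()
  for (ord in .perms[[as.character(k)]]) {
    cur <- ca
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (step in seq_len(k)) {
      p <- pos[ord[step]]
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*" && step < k) blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    all_paths[[length(all_paths) + 1]] <- c(sd, nd)
    if (!blocked) open_paths[[length(open_paths) + 1]] <- c(sd, nd)
  }
  use <- if (length(open_paths) > 0) open_paths else all_paths
  m <- do.call(rbind, use)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_) # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka/Ks for one codon alignment
#'
#' Computes synonymous and nonsynonymous site counts (averaged over the two
#' sequences), pathway-averaged difference counts, the proportions pN and pS,
#' Jukes-Cantor-corrected rates Ka and Ks, and their ratio omega. Ks (or Ka)
#' is reported as `NA` when the corresponding proportion is saturated
#' (>= 0.75); omega is `NA` when Ks is zero or undefined.
#'
#' @param codon_alignment An `aqp_codon_alignment` from [backtranslate()], or
#'   a list with `codons_a`, `codons_b` character vectors.
#' @param min_codons Minimum number of gap-free codon columns.
#' @return One-row tibble: `n_codons`, `N`, `S`, `Nd`, `Sd`, `pN`, `pS`,
#'   `ka`, `ks`, `omega`.
#' @export
kaks_ng86 <- function(codon_alignment, min_codons = 30) {
  gc <- as.list(genetic_code())
  ca <- codon_alignment$codons_a
  cb <- codon_alignment$codons_b
  keep <- ca != "---" & cb != "---"
  ca <- ca[keep]
  cb <- cb[keep]
  if (any(gc[ca] == "*") || any(gc[cb] == "*")) {
    stop("internal stop codon in codon alignment")
  }
  if (length(ca) < min_codons) {
    stop("too few gap-free codon columns (", length(ca), " < ", min_codons, ")")
  }
  sites_a <- vapply(ca, .codon_site_counts, numeric(2), gc = gc)
  sites_b <- vapply(cb, .codon_site_counts, numeric(2), gc = gc)
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- vapply(seq_along(ca), function(i) {
    .codon_pair_diffs(ca[i], cb[i], gc)
  }, numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- Sd / S
  pN <- Nd / N
  ka <- jc_correct(pN)
  ks <- jc_correct(pS)
  omega <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  tibble(n_codons = length(ca), N = N, S = S, Nd = Nd, Sd = Sd,
         pN = pN, pS = pS, ka = ka, ks = ks, omega = omega)
}

#' Selection-pressure scan over coding-sequence pairs
#'
#' For each pair: translates both CDSs, aligns the proteins globally,
#' back-translates to a codon alignment and computes the Nei-Gojobori Ka/Ks.
#' Verdicts: "negative" (omega < 1), "positive" (omega > 1),
#' "neutral/undefined" otherwise. Failed pairs are reported with their error,
#' not fatal.
#'
#' @param cds Tibble with `id`, `sequence` (in-frame CDS).
#' @param pairs Tibble with `id_a`, `id_b`; all unordered pairs when `NULL`.
#' @return An `aqp_kaks` tibble: per-pair NG86 columns plus `verdict` and
#'   `error`; attribute `all_negative` is TRUE when every defined omega < 1.
#' @export
selection_scan <- function(cds, pairs = NULL) {
  if (is.null(pairs)) {
    if (nrow(cds) < 2) {
      pairs <- tibble(id_a = character(), id_b = character())
    } else {
      cmb <- utils::combn(cds$id, 2)
      pairs <- tibble(id_a = cmb[1, ], id_b = cmb[2, ])
    }
  }
  seq_of <- setNames(cds$sequence, cds$id)
  if (nrow(pairs) == 0) {
    empty <- tibble(id_a = character(), id_b = character(),
                    n_codons = integer(), N = numeric(), S = numeric(),
                    Nd = numeric(), Sd = numeric(), pN = numeric(),
                    pS = numeric(), ka = numeric(), ks = numeric(),
                    omega = numeric(), verdict = character(),
                    error = character())
    return(structure(empty, all_negative = FALSE,
                     class = c("aqp_kaks", class(empty))))
  }
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- pairs$id_a[k]
    b <- pairs$id_b[k]
    out <- tibble(id_a = a, id_b = b)
    r <- tryCatch({
      pa <- translate_cds(seq_of[[a]])
      pb <- translate_cds(seq_of[[b]])
      pa <- sub("\\*$", "", pa)
      pb <- sub("\\*$", "", pb)
      al <- global_align(pa, pb)
      kaks_ng86(backtranslate(al, seq_of[[a]], seq_of[[b]]))
    }, error = function(e) e)
    if (inherits(r, "error")) {
      dplyr::bind_cols(out, tibble(omega = NA_real_, verdict = NA_character_,
                                   error = conditionMessage(r)))
    } else {
      r$verdict <- dplyr::case_when(
        is.na(r$omega) ~ "neutral/undefined",
        r$omega < 1 ~ "negative",
        r$omega > 1 ~ "positive",
        TRUE ~ "neutral/undefined"
      )
      dplyr::bind_cols(out, r, tibble(error = NA_character_))
    }
  })
  defined <- res$omega[!is.na(res$omega)]
  structure(res, all_negative = length(defined) > 0 && all(defined < 1),
            class = c("aqp_kaks", class(res)))
}
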