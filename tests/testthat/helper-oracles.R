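# Independent oracles, deliberately coded along different routes than the
# package implementations they check.

# --- exhaustive global-alignment oracle -------------------------------------
# Enumerates every global alignment (all monotone paths) and scores each from
# its aligned strings, charging open + len * extend per maximal gap run.
enum_alignments <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(list(c("", "")))
  out <- list()
  if (nzchar(a) && nzchar(b)) {
    for (al in enum_alignments(substring(a, 2), substring(b, 2))) {
      out[[length(out) + 1]] <- c(paste0(substr(a, 1, 1), al[1]),
                                  paste0(substr(b, 1, 1), al[2]))
    }
  }
  if (nzchar(a)) {
    for (al in enum_alignments(substring(a, 2), b)) {
      out[[length(out) + 1]] <- c(paste0(substr(a, 1, 1), al[1]),
                                  paste0("-", al[2]))
    }
  }
  if (nzchar(b)) {
    for (al in enum_alignments(a, substring(b, 2))) {
      out[[length(out) + 1]] <- c(paste0("-", al[1]),
                                  paste0(substr(b, 1, 1), al[2]))
    }
  }
  out
}

score_alignment_strings <- function(sa, sb, sub, gap_open, gap_extend) {
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  score <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      score <- score + gap_extend + if (in_gap_a) 0 else gap_open
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      score <- score + gap_extend + if (in_gap_b) 0 else gap_open
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      score <- score + sub[ca[k], cb[k]]
      in_gap_a <- FALSE
      in_gap_b <- FALSE
    }
  }
  score
}

nw_oracle_score <- function(a, b, sub, gap_open = -10, gap_extend = -0.5) {
  max(vapply(enum_alignments(a, b), function(al) {
    score_alignment_strings(al[1], al[2], sub, gap_open, gap_extend)
  }, numeric(1)))
}

# --- NG86 pathway oracle ----------------------------------------------------
# Depth-first enumeration of minimal mutational pathways between two codons,
# averaging synonymous/nonsynonymous step counts over stop-free pathways
# (over all pathways when none is stop-free).
GC_TAB <- as.list(Biostrings::GENETIC_CODE)

oracle_codon_diffs <- function(ca, cb) {
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0, 0))) # sd, nd, blocked
    res <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      step_syn <- GC_TAB[[nxt]] == GC_TAB[[cur]]
      hits_stop <- GC_TAB[[nxt]] == "*" && length(remaining) > 1
      for (tail in walk(nxt, setdiff(remaining, p))) {
        res[[length(res) + 1]] <- c(tail[1] + step_syn, tail[2] + !step_syn,
                                    max(tail[3], hits_stop))
      }
    }
    res
  }
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  m <- do.call(rbind, walk(ca, pos))
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

oracle_site_counts <- function(codon) {
  aa <- GC_TAB[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (GC_TAB[[alt]] == aa) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# --- textbook two-pass Pearson r --------------------------------------------
two_pass_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# --- shared fixtures --------------------------------------------------------
sense_codon_set <- names(GC_TAB)[unlist(GC_TAB) != "*"]

edge_key <- function(d) paste(d$gene_a, d$gene_b)
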