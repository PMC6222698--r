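#' Molecular weight of a protein
#'
#' Sum of average-isotopic residue masses plus one water, following the
#' ProtParam convention, reported in kDa.
#'
#' @param sequence Residue string over the 20 canonical letters (X is an
#'   error: mass undefined).
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% AA_CANONICAL)
  if (length(bad) > 0) {
    stop("non-canonical residue(s) at position(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  (sum(AA_MASS[chars]) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the Bjellqvist pKa set (D, E, C, Y side
#' chains and C-terminus as acids; H, K, R side chains and N-terminus as
#' bases, with residue-specific N-terminal pKa).
#'
#' @param sequence Residue string (canonical letters).
#' @param ph pH value(s).
#' @return Net charge in elementary charges (vectorized over `ph`).
#' @export
protein_charge <- function(sequence, ph) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (any(!chars %in% AA_CANONICAL)) {
    stop("non-canonical residue(s) at position(s) ",
         paste(head(which(!chars %in% AA_CANONICAL), 5), collapse = ", "))
  }
  counts <- table(factor(chars, levels = AA_CANONICAL))
  nterm_pka <- if (chars[1] %in% names(PKA_NTERM)) PKA_NTERM[[chars[1]]] else PKA_NTERM_DEFAULT
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - nterm_pka)) +
      counts[["H"]] / (1 + 10^(p - PKA_SIDE[["H"]])) +
      counts[["K"]] / (1 + 10^(p - PKA_SIDE[["K"]])) +
      counts[["R"]] / (1 + 10^(p - PKA_SIDE[["R"]]))
    neg <- 1 / (1 + 10^(PKA_CTERM - p)) +
      counts[["D"]] / (1 + 10^(PKA_SIDE[["D"]] - p)) +
      counts[["E"]] / (1 + 10^(PKA_SIDE[["E"]] - p)) +
      counts[["C"]] / (1 + 10^(PKA_SIDE[["C"]] - p)) +
      counts[["Y"]] / (1 + 10^(PKA_SIDE[["Y"]] - p))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point
#'
#' pH at which the net charge (see [protein_charge()]) is zero, found by
#' bisection on the 0-14 pH interval to 1e-4 pH units. The charge function is monotone
#' decreasing in pH, so the root is unique.
#'
#' @param sequence Residue string (canonical letters).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence) {
  lo <- 0
  hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (protein_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Predict transmembrane segments by hydropathy scanning
#'
#' Kyte-Doolittle sliding-window scan: window means are computed for every
#' window start position; maximal runs of above-threshold starts expand to a
#' candidate segment spanning the first window's start through the last
#' window's end. Segments shorter than `min_len` are dropped, and segments
#' separated by fewer than `min_gap` residues are merged.
#'
#' @param sequence Residue string, length >= `window`.
#' @param window Sliding window width (residues).
#' @param threshold Mean hydropathy cutoff.
#' @param min_len Minimum segment length retained.
#' @param min_gap Segments closer than this many residues are merged.
#' @return Tibble with `start`, `end` (1-based inclusive), one row per
#'   predicted segment, sorted and non-overlapping.
#' @export
predict_tm <- function(sequence, window = 19, threshold = 1.6,
                       min_len = 18, min_gap = 5) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < window) stop("sequence shorter than scanning window")
  h <- unname(KD_SCALE[chars])
  h[is.na(h)] <- 0 # X and friends: neutral
  cs <- cumsum(c(0, h))
  starts <- seq_len(n - window + 1)
  means <- (cs[starts + window] - cs[starts]) / window
  above <- means >= threshold
  if (!any(above)) {
    return(tibble(start = integer(), end = integer()))
  }
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  seg <- tibble(
    start = starts[starts_idx[r$values]],
    end = pmin(starts[ends_idx[r$values]] + window - 1L, n)
  )
  seg <- seg[seg$end - seg$start + 1 >= min_len, , drop = FALSE]
  if (nrow(seg) > 1) {
    merged <- seg[1, ]
    for (i in seq(2, nrow(seg))) {
      gap <- seg$start[i] - merged$end[nrow(merged)] - 1
      if (gap < min_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  as_tibble(seg)
}

#' Physicochemical property table
#'
#' Per-protein length, molecular weight (kDa), isoelectric point (pH units)
#' and predicted transmembrane segment count, mirroring the usual
#' family-characterization table layout.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param ... Passed to [predict_tm()].
#' @return Tibble: `id`, `length_aa`, `mw_kda` (4 decimals), `pi` (2
#'   decimals), `n_tm`.
#' @export
protein_properties <- function(proteins, ...) {
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    tm <- predict_tm(s, ...)
    tibble(
      id = proteins$id[i],
      length_aa = nchar(s),
      mw_kda = round(molecular_weight(s), 4),
      pi = round(isoelectric_point(s), 2),
      n_tm = nrow(tm)
    )
  })
}
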