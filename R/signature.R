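# Residue-signature extraction: NPA boxes, ar/R selectivity filter, Froger
# positions, inter-NPA spacing, and the NIP-III silicon-transporter rule.

lb_window_of <- function(chars, start) {
  lo <- max(1L, start - 5L)
  hi <- min(length(chars), start + 4L)
  paste(chars[lo:hi], collapse = "")
}

le_window_of <- function(chars, start) {
  lo <- max(1L, start - 4L)
  hi <- min(length(chars), start + 6L)
  paste(chars[lo:hi], collapse = "")
}

window_similarity <- function(w, refs) {
  max(vapply(refs, function(r) {
    n <- min(nchar(w), nchar(r))
    if (n == 0) return(0)
    mean(strsplit(substr(w, 1, n), "")[[1]] == strsplit(substr(r, 1, n), "")[[1]])
  }, numeric(1)))
}

#' Locate NPA-like boxes in a protein
#'
#' Scans for tripeptides matching the degenerate pattern `N-[P,L]-[A,S,T,L,V]`
#' (the variant inventory NPA, NPS, NPT, NPL, NPV, NLA). With more than two
#' hits, the pair whose start-to-start spacing is closest to the canonical
#' 108 residues and whose context windows best match the subgroup template
#' boxes is kept. The N-terminal hit is labelled LB (10-residue window,
#' motif at offset 6), the C-terminal hit LE (11-residue window, motif at
#' offset 5). Windows at sequence bounds are clamped and flagged.
#'
#' @param sequence Residue string (length >= 50).
#' @return Tibble with columns `loop` ("LB"/"LE"), `motif_start` (1-based
#'   position of the N), `variant`, `window`, `flag` ("" / "incomplete" /
#'   "clamped"). Zero or one row when fewer than two hits are found.
#' @export
find_npa_boxes <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 50) stop("sequence too short for motif scanning (< 50)")
  chars <- strsplit(sequence, "")[[1]]
  hits <- stringr::str_locate_all(sequence, NPA_PATTERN)[[1]][, 1]
  empty <- tibble(loop = character(), motif_start = integer(),
                  variant = character(), window = character(), flag = character())
  if (length(hits) == 0) return(empty)
  if (length(hits) == 1) {
    return(tibble(loop = "LB", motif_start = as.integer(hits),
                  variant = substr(sequence, hits, hits + 2),
                  window = lb_window_of(chars, hits), flag = "incomplete"))
  }
  if (length(hits) > 2) {
    t <- aqp_templates()
    pairs <- utils::combn(hits, 2)
    score <- apply(pairs, 2, function(p) {
      window_similarity(lb_window_of(chars, p[1]), t$lb_box) +
        window_similarity(le_window_of(chars, p[2]), t$le_box) -
        abs(diff(p) - 108) / 108
    })
    hits <- sort(pairs[, which.max(score)])
  }
  lb <- as.integer(hits[1])
  le <- as.integer(hits[2])
  out <- tibble(
    loop = c("LB", "LE"),
    motif_start = c(lb, le),
    variant = substring(sequence, c(lb, le), c(lb, le) + 2),
    window = c(lb_window_of(chars, lb), le_window_of(chars, le)),
    flag = ""
  )
  out$flag[1] <- if (nchar(out$window[1]) < 10) "clamped" else ""
  out$flag[2] <- if (nchar(out$window[2]) < 11) "clamped" else ""
  out
}

#' Extract the conserved-residue signature of a protein
#'
#' Globally aligns the protein to every reference in the panel, keeps the
#' reference with the highest identity (ties: higher score, then id), and
#' maps the reference's nine annotated anchor columns (four ar/R + five
#' Froger) and two NPA starts through the alignment. Scanner-detected NPA
#' boxes are cross-checked against the mapped reference positions; the
#' alignment wins on disagreement when it lands on a valid motif. Anchors
#' mapped onto gaps are reported as `"-"` and lower the anchor confidence.
#'
#' @param proteins Tibble with `id`, `sequence` (one or more rows).
#' @param panel Reference panel, see [reference_panel()].
#' @param min_identity Below this best identity the protein is rejected.
#' @return Tibble, one row per protein: `id`, `lb_start`, `lb_variant`,
#'   `lb_window`, `le_start`, `le_variant`, `le_window`, `inter_npa`,
#'   `arr`, `froger`, `ref_used`, `ref_identity`, `anchor_confidence`.
#' @export
extract_signature <- function(proteins, panel = reference_panel(),
                              min_identity = 0.25) {
  if (nrow(panel) == 0) stop("empty reference panel")
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    .extract_one(proteins$id[i], proteins$sequence[i], panel, min_identity)
  })
}

.extract_one <- function(id, sequence, panel, min_identity) {
  als <- lapply(panel$sequence, function(r) global_align(sequence, r))
  ident <- vapply(als, `[[`, numeric(1), "identity")
  score <- vapply(als, `[[`, numeric(1), "score")
  ord <- order(-ident, -score, panel$id)
  best <- ord[1]
  if (ident[best] < min_identity) {
    stop("no usable reference for ", id,
         sprintf(" (best identity %.2f < %.2f)", ident[best], min_identity))
  }
  al <- als[[best]]
  # map reference positions -> query positions
  ref2query <- alignment_map(al$aligned_b, al$aligned_a)
  chars <- strsplit(sequence, "")[[1]]
  anchor_at <- function(ref_pos) {
    q <- ref2query[ref_pos]
    ifelse(is.na(q), "-", chars[q])
  }
  arr_res <- anchor_at(panel$arr_pos[[best]])
  fro_res <- anchor_at(panel$froger_pos[[best]])

  boxes <- find_npa_boxes(sequence)
  lb <- boxes$motif_start[boxes$loop == "LB"]
  le <- boxes$motif_start[boxes$loop == "LE"]
  # alignment cross-check: mapped reference NPA starts win on disagreement
  mapped_ok <- function(pos) {
    !is.na(pos) && pos + 2 <= length(chars) &&
      grepl(paste0("^", NPA_PATTERN, "$"),
            paste(chars[pos:(pos + 2)], collapse = ""))
  }
  m_lb <- ref2query[panel$lb_start[best]]
  m_le <- ref2query[panel$le_start[best]]
  if ((length(lb) == 0 || !identical(lb, m_lb)) && mapped_ok(m_lb)) lb <- m_lb
  if ((length(le) == 0 || !identical(le, m_le)) && mapped_ok(m_le)) le <- m_le
  if (length(lb) == 0 || length(le) == 0) {
    stop("incomplete NPA boxes for ", id, "; signature undefined")
  }
  anchors_mapped <- c(!is.na(ref2query[panel$arr_pos[[best]]]),
                      !is.na(ref2query[panel$froger_pos[[best]]]),
                      !is.na(m_lb), !is.na(m_le))
  tibble(
    id = id,
    lb_start = as.integer(lb),
    lb_variant = paste(chars[lb:(lb + 2)], collapse = ""),
    lb_window = lb_window_of(chars, lb),
    le_start = as.integer(le),
    le_variant = paste(chars[le:(le + 2)], collapse = ""),
    le_window = le_window_of(chars, le),
    inter_npa = as.integer(le - lb),
    arr = paste(arr_res, collapse = ","),
    froger = paste(fro_res, collapse = ","),
    ref_used = panel$id[best],
    ref_identity = ident[best],
    anchor_confidence = mean(anchors_mapped)
  )
}

#' NIP-III silicon-transporter test
#'
#' A protein is called a silicon transporter when its ar/R selectivity filter
#' is GSGR and its inter-NPA spacing is 108 residues (within `tolerance`).
#' The exact-spacing call (spacing == 108) is reported alongside.
#'
#' @param signature One-row signature tibble from [extract_signature()], or a
#'   tibble of several.
#' @param tolerance Allowed deviation from the canonical 108-residue spacing.
#' @return Tibble: `id`, `si_transporter`, `exact_spacing`, `rationale`.
#' @export
si_transporter_test <- function(signature, tolerance = 2) {
  filt_ok <- gsub(",", "", signature$arr) == "GSGR"
  sp_ok <- abs(signature$inter_npa - 108L) <= tolerance
  rationale <- dplyr::case_when(
    filt_ok & sp_ok ~ "GSGR filter and canonical 108-residue NPA spacing",
    !filt_ok & sp_ok ~ sprintf("filter is %s, not GSGR", signature$arr),
    filt_ok & !sp_ok ~ sprintf("spacing %d outside 108 +/- %d", signature$inter_npa, tolerance),
    TRUE ~ sprintf("filter is %s and spacing %d outside 108 +/- %d",
                   signature$arr, signature$inter_npa, tolerance)
  )
  tibble(
    id = signature$id,
    si_transporter = filt_ok & sp_ok,
    exact_spacing = signature$inter_npa == 108L,
    rationale = rationale
  )
}
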