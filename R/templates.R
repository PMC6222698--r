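# Subgroup templates and the synthetic AQP protein builder.
#
# Each template instantiates one subgroup's conserved-residue signature: the
# 10-residue loop-B NPA box, the 11-residue loop-E NPA box, the ar/R
# selectivity-filter tetrad (H2, H5, LE1, LE2) and the Froger pentad
# (P1..P5), as curated for the carnation aquaporin family. Transmembrane
# cores are fixed per subgroup (sequence conservation within a subgroup is
# what alignment anchoring relies on); seeds vary loop and terminus content.

NPA_PATTERN <- "N[PL][ASTLV]"
POLAR_ALPHA <- c("S", "T", "Q", "G", "D", "E", "K", "R", "H", "P")
POLAR_W <- c(3, 3, 1.5, 3, 2, 2.5, 2.5, 1.5, 1, 1.5)
HYDRO_ALPHA <- c("L", "I", "V", "F", "A", "M")
HYDRO_W <- c(0.25, 0.20, 0.20, 0.15, 0.10, 0.10)

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Subgroup signature templates
#'
#' One row per aquaporin subgroup found in carnation (PIP1, PIP2, TIP1-TIP5,
#' NIP4-NIP6, SIP1, SIP2, XIP1), carrying the subgroup's curated NPA box
#' windows, ar/R tetrad, Froger pentad, and default inter-NPA spacing
#' (motif start to motif start).
#'
#' @return Tibble: `subgroup`, `subfamily`, `lb_box`, `le_box`, `arr`,
#'   `froger`, `n_tm`, `inter_npa`.
#' @export
aqp_templates <- function() {
  t <- tibble::tribble(
    ~subgroup, ~lb_box,      ~le_box,       ~arr,      ~froger,       ~inter_npa,
    "PIP1",   "SGGHINPAVT", "GTGINPARSLG", "F,H,T,R", "Q,S,A,F,W",   115L,
    "PIP2",   "SGGHINPAVT", "GTGINPARSFG", "F,H,T,R", "M,S,A,F,W",   115L,
    "TIP1",   "SGGHVNPAIT", "GASMNPAVSFG", "H,I,A,V", "T,S,A,Y,W",   108L,
    "TIP2",   "SGGHLNPAVT", "GGSMNPARSFG", "H,I,G,R", "T,S,A,Y,W",   108L,
    "TIP3",   "SGGHVNPAVT", "GASMNPARAFG", "H,I,A,R", "T,A,A,Y,W",   108L,
    "TIP4",   "SGGHLNPAVT", "AASMNPARSFG", "H,I,A,R", "T,S,A,Y,W",   108L,
    "TIP5",   "SGGHVNPAVT", "GGSMNPAYSFG", "N,V,G,Y", "T,S,A,Y,W",   108L,
    "NIP4",   "SGAHFNPAVT", "GASMNPARSIG", "W,F,A,R", "F,S,A,Y,I",   108L,
    "NIP5",   "SGAHLNPSLT", "GGSMNPVRTLG", "A,I,G,R", "F,T,A,Y,L",   108L,
    "NIP6",   "SGAHLNPALT", "GASMNPVRTLG", "A,I,A,R", "F,T,A,Y,L",   108L,
    "SIP1",   "GGASFNPTGT", "GFSMNPANAFG", "I,V,P,N", "M,A,A,Y,W",   106L,
    "SIP2",   "KAGNYNPLTL", "GGCMNPASVMG", "S,Q,G,S", "F,V,A,Y,W",   106L,
    "XIP1",   "SGGHINPSVT", "GAGMNPARCVG", "I,T,A,R", "V,C,A,Y,W",   110L
  )
  t$subfamily <- sub("[0-9]+$", "", t$subgroup)
  t$n_tm <- 6L
  validate_template(t)
  t[, c("subgroup", "subfamily", "lb_box", "le_box", "arr", "froger", "n_tm", "inter_npa")]
}

validate_template <- function(t) {
  stopifnot(all(nchar(t$lb_box) == 10), all(nchar(t$le_box) == 11))
  lb_motif <- substr(t$lb_box, 6, 8)
  le_motif <- substr(t$le_box, 5, 7)
  if (!all(grepl(paste0("^", NPA_PATTERN, "$"), lb_motif))) {
    stop("LB box without a canonical-offset NPA-like motif")
  }
  if (!all(grepl(paste0("^", NPA_PATTERN, "$"), le_motif))) {
    stop("LE box without a canonical-offset NPA-like motif")
  }
  invisible(t)
}

split_res <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

rand_polar <- function(n) {
  paste(sample(POLAR_ALPHA, n, replace = TRUE, prob = POLAR_W), collapse = "")
}

CAP_ALPHA <- c("D", "E", "K", "R") # strongly hydrophilic helix-flanking caps

rand_cap <- function(n) paste(sample(CAP_ALPHA, n, replace = TRUE), collapse = "")

# loop with hydrophilic caps on both ends, so hydropathy windows spanning a
# helix-loop boundary drop below threshold quickly
rand_loop <- function(n, cap = 6L) {
  if (n <= 2 * cap) return(rand_cap(n))
  paste0(rand_cap(cap), rand_polar(n - 2L * cap), rand_cap(cap))
}

# fixed hydrophobic TM cores per template (deterministic in the subgroup
# name, independent of the user's seed)
template_helices <- function(subgroup, arr) {
  seed <- sum(utf8ToInt(subgroup) * 31^(seq_len(nchar(subgroup)) - 1)) + 7
  lens <- c(19L, 19L, 18L, 18L, 19L, 19L)
  with_seed(seed, {
    hx <- lapply(lens, function(L) {
      sample(HYDRO_ALPHA, L, replace = TRUE, prob = HYDRO_W)
    })
    a <- split_res(arr)
    hx[[2]][10] <- a[1]                  # ar/R H2
    hx[[2]][11:12] <- c("F", "M")        # guard: no spurious NPA-like motif
    hx[[5]][10] <- a[2]                  # ar/R H5
    hx[[5]][11:12] <- c("F", "M")
    vapply(hx, paste, character(1), collapse = "")
  })
}

#' Generate a synthetic aquaporin-like protein from a subgroup template
#'
#' Builds a protein with the canonical MIP architecture: an N-terminal polar
#' segment, six hydrophobic transmembrane stretches, the template's loop-B
#' NPA box after helix 2, its loop-E NPA box placed so that the NPA-to-NPA
#' start distance equals `inter_npa`, and the ar/R and Froger residues at
#' template-anchored positions. The transmembrane cores are fixed per
#' subgroup; the seed varies loop and terminus lengths/content. All planted
#' coordinates are returned as ground truth.
#'
#' @param subgroup Subgroup name (row of [aqp_templates()]) or a one-row
#'   template tibble with the same columns (custom templates allowed).
#' @param seed Integer seed; same template + seed reproduces the sequence.
#' @param id Record identifier (default derived from subgroup and seed).
#' @param inter_npa Override the template's NPA start-to-start spacing.
#' @return List with `protein` (one-row tibble: id, description, sequence)
#'   and `truth` (one-row tibble of planted annotations; positions 1-based).
#' @export
make_protein <- function(subgroup, seed, id = NULL, inter_npa = NULL) {
  tpl <- if (is.data.frame(subgroup)) {
    validate_template(subgroup)
    subgroup[1, ]
  } else {
    t <- aqp_templates()
    row <- t[t$subgroup == subgroup, ]
    if (nrow(row) == 0) stop("unknown subgroup: ", subgroup)
    row
  }
  if (is.null(inter_npa)) inter_npa <- tpl$inter_npa
  if (is.null(id)) id <- sprintf("SYN_%s_s%d", tpl$subgroup, seed)
  arr <- split_res(tpl$arr)
  fro <- split_res(tpl$froger)
  hx <- template_helices(tpl$subgroup, tpl$arr)

  with_seed(seed, {
    nterm <- paste0(rand_polar(sample(7:17, 1)), rand_cap(6))
    loopA <- rand_loop(sample(17:18, 1))
    lbHead <- paste0(rand_cap(6), rand_polar(sample(2:4, 1)))
    lbTail <- rand_cap(5)
    d_len <- 16L
    c_len <- inter_npa - 74L - d_len
    if (c_len < 4) {
      d_len <- inter_npa - 78L # squeeze loop D for tight custom spacings
      c_len <- 4L
    }
    if (d_len < 4) {
      stop("inter_npa ", inter_npa, " incompatible with the length budget (needs >= 86)")
    }
    loopC <- rand_loop(c_len)
    loopD <- rand_loop(d_len)
    leHead <- rand_cap(5)
    leTail <- strsplit(paste0(rand_polar(6), rand_cap(4)), "")[[1]]
    leTail[3] <- fro[1] # Froger P1 sits in loop E
    le1_in_window <- arr[3] == substr(tpl$le_box, 2, 2)
    le2_in_window <- arr[4] == substr(tpl$le_box, 8, 8)
    if (!le1_in_window) leTail[5] <- arr[3]
    if (!le2_in_window) leTail[6] <- arr[4]
    cterm <- strsplit(paste0(rand_cap(2), rand_polar(10)), "")[[1]]
    cterm[c(3, 6, 9, 10)] <- fro[2:5] # Froger P2..P5
    cpad <- rand_polar(sample(6:14, 1))

    segs <- c(nterm, hx[1], loopA, hx[2], lbHead, tpl$lb_box, lbTail, hx[3],
              loopC, hx[4], loopD, hx[5], leHead, tpl$le_box,
              paste(leTail, collapse = ""), hx[6],
              paste(cterm, collapse = ""), cpad)
    seq <- paste(segs, collapse = "")
    off <- cumsum(c(0, nchar(segs))) # off[k] = chars before segment k

    lb_win_start <- off[6] + 1L
    le_win_start <- off[14] + 1L
    lb_start <- lb_win_start + 5L
    le_start <- le_win_start + 4L
    stopifnot(le_start - lb_start == inter_npa)
    h2_pos <- off[4] + 10L
    h5_pos <- off[12] + 10L
    le1_pos <- if (le1_in_window) le_win_start + 1L else off[15] + 5L
    le2_pos <- if (le2_in_window) le_win_start + 7L else off[15] + 6L
    p1_pos <- off[15] + 3L
    p25_pos <- off[17] + c(3L, 6L, 9L, 10L)
    tm_start <- off[c(2, 4, 8, 10, 12, 16)] + 1L
    tm_end <- tm_start + nchar(unlist(hx)) - 1L

    arr_pos <- c(h2_pos, h5_pos, le1_pos, le2_pos)
    froger_pos <- c(p1_pos, p25_pos)
    chars <- strsplit(seq, "")[[1]]
    stopifnot(identical(chars[arr_pos], arr), identical(chars[froger_pos], fro))

    list(
      protein = tibble(
        id = id,
        description = sprintf("synthetic %s aquaporin (seed %d)", tpl$subgroup, seed),
        sequence = seq
      ),
      truth = tibble(
        id = id, subgroup = tpl$subgroup, subfamily = tpl$subfamily,
        lb_start = lb_start, le_start = le_start,
        lb_variant = substr(tpl$lb_box, 6, 8), le_variant = substr(tpl$le_box, 5, 7),
        inter_npa = as.integer(inter_npa),
        arr = tpl$arr, froger = tpl$froger,
        arr_pos = list(arr_pos), froger_pos = list(froger_pos),
        tm_start = list(tm_start), tm_end = list(tm_end),
        length = nchar(seq)
      )
    )
  })
}

#' Annotated reference panel
#'
#' One synthetic exemplar per subgroup, generated deterministically from the
#' subgroup templates, with residue-level annotations of both NPA motif
#' starts, the four ar/R columns and the five Froger columns. It plays the
#' role of the curated cross-species exemplar panels used in family
#' classification; the exemplars here are synthetic template instances, not
#' database sequences.
#'
#' @return Tibble: `id`, `subgroup`, `subfamily`, `sequence`, `lb_start`,
#'   `le_start`, `arr`, `froger`, and list-columns `arr_pos`, `froger_pos`.
#' @export
reference_panel <- function() {
  if (!is.null(.aq_cache$panel)) return(.aq_cache$panel)
  t <- aqp_templates()
  panel <- purrr::map_dfr(seq_len(nrow(t)), function(i) {
    mp <- make_protein(t$subgroup[i], seed = 1000L + i,
                       id = paste0("REF_", t$subgroup[i]))
    dplyr::bind_cols(
      mp$protein[, c("id", "sequence")],
      mp$truth[, c("subgroup", "subfamily", "lb_start", "le_start",
                   "arr", "froger", "arr_pos", "froger_pos")]
    )
  })
  .aq_cache$panel <- panel
  panel
}
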