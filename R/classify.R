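# Homology-based subfamily/subgroup assignment and systematic nomenclature.

#' Assign subfamily and subgroup by nearest reference
#'
#' Each protein inherits subfamily and subgroup from the panel reference with
#' the highest global-alignment identity (ties: higher alignment score, then
#' lexicographic reference id). Proteins whose best identity falls below
#' `min_identity` are reported as unclassified. Calls where the top two
#' references disagree in subgroup with identities within 0.02 are flagged
#' ambiguous.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param panel Reference panel ([reference_panel()]).
#' @param min_identity Identity floor for classification (default 0.35;
#'   aquaporin subfamilies are deeply diverged and calls below it are
#'   unreliable).
#' @return Tibble: `id`, `subfamily`, `subgroup`, `nearest_reference`,
#'   `identity`, `ambiguous`.
#' @export
assign_subfamily <- function(proteins, panel = reference_panel(),
                             min_identity = 0.35) {
  if (nrow(panel) == 0) stop("empty reference panel")
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    als <- lapply(panel$sequence, function(r) {
      global_align(proteins$sequence[i], r)
    })
    ident <- vapply(als, `[[`, numeric(1), "identity")
    score <- vapply(als, `[[`, numeric(1), "score")
    ord <- order(-ident, -score, panel$id)
    b <- ord[1]
    unclass <- ident[b] < min_identity
    amb <- FALSE
    if (!unclass && length(ord) > 1) {
      b2 <- ord[2]
      amb <- panel$subgroup[b2] != panel$subgroup[b] &&
        (ident[b] - ident[b2]) < 0.02
    }
    tibble(
      id = proteins$id[i],
      subfamily = if (unclass) "unclassified" else panel$subfamily[b],
      subgroup = if (unclass) NA_character_ else panel$subgroup[b],
      nearest_reference = panel$id[b],
      identity = ident[b],
      ambiguous = amb
    )
  })
}

#' Assign systematic names within subgroups
#'
#' Within each subgroup, members are ordered by descending identity to their
#' nearest reference (ties by id) and numbered `<prefix><subgroup>;1`,
#' `;2`, ... Curated names already in use are preserved: a named entry of
#' `curated` (name = protein id, value = curated name) pins that protein,
#' and every curated value reserves its number so new members continue after
#' the highest reserved index.
#'
#' @param calls Classification tibble from [assign_subfamily()].
#' @param species_prefix Name prefix, e.g. `"Dca"` for carnation.
#' @param curated Optional character vector of names in use (optionally named
#'   by protein id to pin inputs to their curated names).
#' @return `calls` with an `assigned_name` column (NA for unclassified).
#' @export
name_members <- function(calls, species_prefix = "Dca", curated = NULL) {
  if (anyDuplicated(curated)) {
    stop("duplicate curated names: ", curated[duplicated(curated)][1])
  }
  calls$assigned_name <- NA_character_
  if (nrow(calls) == 0) return(calls)
  pinned <- if (!is.null(names(curated))) curated[nzchar(names(curated))] else character()
  calls$assigned_name[match(names(pinned), calls$id)] <- unname(pinned)
  for (sg in unique(calls$subgroup[!is.na(calls$subgroup)])) {
    stem <- paste0(species_prefix, sg, ";")
    reserved <- c(curated, calls$assigned_name)
    reserved <- reserved[!is.na(reserved) & startsWith(reserved, stem)]
    next_k <- if (length(reserved) == 0) 1L else {
      max(as.integer(sub(".*;", "", reserved))) + 1L
    }
    idx <- which(calls$subgroup == sg & is.na(calls$assigned_name))
    idx <- idx[order(-calls$identity[idx], calls$id[idx])]
    if (length(idx) > 0) {
      calls$assigned_name[idx] <- paste0(stem, seq(next_k, next_k + length(idx) - 1))
    }
  }
  dup <- calls$assigned_name[!is.na(calls$assigned_name)]
  if (anyDuplicated(dup)) stop("name collision: ", dup[duplicated(dup)][1])
  calls
}

#' Subfamily census
#'
#' Counts classified members per subfamily; unclassified proteins are tallied
#' separately.
#'
#' @param calls Classification tibble from [assign_subfamily()].
#' @return Tibble `subfamily`, `n` covering PIP, TIP, NIP, SIP, XIP and
#'   unclassified (zero-filled).
#' @export
family_census <- function(calls) {
  levels <- c("PIP", "TIP", "NIP", "SIP", "XIP", "unclassified")
  tibble(
    subfamily = levels,
    n = unname(vapply(levels, function(l) sum(calls$subfamily == l), integer(1)))
  )
}
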