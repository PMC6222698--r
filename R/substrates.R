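# Rule-based substrate-specificity prediction from residue signatures.
#
# The prediction is a literature-derived lookup: a rule keys on subgroup,
# ar/R tetrad and Froger pentad, optionally narrowed by exact LB/LE box
# windows (the published carnation table contains signature-identical
# proteins with different predictions that differ only in subgroup or in a
# box window, so the tetrad+pentad key alone is not injective). Rules are
# shipped as data, not code, so the mapping is auditable and extensible.

SUBSTRATE_VOCAB <- c("Boron", "CO2", "H2O2", "Urea", "Ammonia", "Silicon", "Water")

split_substrates <- function(x) {
  ifelse(is.na(x) | !nzchar(x), list(character()), strsplit(x, ",", fixed = TRUE))
}

#' Load the substrate rule table
#'
#' @param path Optional path to a rule TSV (columns `rule_id`, `subgroup`,
#'   `arr`, `froger`, `lb_box`, `le_box`, `hove`, `azad`, `provenance`;
#'   `*` = wildcard). Defaults to the packaged rules for the carnation
#'   aquaporin family.
#' @return Validated rule tibble.
#' @export
substrate_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "substrate_rules.tsv", package = "aquascan")
  }
  rules <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c("rule_id", "subgroup", "arr", "froger", "lb_box", "le_box", "hove", "azad")
  if (!all(need %in% names(rules))) {
    stop("malformed rule table: missing column(s) ",
         paste(setdiff(need, names(rules)), collapse = ", "))
  }
  subs <- unlist(c(split_substrates(rules$hove), split_substrates(rules$azad)))
  bad <- setdiff(subs, SUBSTRATE_VOCAB)
  if (length(bad) > 0) stop("unknown substrate in rule table: ", bad[1])
  rules
}

#' The published carnation aquaporin signature table
#'
#' Curated residue signatures (NPA box windows, ar/R tetrad, Froger pentad)
#' and literature-based substrate assignments (Hove and Azad schemes) for the
#' 30 carnation (Dianthus caryophyllus) aquaporins.
#'
#' @return Tibble with columns `gene`, `subgroup`, `lb_box`, `le_box`,
#'   `arr`, `froger`, `hove`, `azad`.
#' @export
dca_signature_table <- function() {
  path <- system.file("extdata", "dca_aqp_signatures.tsv", package = "aquascan")
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  x$hove[is.na(x$hove)] <- ""
  x$azad[is.na(x$azad)] <- ""
  x
}

#' Predict transported substrates from a residue signature
#'
#' Matches each signature against the rule table: a rule applies when its
#' subgroup, ar/R tetrad and Froger pentad equal the query's and its LB/LE
#' box fields are wildcards or equal the query's box windows. The most
#' specific applicable rule wins (most non-wildcard box fields); no match
#' yields an empty prediction. The NIP-III silicon call
#' ([si_transporter_test()]) is appended independently of the rules.
#'
#' @param signatures Signature tibble from [extract_signature()] (or any
#'   tibble with `id`, `lb_window`, `le_window`, `arr`, `froger`,
#'   `inter_npa`).
#' @param calls Classification tibble from [assign_subfamily()] (needs `id`,
#'   `subgroup`).
#' @param rules Rule table ([substrate_rules()]).
#' @return Tibble: `id`, `hove`, `azad` (comma-joined substrate sets, ""
#'   when empty), `matched_rule` (NA when none), `si_transporter`.
#' @export
predict_substrates <- function(signatures, calls, rules = substrate_rules()) {
  sg <- setNames(calls$subgroup, calls$id)
  si <- si_transporter_test(signatures)
  purrr::map_dfr(seq_len(nrow(signatures)), function(i) {
    s <- signatures[i, ]
    subgroup <- sg[[s$id]]
    hit <- rules[
      !is.na(subgroup) &
        rules$subgroup == subgroup &
        rules$arr == s$arr &
        rules$froger == s$froger &
        (rules$lb_box == "*" | rules$lb_box == s$lb_window) &
        (rules$le_box == "*" | rules$le_box == s$le_window),
    ]
    if (nrow(hit) > 1) {
      spec <- (hit$lb_box != "*") + (hit$le_box != "*")
      hit <- hit[order(-spec, hit$rule_id), ][1, ]
    }
    tibble(
      id = s$id,
      hove = if (nrow(hit) == 1) ifelse(is.na(hit$hove), "", hit$hove) else "",
      azad = if (nrow(hit) == 1) ifelse(is.na(hit$azad), "", hit$azad) else "",
      matched_rule = if (nrow(hit) == 1) hit$rule_id else NA_character_,
      si_transporter = si$si_transporter[i]
    )
  })
}
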