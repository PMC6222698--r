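#' Read a FASTA file into a tibble
#'
#' Parses a protein or nucleotide FASTA file into one row per record.
#' Sequences are uppercased; duplicate identifiers are an error. The
#' identifier is the first whitespace-delimited token of the header, the
#' remainder (if any) becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble(id = character(), description = character(), sequence = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("malformed FASTA: line 1 does not start with '>' in ", path)
  }
  bad <- which(is_hdr & nchar(trimws(substring(lines, 2))) == 0)
  if (length(bad) > 0) stop("malformed FASTA header at record ", bad[1])
  grp <- cumsum(is_hdr)
  headers <- trimws(substring(lines[is_hdr], 2))
  seqs <- vapply(
    split(lines[!is_hdr], grp[!is_hdr]),
    function(x) toupper(paste(x, collapse = "")), character(1)
  )
  # records with no sequence lines would drop out of the split; realign
  seq_full <- rep("", length(headers))
  seq_full[as.integer(names(seqs))] <- seqs
  if (any(seq_full == "")) {
    stop("FASTA record with empty sequence: ", headers[seq_full == ""][1])
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1])
  }
  tibble(id = ids, description = desc, sequence = unname(seq_full))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with columns `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[i])) paste(x$id[i], desc[i]) else x$id[i]
    s <- x$sequence[i]
    chunks <- substring(s, seq(1, nchar(s), width), pmin(seq(width, nchar(s) + width - 1, width), nchar(s)))
    writeLines(c(paste0(">", hdr), chunks), con)
  }
  invisible(path)
}

#' Validate a protein tibble against the canonical alphabet
#'
#' @param x Tibble with `id` and `sequence` columns.
#' @param allow_x Permit the ambiguity letter X.
#' @return `x`, invisibly, or an error naming the offending record.
#' @export
validate_proteins <- function(x, allow_x = TRUE) {
  alpha <- paste0(c(AA_CANONICAL, if (allow_x) "X"), collapse = "")
  bad <- grepl(sprintf("[^%s]", alpha), x$sequence)
  if (any(bad)) {
    stop("non-canonical residues in record ", x$id[bad][1])
  }
  if (any(!nzchar(x$sequence))) stop("empty sequence in record ", x$id[!nzchar(x$sequence)][1])
  if (anyDuplicated(x$id)) stop("duplicate id: ", x$id[duplicated(x$id)][1])
  invisible(x)
}

# ---- expression matrices ----------------------------------------------------

#' Construct an expression matrix
#'
#' An expression matrix is a tibble whose first column is `gene_id` and whose
#' remaining columns are numeric per-sample values, carrying a unit tag that
#' records its transformation history (`counts`, `fpkm`, `log2fpkm1`, or
#' `relative`).
#'
#' @param x Data frame with a `gene_id` column and numeric sample columns.
#' @param unit One of `"counts"`, `"fpkm"`, `"log2fpkm1"`, `"relative"`.
#' @return An `aqp_expr` tibble.
#' @export
expression_matrix <- function(x, unit = c("counts", "fpkm", "log2fpkm1", "relative")) {
  unit <- match.arg(unit)
  x <- as_tibble(x)
  if (names(x)[1] != "gene_id") stop("first column must be 'gene_id'")
  vals <- x[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) stop("sample columns must be numeric")
  if (anyNA(vals)) stop("missing cells are not allowed in an expression matrix")
  if (any(as.matrix(vals) < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id")
  structure(x, unit = unit, class = c("aqp_expr", class(x)))
}

#' @export
print.aqp_expr <- function(x, ...) {
  cat(sprintf("# Expression matrix: %d genes x %d samples [unit: %s]\n",
              nrow(x), ncol(x) - 1, expr_unit(x)))
  NextMethod()
}

#' Unit tag of an expression matrix
#' @param x An `aqp_expr` object.
#' @return The unit string.
#' @export
expr_unit <- function(x) attr(x, "unit")

expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

new_expr_from_values <- function(m, unit) {
  expression_matrix(
    dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m)),
    unit = unit
  )
}

#' Read a gene-by-sample TSV into an expression matrix
#'
#' The first column must hold gene identifiers and the header row sample
#' identifiers. A `# unit: <unit>` comment line, when present, declares the
#' unit; otherwise `unit` must be supplied.
#'
#' @param path Path to a tab-separated file.
#' @param unit Declared unit; overrides any header comment.
#' @return An `aqp_expr` tibble.
#' @export
read_expression_tsv <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 5)
  hdr_unit <- sub("^#\\s*unit:\\s*", "", grep("^#\\s*unit:", first, value = TRUE))
  if (is.null(unit)) {
    if (length(hdr_unit) == 0) stop("no unit comment in file; supply `unit`")
    unit <- hdr_unit[1]
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(df)[1] <- "gene_id"
  for (j in seq(2, ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) | is.na(col))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s'", bad, names(df)[j]))
    }
  }
  if (anyNA(df)) {
    idx <- which(is.na(df), arr.ind = TRUE)[1, ]
    stop(sprintf("blank cell at row %d, column '%s'", idx[1], names(df)[idx[2]]))
  }
  expression_matrix(df, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Writes a `# unit:` comment line followed by the gene-by-sample table, so
#' that [read_expression_tsv()] round-trips losslessly.
#'
#' @param x An `aqp_expr` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  writeLines(sprintf("# unit: %s", expr_unit(x)), con)
  close(con)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
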