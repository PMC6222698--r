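# Field constants: residue masses, pKa sets, hydropathy scale, genetic code.

# Average isotopic residue (monomer minus water) masses in Da, as used by
# ExPASy ProtParam. One water (18.01524 Da) is added per chain.
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist pKa set (the ProtParam set): side chains, C-terminus, and
# residue-specific N-terminal pKa values.
PKA_SIDE <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0, R = 12.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
PKA_NTERM_DEFAULT <- 7.5

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,  E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5,  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA_CANONICAL <- names(AA_MASS)

# Standard genetic code, from Biostrings
genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_cds <- function(nt) {
  if (nchar(nt) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  paste(unname(genetic_code()[codons]), collapse = "")
}

blosum62 <- function() {
  if (is.null(.aq_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aq_cache$blosum62 <- e$BLOSUM62
  }
  .aq_cache$blosum62
}
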