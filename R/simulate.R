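# Seeded generators for every input class the pipeline consumes, with
# planted ground truth. All generators are pure functions of (parameters,
# seed).

#' Generate a coding-sequence pair with controlled divergence
#'
#' Builds a random stop-free ancestral CDS and a derived copy carrying
#' planted single-nucleotide substitutions: synonymous changes sized so that
#' the Nei-Gojobori Ks approaches `ks_target` and nonsynonymous changes so
#' that Ka approaches `omega * ks_target`. Each mutated codon carries exactly
#' one change, so the planted difference counts are recovered exactly by
#' NG86 counting. No stop codons are introduced.
#'
#' @param n_codons Codons in the CDS (>= 50).
#' @param omega Target Ka/Ks ratio (>= 0; 0 plants no nonsynonymous change).
#' @param ks_target Target synonymous rate (0 <= ks_target < 0.75-ish; 0
#'   requests an identical pair).
#' @param seed Integer seed.
#' @return List: `cds` (tibble `id`, `sequence` with ids "anc", "der") and
#'   `truth` (tibble with planted `sd`, `nd` counts and targets).
#' @export
make_cds_pair <- function(n_codons, omega, ks_target, seed) {
  if (n_codons < 50) stop("n_codons must be >= 50")
  if (omega < 0) stop("omega must be >= 0")
  if (ks_target < 0 || ks_target >= 0.75) stop("ks_target must be in [0, 0.75)")
  gc <- as.list(genetic_code())
  with_seed(seed, {
    codons <- sample(sense_codons(), n_codons, replace = TRUE)
    sites <- vapply(codons, .codon_site_counts, numeric(2), gc = gc)
    S <- sum(sites["syn", ])
    N <- sum(sites["nonsyn", ])
    pS <- 0.75 * (1 - exp(-4 * ks_target / 3))
    pN <- 0.75 * (1 - exp(-4 * omega * ks_target / 3))
    sd_n <- round(pS * S)
    nd_n <- round(pN * N)

    single_changes <- function(codon, synonymous) {
      out <- character()
      for (p in 1:3) {
        for (nt in setdiff(NT, substr(codon, p, p))) {
          alt <- codon
          substr(alt, p, p) <- nt
          if (gc[[alt]] == "*") next
          if ((gc[[alt]] == gc[[codon]]) == synonymous) out <- c(out, alt)
        }
      }
      out
    }
    syn_ok <- which(vapply(codons, function(c) length(single_changes(c, TRUE)) > 0, logical(1)))
    der <- codons
    if (sd_n + nd_n > n_codons) {
      stop("targets unreachable at ", n_codons, " codons; increase n_codons")
    }
    if (length(syn_ok) < sd_n) {
      stop("not enough synonymous-capable codons; increase n_codons")
    }
    syn_idx <- sample(syn_ok, sd_n)
    for (i in syn_idx) {
      opts <- single_changes(codons[i], TRUE)
      der[i] <- opts[sample.int(length(opts), 1)]
    }
    non_pool <- setdiff(seq_len(n_codons), syn_idx)
    non_ok <- non_pool[vapply(codons[non_pool],
                              function(c) length(single_changes(c, FALSE)) > 0,
                              logical(1))]
    if (length(non_ok) < nd_n) {
      stop("not enough nonsynonymous-capable codons; increase n_codons")
    }
    non_idx <- sample(non_ok, nd_n)
    for (i in non_idx) {
      opts <- single_changes(codons[i], FALSE)
      der[i] <- opts[sample.int(length(opts), 1)]
    }
    list(
      cds = tibble(
        id = c("anc", "der"),
        sequence = c(paste(codons, collapse = ""), paste(der, collapse = ""))
      ),
      truth = tibble(n_codons = n_codons, omega = omega, ks_target = ks_target,
                     sd_planted = sd_n, nd_planted = nd_n, S = S, N = N)
    )
  })
}

#' Generate an FPKM-like expression matrix with planted correlation structure
#'
#' Genes of one module share a latent per-sample profile (plus Gaussian noise
#' on the log2 scale); each planted negative pair anti-shares a latent
#' profile; remaining genes follow independent latents. Values are emitted on
#' an FPKM-like scale (roughly 0-500) such that `log2(FPKM + 1)` returns the
#' latent-space values exactly, so correlation analysis operates on the
#' planted structure. At `noise_sd = 0`, within-module correlations are
#' exactly +1 and negative-pair correlations exactly -1.
#'
#' @param n_genes,n_samples Matrix dimensions (`n_samples >= 8`).
#' @param modules List of disjoint integer vectors (gene indices) sharing a
#'   profile.
#' @param negative_pairs List of length-2 integer vectors (gene indices).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param seed Integer seed.
#' @return List: `expr` (an `aqp_expr`, unit fpkm), `truth` (tibble of
#'   planted edges: `gene_a`, `gene_b`, `sign`).
#' @export
make_expression <- function(n_genes, n_samples, modules = list(),
                            negative_pairs = list(), noise_sd = 0.3, seed = 1) {
  if (n_samples < 8) stop("n_samples must be >= 8")
  mod_genes <- unlist(modules)
  if (anyDuplicated(mod_genes)) stop("modules must be disjoint")
  neg_genes <- unlist(negative_pairs)
  if (any(neg_genes %in% mod_genes) || anyDuplicated(neg_genes)) {
    stop("negative pairs must not overlap modules or each other")
  }
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  with_seed(seed, {
    amp <- 2.0
    logm <- matrix(NA_real_, n_genes, n_samples)
    noise <- function() rnorm(n_samples, 0, noise_sd)
    for (mod in modules) {
      z <- runif(n_samples, -1.5, 1.5)
      for (g in mod) logm[g, ] <- runif(1, 4.5, 5.5) + amp * z + noise()
    }
    for (np in negative_pairs) {
      z <- runif(n_samples, -1.5, 1.5)
      logm[np[1], ] <- runif(1, 4.5, 5.5) + amp * z + noise()
      logm[np[2], ] <- runif(1, 4.5, 5.5) - amp * z + noise()
    }
    for (g in which(is.na(logm[, 1]))) {
      z <- runif(n_samples, -1.5, 1.5)
      logm[g, ] <- runif(1, 4.5, 5.5) + amp * z + noise()
    }
    fpkm <- pmax(2^logm - 1, 0)
    dimnames(fpkm) <- list(gene_ids, sample_ids)
    edge <- function(gs, sign) {
      if (length(gs) < 2) return(NULL)
      cmb <- utils::combn(sort(gene_ids[gs]), 2)
      tibble(gene_a = cmb[1, ], gene_b = cmb[2, ], sign = sign)
    }
    truth <- dplyr::bind_rows(
      purrr::map_dfr(modules, edge, sign = "positive"),
      purrr::map_dfr(negative_pairs, edge, sign = "negative")
    )
    list(expr = new_expr_from_values(fpkm, unit = "fpkm"), truth = truth)
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' The reference gene holds a constant Ct in every sample and replicate;
#' each target gene's Ct in a sample is shifted by `-log2(fold_change)`
#' relative to the calibrator (first sample), plus replicate noise.
#'
#' @param genes Character vector of target gene ids.
#' @param samples Character vector of sample ids; the first is the
#'   calibrator.
#' @param fold_changes Matrix (genes x samples) of positive fold changes
#'   relative to the calibrator, or a single number recycled; the calibrator
#'   column is forced to 1.
#' @param n_replicates Replicates per (gene, sample).
#' @param noise_sd Replicate noise SD in cycles (technical-replicate scale).
#' @param reference_gene Reference gene id.
#' @param seed Integer seed.
#' @return List: `ct` (tibble `gene_id`, `sample_id`, `replicate`, `ct`),
#'   `truth` (tibble `gene_id`, `sample_id`, `fold_change`),
#'   `reference_gene`, `calibrator`.
#' @export
make_ct_table <- function(genes, samples, fold_changes, n_replicates = 3,
                          noise_sd = 0.05, reference_gene = "GADPH", seed = 1) {
  fc <- matrix(fold_changes, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  fc[, 1] <- 1
  if (any(fc <= 0)) stop("fold changes must be positive")
  with_seed(seed, {
    base_ct <- setNames(runif(length(genes), 22, 30), genes)
    rows <- tidyr::expand_grid(gene_id = genes, sample_id = samples,
                               replicate = seq_len(n_replicates))
    rows$ct <- base_ct[rows$gene_id] -
      log2(fc[cbind(rows$gene_id, rows$sample_id)]) +
      rnorm(nrow(rows), 0, noise_sd)
    ref <- tidyr::expand_grid(gene_id = reference_gene, sample_id = samples,
                              replicate = seq_len(n_replicates))
    ref$ct <- 20
    truth <- tibble(
      gene_id = rep(genes, times = length(samples)),
      sample_id = rep(samples, each = length(genes)),
      fold_change = as.vector(fc)
    )
    list(ct = dplyr::bind_rows(ref, rows), truth = truth,
         reference_gene = reference_gene, calibrator = samples[1])
  })
}

# subgroup composition of the carnation aquaporin family
STUDY_COMPOSITION <- c(
  PIP1 = 3, PIP2 = 6, TIP1 = 4, TIP2 = 2, TIP3 = 3, TIP4 = 1, TIP5 = 1,
  NIP4 = 1, NIP5 = 2, NIP6 = 3, SIP1 = 1, SIP2 = 2, XIP1 = 1
)

#' Simulate a study-scale aquaporin proteome
#'
#' Generates a synthetic proteome whose subgroup composition matches the
#' carnation aquaporin family (30 proteins: 9 PIP, 11 TIP, 6 NIP, 3 SIP,
#' 1 XIP), optionally with near-identical allele-ORF partners for the first
#' `n_allele_pairs` members (about 2% of positions mutated outside planted
#' anchors, emulating allelic copies).
#'
#' @param seed Integer seed.
#' @param composition Named integer vector: members per subgroup.
#' @param n_allele_pairs Allele partners to append.
#' @return List: `proteins` (tibble), `truth` (tibble of planted
#'   annotations), `allele_truth` (tibble `id_a`, `id_b`).
#' @export
simulate_proteome <- function(seed, composition = STUDY_COMPOSITION,
                              n_allele_pairs = 0) {
  specs <- tibble(
    subgroup = rep(names(composition), composition),
    member = unlist(lapply(composition, seq_len), use.names = FALSE)
  )
  out <- purrr::map(seq_len(nrow(specs)), function(i) {
    make_protein(specs$subgroup[i], seed = seed * 100L + i,
                 id = sprintf("syn%05d.1", seed * 100L + i))
  })
  proteins <- purrr::map_dfr(out, "protein")
  truth <- purrr::map_dfr(out, "truth")
  allele_truth <- tibble(id_a = character(), id_b = character())
  if (n_allele_pairs > 0) {
    stopifnot(n_allele_pairs <= nrow(proteins))
    pick <- seq_len(n_allele_pairs)
    alleles <- purrr::map_dfr(pick, function(i) {
      with_seed(seed * 1000L + i, {
        chars <- strsplit(proteins$sequence[i], "")[[1]]
        protected <- unique(c(
          seq(truth$lb_start[i] - 5, truth$lb_start[i] + 4),
          seq(truth$le_start[i] - 4, truth$le_start[i] + 6),
          truth$arr_pos[[i]], truth$froger_pos[[i]]
        ))
        mutable <- setdiff(seq_along(chars), protected)
        n_mut <- max(1L, round(0.02 * length(chars)))
        for (p in sample(mutable, n_mut)) {
          pool <- if (chars[p] %in% HYDRO_ALPHA) HYDRO_ALPHA else setdiff(POLAR_ALPHA, chars[p])
          chars[p] <- sample(setdiff(pool, chars[p]), 1)
        }
        tibble(id = paste0(proteins$id[i], "_allele"),
               description = paste("allelic ORF of", proteins$id[i]),
               sequence = paste(chars, collapse = ""))
      })
    })
    allele_truth <- tibble(id_a = proteins$id[pick], id_b = alleles$id)
    proteins <- dplyr::bind_rows(proteins, alleles)
  }
  list(proteins = proteins, truth = truth, allele_truth = allele_truth)
}
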