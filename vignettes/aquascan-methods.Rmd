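---
title: "Methods: genome-wide aquaporin characterization with aquascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide aquaporin characterization with aquascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquascan)
```

# Scope and model

aquascan implements the analysis chain used in genome-wide characterizations
of plant aquaporin (AQP / major intrinsic protein, MIP) families, with the
carnation (*Dianthus caryophyllus*) family — 30 members in five subfamilies
(9 PIP, 11 TIP, 6 NIP, 3 SIP, 1 XIP) — as its running system. The chain is:

1. **Screening** — a candidate protein must look like a complete MIP: length
   200–400 residues, at least two NPA-like boxes, and at least five predicted
   transmembrane (TM) segments. A precomputed domain table (e.g. an HMM
   search against the MIP profile) can override the length/TM heuristic.
2. **Residue signature** — the two NPA boxes (loop B and loop E, with
   degenerate variants NPS/NPT/NPL/NPV/NLA), the ar/R selectivity filter
   (helix-2, helix-5, and two loop-E positions), the five Froger positions,
   and the inter-NPA spacing.
3. **Classification** — nearest-reference assignment by global-alignment
   identity against an annotated per-subgroup panel, systematic
   `<prefix><subgroup>;<k>` naming, and a subfamily census.
4. **Substrate prediction** — a literature-derived rule lookup from
   (subgroup, ar/R tetrad, Froger pentad, NPA box windows) to substrate sets
   under two published schemes, plus the independent NIP-III silicon rule
   (GSGR filter and 108-residue inter-NPA spacing).
5. **Selection pressure** — pairwise Ka/Ks by Nei–Gojobori (1986) counting
   with Jukes–Cantor correction on codon alignments obtained by
   back-translating protein alignments.
6. **Expression** — FPKM from counts, log2(FPKM+1), qPCR relative
   quantification by 2^−ΔΔCt, and hierarchical grouping of genes into
   k = 3 expression groups.
7. **Co-expression** — Pearson correlations across samples, edges kept when
   the correlation falls in the lower/upper 5% percentile tails *and*
   |r| ≥ 0.75, then connectivity ranking.

Every stage consumes and produces tibbles, so the pipeline composes with the
usual tidyverse verbs; network, Ka/Ks and grouping results carry
`tidy()`/`glance()` and `autoplot()` methods.

# The synthetic-data generator

Real genome-scale inputs (a proteome, RNA-seq FPKM tables, qPCR plates)
cannot be bundled, so every input class has a seeded generator that plants
ground truth, and the tests are plant-and-recover experiments.

**Proteins** (`make_protein()`, `simulate_proteome()`). Each of the 13
subgroup templates carries the curated loop-B box (10-mer, motif at offset
6), loop-E box (11-mer, motif at offset 5), ar/R tetrad and Froger pentad of
its carnation exemplar. A generated protein is: polar N-terminus, six
hydrophobic helices (18–19 residues over L/I/V/F/A/M), the LB box in the
loop after helix 2, the LE box placed so the NPA start-to-start distance
equals the template's spacing (PIP 115, TIP/NIP 108, SIP 106, XIP 110;
start-to-start is the convention under which the silicon-transporter spacing
is 108), and the ar/R + Froger residues at template-anchored positions. TM
cores are fixed per subgroup — within-subgroup conservation is what
alignment anchoring and nearest-reference classification rely on — while
the seed varies loop/terminus content and lengths. Loop ends are capped
with strongly hydrophilic residues (D/E/K/R) and internal loops are at
least 16 residues, chosen so the Kyte–Doolittle scanner at its defaults
(window 19, threshold 1.6) finds exactly the six planted helices; the loop
alphabet excludes asparagine so no spurious NPA-like boxes arise. The
reference panel is the set of 13 template instances at fixed internal
seeds, shipped with residue-level annotations; it is synthetic, standing in
for the curated cross-species exemplar panels used in published family
classifications. `simulate_proteome()` emits a 30-protein set with the
carnation subgroup composition, optionally with allele-ORF partners (2% of
non-anchor positions mutated, keeping identity ≳ 0.97).

**CDS pairs** (`make_cds_pair()`). A random stop-free ancestral CDS is
mutated one substitution per chosen codon: synonymous changes sized so
NG86's Ks approaches the target, nonsynonymous so Ka approaches
ω × Ks. Because mutated codons differ at exactly one site, NG86 counting
recovers the planted difference counts exactly, which is what the generator
tests assert.

**Expression matrices** (`make_expression()`). Module genes share a latent
per-sample profile on the log2 scale (amplitude 2, latent uniform on
±1.5, gene baselines 4.5–5.5) plus Gaussian noise; negative pairs
anti-share a latent. Values are emitted as FPKM = 2^x − 1 (range ~0–400),
so `log2(FPKM + 1)` returns the latent-space values exactly: at zero noise
within-module correlations are exactly +1 and negative pairs exactly −1.
What the generator does *not* emulate: count overdispersion, library-size
artifacts, shared housekeeping trends, or heavy-tailed expression — passing
recovery tests show the thresholding logic is correct, not that real
RNA-seq would yield these precisions.

**Ct tables** (`make_ct_table()`). The reference gene sits at a constant
Ct; each target's Ct shifts by −log2(fold change) against the calibrator
(first sample), plus replicate noise of SD 0.05 cycles — the
technical-replicate precision scale of SYBR assays after averaging three
replicates. At that scale the 15% fold-change recovery tolerance used in
the tests corresponds to ≈3.5σ.

# Numerical and design choices

- **Alignment**: Needleman–Wunsch with affine gaps in C++ (BLOSUM62, gap
  open −10, extend −0.5 — Clustal-like defaults, since published family
  studies rarely state parameters). Ties break deterministically:
  match/mismatch over gap-in-a over gap-in-b. Identity = matching columns /
  all alignment columns. An exhaustive alignment-path enumerator serves as
  the oracle on short strings.
- **Trees**: descriptive only. Classification is decided by
  nearest-reference identity (floor 0.35; calls with the top two references
  in different subgroups within 0.02 identity are flagged ambiguous), and
  the neighbor-joining tree on p-distances (gap columns dropped) is emitted
  for inspection. Maximum-likelihood trees with bootstrap support are out
  of scope.
- **NPA scanning**: degenerate pattern `N-[P,L]-[A,S,T,L,V]`, from the
  variant inventory observed in the family. With more than two hits, the
  pair closest to 108-residue spacing with the best window match to the
  template boxes wins. Signature anchors are mapped through the pairwise
  alignment to the single best reference (star alignment) rather than a
  full MSA: simpler, deterministic, and sufficient given subgroup-level
  conservation. Anchors landing on gaps are reported as `-` and reduce the
  anchor confidence.
- **Substrate rules are data**: the packaged table deduplicates the 30
  published carnation rows into 20 keyed rules. The tetrad+pentad key alone
  is not injective in that table (signature-identical proteins differ in
  predictions by subgroup or by one NPA box window), so rules key on
  subgroup + tetrad + pentad with optional exact box fields;
  most-specific-match wins. Blank published cells are reproduced as empty
  predictions, never imputed as "water only". The silicon call is appended
  independently of the rules. Spacing tolerance for the silicon rule is ±2
  residues by default, with the strict ==108 call reported alongside.
- **Ka/Ks**: classic NG86 — per-position synonymous-fraction site counts
  (changes to stop codons count as nonsynonymous so N + S = 3 per codon),
  equal-weight averaging over minimal mutational pathways that avoid stop
  intermediates, Jukes–Cantor correction, Ks reported as undefined when
  pS ≥ 0.75 (saturation). This replaces ML codon models deliberately: the
  biological claim tested (purifying selection, ω < 1) is a sign claim
  robust to estimator choice, and NG86 is fully specifiable and
  oracle-checkable by pathway enumeration.
- **ProtParam conventions**: average isotopic residue masses + one water
  (kDa, 4 decimals); pI by bisection to 1e-4 on the Bjellqvist pKa set with
  residue-specific N-terminal pKa (2 decimals). X has no defined mass and
  is an error for these two operations.
- **TM prediction** is a transparent hydropathy scanner, not a trained
  topology model: runs of above-threshold window starts expand to segments
  spanning first-window-start to last-window-end (a centered-window reading
  would make the 18-residue minimum unreachable under a 19-window), then
  short segments are dropped and segments closer than 5 residues merged.
  Counts from trained HMM predictors on real proteins (5–7 for this family)
  should be treated as a plausibility band, not an equality target.
- **Percentile thresholds**: computed on the off-diagonal correlation
  distribution of the input gene set (the faithful single-set reduction of
  bait-vs-comparison percentile ranks), applied conjunctively with
  |r| ≥ 0.75. Ranks 0/100 disable the respective tail cut, so (0, 100,
  0.75) reduces to the pure absolute-correlation rule.
- **Expression grouping**: Euclidean distance on gene rows, average
  linkage, cut at k = 3 (the published heat-map structure); relative
  (2^−ΔΔCt) values are log2-transformed first; labels are ordered by
  descending cluster mean so group 1 is always the high-expression group.
  The linkage/metric choice is recorded because heat-map tools rarely state
  theirs.

# What the recovery experiments measure

The standard co-expression fixture is 30 genes × 11 samples (the study's
RNA-seq sample count), two 5-gene modules, four negative pairs (matching
the four published negative correlations), noise SD 0.3, seeds 1–10.
Module-edge precision and recall are computed on the positive edge set:
the upper-percentile rule retains at most ⌈0.05 × 435⌉ = 22 positive edges
against 20 planted ones, so precision is ≥ 20/22 by construction whenever
recall holds, and the test asserts ≥ 0.9 for both, per seed. Negative-pair
recovery is asserted separately as recall. Precision over the negative tail
is *not* asserted: with 11 samples the null Pearson tail at |r| ≥ 0.75
admits a couple of background pairs per fixture no matter the generator,
which is a property of the sample size, not a defect of the thresholds.

Selection verdicts are asserted at planted ω = 0.2 (all negative, 10
seeds, 300 codons) and ω = 3 (positive); monotonicity of the estimate is
checked across ω ∈ {0.1, 0.5, 1, 2} at 500 codons. Problem sizes
throughout (30 proteins, 300–500 codons, 30 × 11 expression, 10 seeds)
were chosen as the smallest scales at which the planted effects are
unambiguous.

# Known limitations

- The reference panel is synthetic; applying the classifier to real
  proteomes requires swapping in a curated panel (FASTA + annotation table)
  of the comparator species.
- Identity-based subgroup assignment can disagree with tree-topology
  assignment near subgroup boundaries; the `ambiguous` flag marks those
  calls.
- The hydropathy TM scanner will not reproduce trained-model topology
  calls on real sequences.
- HMMER/BLAST searching, read mapping, ML phylogenetics and codeml-style
  model fits are out of scope by design; the package starts from parsed
  sequences and count/Ct tables.
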