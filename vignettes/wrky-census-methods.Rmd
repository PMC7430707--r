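---
title: "Methods: the WRKY family census pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the WRKY family census pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkycensus)
```

This vignette documents the models and procedures behind `wrkycensus`,
the parameters that matter, the design decisions taken where the
published census workflows leave details open, and what the synthetic
validation does and does not show about real data.

## The inclusion criterion: a complete WRKY domain

A candidate protein joins the family if it carries at least one complete
WRKY domain: a heptapeptide signature paired with a downstream zinc
finger.

**Heptapeptide rule.** A 7-mer is admitted when its first three residues
are exactly `WRK` and its Hamming distance to the canonical `WRKYGQK` is
at most `max_mismatch` (default 2, range 0–2), plus a relaxed exact-`WR`
rule that admits the rare `WRKSGQR` variant. This is the tightest formal
rule covering every heptapeptide observed across published plant WRKY
censuses (`WRKYGQK`, `WRKYGEK`, `WRKYGKK`, `WRKYGSK`, `WRKSGQR`); named
variants are reported literally, any other admissible 7-mer as `other`.
`X` residues never satisfy a constrained position.

**Zinc finger rule.** Published group-specific finger layouts differ only
in their spacers — `C-X(3..4)-C-X(22..23)-H-X-H`,
`C-X(4..5)-C-X(23)-H-X-H`, `C-X(7)-C-X(23)-H-X-C` — so the scanner
matches their union, `C-X(3..7)-C-X(22..23)-H-X-[H|C]`, and lets the
terminal residue set the type (H → C2H2, C → C2HC). Using one
generalized pattern avoids prejudging group membership at detection
time. Overlapping candidates resolve leftmost-first with smallest
spacers, and scanning resumes after each accepted match.

**Pairing.** Each heptapeptide is paired with the nearest downstream
unused finger whose first cysteine lies within `linker_max` residues of
the heptapeptide's end. `linker_max` defaults to 50, consistent with the
~60-residue span of the full domain; the value is a package decision, as
census papers do not state how far the finger may trail, and it is
configurable. Unpaired heptapeptides or fingers are not domains.

## Physicochemical prediction

Molecular weight is the sum of average (isotope-abundance weighted)
residue masses plus one water, reported in kDa; `X` contributes a
configurable mass (0 by default). The isoelectric point is the root of
the Henderson–Hasselbalch net-charge function over the termini and the
D/E/C/Y/H/K/R side chains, found by bisection on pH 0–14 to a charge
tolerance of 1e-4. The side-chain pKa values are the Bjellqvist-style
set used by the common proteomics calculators (D 4.05, E 4.45, C 9.0,
Y 10.0, H 5.98, K 10.0, R 12.0); terminal pKa defaults are 9.094/2.869.
The charge function is strictly decreasing in pH, so the root is unique
and bisection always converges.

## Alignment machinery

All aligners share a single affine-gap Gotoh kernel (compiled C++) that
operates on a precomputed column-score matrix, so sequence–sequence and
profile–profile alignment use identical gap bookkeeping. Gap costs
follow the EMBOSS convention (first gap residue `gap_open`, later
residues `gap_extend`; defaults 10/0.5 with BLOSUM62), and traceback
ties break deterministically diagonal > up > left.

The progressive MSA builds a guide tree from 3-mer count distances
clustered by UPGMA and merges profiles leaves-inward; a profile column
is a residue-frequency vector (gaps excluded, normalized by row count),
and the column–column score is the frequency-weighted BLOSUM62 dot
product. Gaps, once introduced, are never removed. This is a standard
progressive aligner, not a reimplementation of any specific external
tool; the pipeline also accepts an externally computed gapped FASTA via
`as_msa()`, so any MSA program can be substituted.

Local similarity for tandem-duplication calls uses the Smith–Waterman
kernel and reports the EMBOSS "Similarity" convention: positively
scoring aligned pairs over total alignment columns, ×100.

## Distances, trees, supports

Distances are p-distances under pairwise deletion: for each pair of
rows, columns where either row is gapped are dropped and the distance is
the mismatch fraction over the remaining sites. A pair with zero
comparable sites is an error rather than a silent zero. Trees come from
an in-house Saitou–Nei neighbor joining: the standard Q criterion, ties
broken by the first minimal pair in row-major order, negative branch
lengths clamped to zero with the deficit moved to the sister branch so
the pair still sums to the joined distance. On additive matrices the
implementation recovers the generating tree's topology and path lengths
to 1e-9 (verified against an independent implementation in the test
suite). Bootstrap supports resample alignment columns with replacement;
replicate `r` draws from an RNG stream seeded `seed + r`, making runs
reproducible and taxon-order independent; the support of each internal
bipartition of the full-data tree is the percentage of replicate trees
containing it. Published censuses typically use 1,000 replicates; the
package's tests and acceptance runs use 10–200, which is ample to
separate strong from weak edges in families of this size, and the count
is a single parameter.

## Classification and reconciliation

Domain architecture gives a provisional group (two C2H2 → I; one C2H2 →
II; one C2HC → III; two domains with a C2HC finger → an intermediate
flagged as III-leaning). Tree evidence is the majority label of the
`k = 3` nearest labelled reference leaves by patristic distance, ties
broken by total path length then lexicographically. `k = 3` is local
enough to respect subgroup clades yet robust to a single misplaced
reference; published censuses read clades by eye and state no rule.

Reconciliation: if the top-level groups agree, the tree's subgroup wins
(architecture cannot see subgroups). If they disagree but the
neighbourhood is unanimous, the tree wins — this is what places
single-domain proteins whose relatives are all group I, and two-domain
C2HC proteins with group III. If the query's finger type contradicts
the expected finger type of every neighbour, or the neighbourhood is
mixed, the gene is NG (no group) and the decision trace records why.
This reconstruction reproduces the published pattern of exceptions
(tree-overridden members and NG genes) without per-gene special-casing,
but it *is* a reconstruction: the NG rule is the package's own.

## Genome context

Genes are named by physical position: natural chromosome order (numeric
suffix, so Chr2 < Chr10) then ascending start coordinate. Tandem
duplications require the same chromosome, a span gap (0 for overlapping
loci) of at most 100 kbp, and at least 70% local-alignment similarity,
computed on proteins by default — the conservative choice for paralog
similarity, configurable to nucleotide. Gene clusters chain consecutive
genes whose start-to-start distance stays within the window (default
100 kbp); published figures mark clusters visually without a formula, so
the chaining rule is an explicit stand-in and cluster counts should not
be over-interpreted.

## Exon–intron inference

Structures come from exact-match chaining of the CDS against the
genomic sequence: the longest common prefix anchors the first exon; at
each divergence point the next exon resumes at an exact downstream match
of the remaining CDS, probing with the longest CDS prefix (ceiling
12 bp) that still occurs downstream so that exons shorter than the probe
ceiling are still found. Among candidate splits the solver prefers
introns with canonical `GT..AG` termini, then longer exons, then the
leftmost resumption point, and backtracks if a choice cannot complete.
The recovered exons must concatenate exactly to the CDS, or the call
errors with the offset of first failure. Degenerate inputs
(genomic = CDS) yield a single exon and zero introns.

## Promoter scanning

Promoters are fixed-length upstream slices (default 1,500 bp): for plus
-strand genes the bases ending immediately before the start, for minus
-strand genes the reverse complement of the bases after the end,
truncated with a warning at chromosome edges. The element library is a
plain editable table of IUPAC cores for the commonly screened elements
(W-box `TGACY`, ABRE `ACGTG`, G-box `CACGTG`, MBS, LTR, ARE, TGACG/CGTCA
motifs, CAAT/TATA cores, …). Web scanners keep their matrix definitions
internal, so hits from this library are format-compatible with, but not
numerically identical to, any particular online tool — which is why
database-dependent counts (such as how many genes carry a W-box) are
reported as context, never validated against published numbers. Every
match on either strand is reported, overlaps included, ordered by
position, element, strand.

## Expression quantification

`delta_delta_ct()` implements the classical relative-quantification
model at 100% amplification efficiency: per replicate,
ΔCt = Ct_target − Ct_reference; ΔΔCt subtracts the gene's mean
calibrator ΔCt; fold = 2^−ΔΔCt. Replicates are aggregated as the mean
of per-replicate folds with a standard error (`mean_of_folds`,
matching common practice); exponentiating the mean ΔΔCt instead is a
config switch (`fold_of_means`), under which the calibrator column is
identically 1 even for noisy input. The transformation is exactly
invertible, which the tests exploit by generating noise-free Ct tables
from known folds. Published per-gene fold curves cannot be validated
without the underlying raw Ct values, so expression validation is
synthetic-recovery only. Expression matrices cluster with average
linkage under correlation distance (1 − Pearson), with a Euclidean
fallback for zero-variance genes.

## The synthetic family generator

`generate_family()` emulates the statistical structure a census assumes,
with every default mirroring the published sorghum family composition:
group counts 11 (I), 4/8/20/6/12 (IIa–IIe), 31 (III) out of 92 grouped
genes; heptapeptide variants in 13/94 of proteins split 6:5:1:1 over
WRKYGEK/WRKYGKK/WRKYGSK/WRKSGQR; intron counts drawn from the observed
4/10/58/8/8/5/0/1 histogram over 0–7; two tandem pairs inside 100-kbp
windows; 1,500-bp promoters; Ct tables for five genes over a 0–24 h
design with three replicates.

Choices the generator makes where no published value exists, fixed once
and documented here:

* **Ancestors** are built from the pattern layouts plus random filler
  (filler alphabet excludes C and W so no spurious motif can arise from
  background), one ancestor per subgroup, so subgroups are separable by
  construction rather than by resembling any real reference set.
* **Divergence** defaults to 0.15 substitutions per non-critical site
  from the subgroup ancestor. This keeps independent paralogs at ~75%
  pairwise identity — realistic for within-subgroup family members and,
  importantly, consistent with the census's own premise that the family
  is non-redundant at the 0.95 dedup threshold. Pattern-critical
  residues (the heptapeptide and the coordinating C/C/H/[H|C]) are held
  fixed unless a variant is drawn.
* **Tandem pairs** diverge at 0.10 within the pair: more similar than
  random paralogs, below the redundancy threshold, comfortably above
  the 70% tandem similarity criterion.
* **Introns** are `GT` + 46–146 random bases + `AG`, inserted at cut
  points that keep every exon at least 20 bp. Ultra-short exons would
  make exact structure recovery ill-posed (two canonical splicings can
  yield the same CDS) and are rare in plant genomes.
* **Reverse translation** draws synonymous codons uniformly; no codon
  -usage bias is modelled.
* **Placement** spaces non-tandem neighbours ≥150 kbp apart so the only
  within-window pairs are the planted tandems.
* **Expression** folds are log2-uniform in ±3; Ct tables are noise-free
  by default (`ct_noise_sd` adds replicate noise).

All randomness flows from the single mandatory seed; identical
configurations produce byte-identical output files.

**What synthetic validation does not show.** The generator draws
substitutions uniformly at non-critical sites, includes no indels
(alignments of generated families are ungapped by construction), no
codon-usage or GC structure, no UTRs, and subgroup ancestors far more
separated than real subgroups are. Passing tests therefore demonstrate
that the machinery is correct — patterns are matched as specified,
structures invert splicing exactly, trees recover additive signal,
folds invert the Ct model — not that classification accuracy on real,
historically entangled families will reach the synthetic rates. On real
data the reference panel quality and alignment quality dominate.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run families of 12–94 genes
with 21 labelled references, bootstrap counts of 10–200, exhaustive
alignment oracles to length 3 with seeded samples to length 6, and a
1,000-gene structure-inversion batch; these sizes exercise every code
path at full fidelity while keeping a complete run in the low minutes on
one core. Bisection tolerance for pI is 1e-4 on charge; NJ branch
lengths are serialized at 15 significant digits so round-trips preserve
additivity to 1e-9; all coordinates are 1-based inclusive end to end,
with conversions only inside format writers.

## Known limitations

* Group II subgroup calls require a labelled reference panel; without
  one the pipeline reports top-level groups only.
* The NG rule is a reconstruction of practice, not a published
  algorithm; genuinely ambiguous genes depend on `k` and panel quality.
* Promoter hits depend on the shipped IUPAC cores; counts are not
  comparable to matrix-based scanners.
* CD-HIT's word heuristics are not reproduced: redundancy removal uses
  exact global-alignment identity, which is slower but deterministic.
* Structure inference assumes the genomic sequence begins at the CDS
  start (no 5' UTR) and tolerates trailing 3' sequence.
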