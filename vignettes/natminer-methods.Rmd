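---
title: "Methods: mining and annotating microbial NAT genes with natminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and annotating microbial NAT genes with natminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natminer)
```

## The problem

Arylamine *N*-acetyltransferases (NATs, E.C. 2.3.1.5) acylate aromatic
amines using acyl-CoA donors, via a cysteine–histidine–aspartate
protease-like catalytic triad. Beyond xenobiotic detoxification, NAT
homologues act in microbial secondary metabolism — most famously as the
amide synthase that closes the macrolactam ring of ansamycin antibiotics
such as rifamycin, encoded at the end of the core biosynthetic gene
cluster (BGC). Surveying genomes for *NAT* genes therefore involves a
chain of desk tasks: translated homology search, reconstruction of open
reading frames (including frameshifted pseudogenes), motif- and
triad-based family verification, nomenclature assignment, BGC context
analysis, similarity networks and phylogenies, plasmid screening, and
genomic-island detection.

`natminer` implements that chain as a tested, reusable pipeline. Because
the real survey substrate (hundreds of thousands of genome records and
several external services) is not reproducible on a desk, the package
pairs every analysis stage with a seeded synthetic-genome generator whose
implant manifests are exact ground truth, so each stage's claims are
measurable.

## Homology search

`translated_genome_search()` replaces a tBLASTn run: the query protein is
aligned locally (affine gaps) against all six reading frames of every
contig; within a frame, successive loci are found by masking the aligned
span and re-aligning. The alignment itself is the exact Gotoh dynamic
programme (`Biostrings::pairwiseAlignment`) under BLOSUM62 with gap open
11 and extension 1 — the protein-BLAST defaults (`default_scoring()`).
The test suite cross-checks scores against an independently written
recursive Gotoh oracle on hundreds of seeded pairs. Alignment
tie-breaking among co-optimal tracebacks follows the alignment library's
deterministic rule; scores, identities and coverages are unaffected.

E-values use the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with
fixed constants $K = 0.041$, $\lambda = 0.267$ (gapped BLOSUM62). They
are deliberately not re-estimated per search: all thresholding here (the
default `max_evalue = 1e-6`, and the similarity-network threshold below)
only needs a fixed, monotone score-to-E mapping, and fixed constants keep
results reproducible across machines. Because an exact aligner has no
X-drop heuristic, a local hit can extend a short distance across a
frameshift at slightly positive score; the reconstruction step accounts
for this (below).

## Locus reconstruction and annotation

`reconstruct_orf()` converts the hits at one genomic locus into a gene
model. Outer hit boundaries are extended in-frame to the nearest upstream
ATG and downstream stop (a contig edge sets a `partial` flag). Hits in
different frames — the signature of a frameshift pseudogene — are joined
at the midpoint of their genomic gap, each side snapped to its own codon
lattice. Where two hits overlap genomically (the aligner overextension
noted above), the overlap is allocated to the hit with higher alignment
identity before the midpoint rule applies; on synthetic frameshift
implants this keeps the reconstructed protein within edit distance 2 of
the lesioned ground truth (the lesion codon itself is unrecoverable).

Annotation rests on the four semi-conserved family motifs `VPFENL`,
`RGGYC`, `THRL` and `VDV`, which house the catalytic triad (Cys in
`RGGYC`, His in `THRL`, Asp in `VDV`). "Semi-conserved" is
operationalised in `scan_motifs()` as: a window hits a motif when its
BLOSUM62 score reaches 60% of the consensus self-score *and* the
catalytic residue matches exactly (Glu is tolerated for the Asp position
and flagged — the known functional triad variant). The 0.6 fraction
admits the consensi and single conservative substitutions while rejecting
random windows; a property test confirms that 300-residue random proteins
never pass the three-motif screen. Motif hits must appear in canonical
order; the best ordered, non-overlapping combination is selected by
dynamic programming.

`classify_and_name()` labels each locus `intact`, `frameshifted_pseudogene`
(more than one segment), `truncated` (partial flag), or `non_nat` (fewer
than three motifs, absent triad, or best-reference identity < 25% /
coverage < 75%). Callable loci are numbered `NAT1, NAT2, …` per species
in descending best-reference identity, ties broken by genomic coordinate.
The exact identity bands of the gene-nomenclature committee are not
public; the thresholds are therefore configuration with these defaults.

## BGC context

`extract_window()` applies the survey's flank rule — 500 kb per side for
prokaryotes, 1 Mb for eukaryotes — clipped at contig ends, and removes
any feature crossing a window edge, because cluster predictors refuse
inputs that begin or end with a partial ORF. `assign_membership()`
implements the membership rule verbatim: a locus in the overlapping
region of several protoclusters belongs to all of them; the overlap
minimum is one base, since the rule is stated without a minimum.
Protocluster predictions themselves are consumed as feature tables
(antiSMASH-style GenBank/GFF3 or generator output); cluster detection is
out of scope by design.

`map_synteny()` replaces a MultiGeneBlast comparison with gene-level
bidirectional best hits; two clusters are 100%-conserved only under a
BBH bijection covering all genes of both, in identical or fully reversed
order, with every link at 100% identity (identity measured over the
aligned span, as cluster-comparison tools report it). Conservation groups
are the transitive closure, represented by the lexicographically smallest
cluster id.

## Networks and trees

`build_ssn()` computes all-vs-all alignments and connects two proteins
when $-\log_{10} E \ge 29$ — the published alignment-score threshold
(E-value $10^{-29}$). With this package's fixed E-value constants the
absolute edge set differs from web SSN services; only the threshold
semantics are reproduced, and monotonicity (raising the threshold never
adds edges) is asserted in tests.

`distance_matrix()` builds a center-star multiple alignment (center = the
sequence maximising summed pairwise global scores; columns merged by
center coordinates, "once a gap, always a gap") and reports p-distances —
the protein NJ default of the common tree tools. A progressive aligner
would be better on real, indel-rich families; the center-star scheme is
fully specified, dependency-free and exact on the generator's gap-free
families, which is what the recovery tests need. `nj_tree()` performs
Saitou–Nei agglomeration (via `ape::nj`), clamping negative branch-length
estimates to zero with a flag; on additive matrices the tree reproduces
all pairwise distances to 1e-9. `bootstrap_nj()` resamples alignment
columns, rebuilds NJ per replicate, and supports each original internal
split by its replicate frequency. Input order is canonicalised (sorted
ids) before resampling so supports are invariant to row permutation;
ties in the NJ criterion are otherwise order-sensitive. The conventional
replicate number is 1000; tests use 50–100 to keep runtimes in seconds.

## Plasmids and genomic islands

`plasmid_screen()` relaxes the identity threshold to 40% — the setting
reported to retrieve the maximum number of non-redundant translated hits
from plasmid databases — and reports per-plasmid counts, since plasmids
often carry several *NAT* genes. The high-scoring-pair threshold is
implemented as percent identity (configurable), the most direct reading.

`detect_gc_islands()` is an explicit compositional proxy for
island-prediction services (which are external): sliding-window GC
(window 1000 bp, step 500 bp — resolving islands of a few kb and larger;
both unstated in the source methods and chosen here once), flagging
windows at least 2 standard deviations from the replicon mean, and
merging adjacent flagged windows of like direction. The z = 2 default
favours sensitivity; at that level a ~200-window replicon will flag a few
background windows, so island calls should be read jointly with their
`z` and `mean_gc` columns (the recovery claim is about overlap of implanted
islands, not call precision). Codon-usage and mobility-gene evidence used
by dedicated island predictors are out of scope.

## The synthetic-data generator

`generate_genome()` draws i.i.d. bases at a requested GC fraction — a
deliberately featureless background: no genes, no codon bias, no repeats.
`implant_locus()` back-translates a protein (standard/bacterial codon
table, uniform synonymous choice — the least-assumption default, as the
source methods are silent on codon usage) and overwrites a window of the
genome, so implanting never moves other coordinates; frameshift lesions
(single indel, matching the described pseudogenes) and end truncations
(20–40% clipped, placed at a contig edge so partiality is recoverable)
are absorbed inside the window padding. `implant_cluster()` builds
BGC-like neighborhoods with a spanning protocluster feature;
`implant_gc_island()` resamples an interval at a different GC;
`evolve_family()` evolves a protein family along a star or guide tree
under a Jukes–Cantor-style substitution model.

The bundled synthetic reference protein (`nat_reference_protein()`)
carries the four motifs in the N-terminal half (catalytic C at 64, H at
101, D at 122 of 280 residues), as natural NATs do; the frameshift lesion
band sits downstream (55–85% of the ORF) so that lesions never destroy
the motif block — frameshifted and 3'-truncated implants remain
motif-recognisable, as the annotated natural pseudogenes are. All
randomness derives from one user seed split per stage and entity by
stable string hashing (32-bit substream seeds, as R's RNG seeding is
32-bit), making results independent of call order.

What the generator does *not* emulate: real gene density and overlapping
ORFs, codon bias, repeats and mobile elements, sequencing error, indel
evolution within families, and fungal introns (generated genes are
intron-less). Passing recovery tests therefore demonstrate correctness of
the pipeline's logic under clean conditions, not performance on real
genomes, where alignment heuristics, gene callers and island predictors
face far harder inputs.

## Standing study conditions

`synthetic_survey_benchmark()` fixes the package's recovery claims: 20
replicons of 20 kb carrying 50 implants (intact : frameshift : truncated
= 32 : 12 : 6, alternating strands, spaced beyond the 5 kb locus-grouping
distance), plus 5 replicons of 100 kb with one 10 kb island each
(background GC 0.60, island GC 0.30). At the default thresholds the
pipeline recovers and correctly classifies all implants, makes no false
NAT call on non-implanted sequence, and covers every implanted island;
the acceptance script (`scripts/acceptance.R`) recomputes these rates at
an arbitrary seed, alongside the arithmetic over the bundled survey-table
transcriptions. Problem sizes were chosen so the whole suite runs in
minutes on one CPU.

## Known limitations

* The exact aligner has no heuristic seeding; genome-scale inputs
  (megabase contigs, thousands of queries) are outside the intended
  desk scale.
* Frameshift joins place the boundary at the inter-hit midpoint; the
  boundary codon or two next to the lesion is approximate, bounded by the
  inter-hit gap.
* E-values use fixed constants; absolute values differ from BLAST's
  per-search estimates (relative ordering and thresholds do not).
* Symbol assignment implements a deterministic stand-in for committee
  nomenclature; identity bands are configurable, not authoritative.
* The GC-island detector is compositional only and inherits the usual
  blind spots (ameliorated islands, compositionally typical transfers).
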