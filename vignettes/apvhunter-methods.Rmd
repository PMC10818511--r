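---
title: "Methods: detecting vesicle-transferred haloarchaeal plasmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting vesicle-transferred haloarchaeal plasmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`apvhunter` detects pR1SE-like archaeal plasmids (apHPVs) — elements defined
by a conserved core of two syntenic gene clusters (cluster 1: ORF6–ORF9;
cluster 2: ORF17, ORF21, ORF23–ORF25) separated by a short variable region —
in assembled contigs, and characterizes them: circularity, replication-origin
repeats, a core/shell/cloud pangenome, COG functional shifts and CRISPR
spacer targeting. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic benchmark does and
does not demonstrate.

## Profile model and scoring

Each of the six searched markers (ORF6, ORF8, ORF17, ORF21, ORF23, ORF24)
is modeled as a profile HMM built from a seed alignment.

* **Architecture.** Match, insert and delete states per position, with
  transitions {M→M, M→I, M→D, I→M, I→I, D→M, D→D} plus a begin distribution
  over {M1, D1}. There is no D–I adjacency; insert runs bordered by a delete
  are credited to the delete's direct transition. Alignment columns whose
  gap fraction is ≤ `gap_fraction_max` (default 0.5, boundary inclusive)
  become match states.
* **Estimation.** Emissions and transitions are counts over the seed rows
  plus a Laplace-style pseudocount (default 0.1 per amino acid and per
  transition). The background is estimated from the alignment residues by
  default; a fixed vector or the uniform distribution can be supplied.
  Insert states emit the background, so insertions cost transitions only.
* **Scoring.** Glocal Viterbi: the whole profile must be traversed, the
  alignment is local in the sequence (flanking residues are free on both
  sides — they are emitted identically by the null model). The bitscore is
  the log2-odds of the best path against the background null. There is no
  E-value calibration; retrieval is threshold-based, with a default
  bitscore threshold of 50 and a profile-coverage threshold (aligned match
  states / L) of 0.70. Coverage is measured on the profile, not the
  sequence: it is then well-defined for the glocal mode regardless of
  sequence length. Residues outside the 20-letter alphabet (X) score as
  background (zero log-odds).
* **Tie-breaking.** On equal path scores the traceback prefers match over
  delete over insert, making projections deterministic.
* **Envelope coordinates.** A marker hit is reported with the contig span
  of the residues aligned to match states, not the span of the whole ORF.
  This matters because the bundled ORF caller is a maximal-ORF caller: a
  marker gene preceded by a stop-free stretch can be fused into one long
  ORF, and using ORF bounds would scramble marker order in the synteny
  test.

The iterative refinement loop mirrors profile-based family building: build
a profile, search the database, project new hits onto the match states,
apply trimming rules, rebuild; stop when an iteration adds nothing. The
original procedure removed badly-fitting sequences on visual inspection;
here that curation is replaced by two quantitative rules — a candidate is
blacklisted when its unaligned overhang beyond the profile ends exceeds
`overhang_max × L` (default 0.30) or its inserted residues exceed
`gap_insert_max × L` (default 0.30). The blacklist only grows, and
blacklisted accessions never re-enter.

## ORF calling

A deliberately simple six-frame maximal-ORF caller stands in for a trained
gene finder: start codons ATG/GTG/TTG, stops TAA/TAG/TGA, translation
table 11, minimum protein length 60, reverse-strand calls mapped to forward
coordinates (0-based, half-open everywhere; GFF3 export converts to
1-based inclusive). Ns translate to X and do not split ORFs. Externally
produced gene calls can be supplied as a TSV instead. On high-GC sequence
(stop codons are AT-rich) spurious long ORFs are common; they do not affect
marker detection (they score as background) but they do inflate ORF-index
based quantities — see "variable region" below.

## Element classification and synteny

A contig is **complete** when it carries at least five of the six distinct
markers and is strictly longer than 10,000 bp, **incomplete** with three or
four distinct markers, otherwise negative. Distinctness is over marker
names; when one ORF passes several profiles only the best-scoring marker is
kept (ties alphabetical). Both count thresholds and the length bound are
configurable; the length bound is strict because the source criterion says
"longer than".

Synteny requires, in one consistent reading orientation, every present
cluster-1 marker before every present cluster-2 marker with within-cluster
order conserved; linear contigs are tested in both orientations, circular
contigs over all rotations of both orientations. The variable-region gene
count is the number of ORFs strictly between the last cluster-1 hit and the
first cluster-2 hit. With the naive ORF caller this count is an upper bound
on the number of planted genes (spurious ORFs only add to it); the exact
planted count is recovered when curated gene calls are supplied, which is
how the unit tests pin it.

The core region spans from the first cluster-1 hit to the last cluster-2
hit plus ten flanking genes on each side (truncated at linear contig ends,
wrapped across the origin of circular contigs).

## Repeats, circularity, origins

* **Terminal repeats.** A contig is circular when an exact prefix of more
  than 30 bp equals a suffix (strictly greater; the default `min_len = 31`).
  The longest such repeat is reported.
* **Repeat finder.** All maximal pairs (p1, p2, len) with Hamming distance
  ≤ 1 between the two copies (same orientation, or reverse complement for
  palindromic pairs), len strictly greater than 25, non-overlapping copies,
  and copy separation ≤ 5 kbp (configurable; origin repeats are local
  features). Maximality means no one-base extension on either side keeps
  the distance within budget. Candidate diagonals come from shared exact
  k-mers with k = ⌊(min_len − m) / (m + 1)⌋ (pigeonhole-complete for
  mismatch budget m); each candidate diagonal is scanned once for maximal
  mismatch-bounded windows. Within a tandem run longer than its period,
  every period-length sub-window is a maximal non-overlapping pair; the
  scanner emits them all and de-duplicates. An exhaustive definitional
  oracle (enumerate all windows, test the extension property literally)
  validates the scanner in the test suite; a full-scan mode without seeding
  is also exposed and tested for equality.
* **Origin placement.** A repeat whose midpoint lies within 2,000 bp
  upstream of the cluster-1 start is `before_cluster1`; within 2,000 bp
  downstream of the cluster-2 end, `after_cluster2`. Upstream and
  downstream are taken in the element's reading orientation (majority
  strand of the marker hits), and distances are computed modulo the contig
  length on circular contigs. The window default is a judgment call
  ("directly before / just after" is qualitative) and is exposed.

## Pangenome

Proteins from detected elements are clustered greedily: sort by length
descending (ties by id), join the first cluster whose representative aligns
at ≥ 15% identity, else found a new cluster. Identity is Needleman–Wunsch
global alignment (BLOSUM62, gap open 11, extend 1) with matches divided by
the shorter sequence length — the cd-hit convention.

One consequential choice: a forced global alignment of two *unrelated*
proteins still yields roughly 20% coincidental identity (the classic
twilight-zone inflation from optimizing matches under affine gaps), so a
raw 15% cutoff would merge everything. The BLAST-backed tool this step
mirrors computes identity only over significant local alignments —
unrelated pairs simply produce no alignment. We reproduce that behaviour
with a score gate: identity counts toward the threshold only when the
global alignment score is positive (`min_score = 0`, configurable;
`-Inf` disables the gate). Homologous pairs at ≥ 25% identity score far
above zero; unrelated pairs score strongly negative.

Clusters are labeled by the number of distinct genomes they recruit:
core if strictly more than 90% of genomes, shell above 50%, cloud above
10%. The count thresholds use the smallest integer strictly exceeding the
fraction, `⌊f·n + ε⌋ + 1` with ε = 1e−9 guarding against floating-point
representation (for 41 genomes: 37, 21, 5). The presence/absence matrix
(default: clusters present in more than 10% of genomes, i.e. the pangenome
proper; the label subset is configurable) feeds Jaccard distances — chosen
because the source method does not name its binary metric and Jaccard is
standard for presence/absence profiles; pairs with an empty union get
distance 1. Average linkage (UPGMA) is implemented directly with
unweighted cross-pair means and deterministic tie-breaking on the
lexicographically smallest label pair; `stats::hclust(method = "average")`
serves as the independent reference in the tests. Newick export writes
ultrametric branch lengths (height differences) and quotes labels
containing metacharacters.

Mean pairwise amino-acid identity per cluster uses the same aligner over
all member pairs. Note that the family *mean* pairwise identity is not the
generator's parent–child target: two independent mutants at 50% identity to
a parent sit near 25–35% to each other, so parameter-recovery tests pin
the pair identity, not the family mean.

## Functional comparisons

COG relative abundance counts unique (gene, category) assignments — a gene
with several categories contributes once per category, duplicate
annotations are de-duplicated — normalized by the set total; the difference
profile subtracts the reference set from the element set, so positive
values mean enrichment on the elements. Spacer matching is full-length
ungapped alignment of each spacer at every offset of each target, both
strands, keeping hits strictly above 97% identity and strictly longer than
30 nt; at that identity over 30–50 nt, gapped hits add nothing, and the
sliding-window semantics make the matcher oracle-testable. Plasmid counts
per taxon class are normalized by genome counts, with classes missing from
either input dropped with a warning.

## The synthetic benchmark

`generate_benchmark()` derives every input from one seed (identical
configurations are byte-identical): 20 complete elements, 20 single-cluster
fragments (80% cluster-1, echoing the strong cluster-1 bias among real
incomplete elements), 60 decoys. Element contigs encode flanking genes,
cluster 1, a variable region of 3–11 genes, cluster 2 and more flanks,
back-translated with GC-calibrated codon weights to a target drawn from
57.6–64.8% (the observed GC band); marker proteins are BLOSUM62-biased
substitution mutants of bundled synthetic seed parents at 45–75% identity
(comfortably above the ~18% floor seen across real homologs — detection
down to that floor is not claimed). Origin repeats (30 bp units; direct,
interspersed or palindromic) are planted directly before cluster 1 or just
after cluster 2; half of the element contigs are circularized with 40 bp
terminal repeats; whole contigs are reverse-complemented with probability
0.5. Decoys match length and GC and are rejection-sampled so every ORF
scores at least 10 bits below threshold. The planted pangenome fixes each
cluster's representative and rejection-samples members so their score-gated
identity is ≥ 0.18 to their own representative and < 0.12 to every other —
the separability the clustering threshold of 0.15 requires, by
construction. COG tables draw one category per gene from a base
distribution (reference) and from base plus the planted delta (elements);
multi-category genes are exercised in unit tests rather than the
generator, keeping the delta estimator exactly multinomial.

What passing on this benchmark shows: the implementations are correct
against their contracts and independent oracles, and the pipeline recovers
planted truth under realistic composition, identity and size regimes. What
it does not show: performance on real assemblies — no sequencing error,
no fragmented or chimeric contigs, no mosaic homology, no trained
gene-model subtleties, and marker divergence milder than the worst real
cases. The headline counts of the original survey depend on public
database snapshots and are out of scope here.

Fragments carrying only cluster 1 deserve a note: only two of the six
searched markers (ORF6, ORF8) sit in cluster 1, so under the three-marker
rule these fragments classify as negative, and only cluster-2 fragments
(four markers) can be called incomplete. The original survey reports many
cluster-1 incomplete elements; reproducing that would require profiles for
ORF7/ORF9 (supported via the synteny model and gene-call inputs, but not
part of the searched six).

## Problem sizes and runtime

Defaults keep every stage desk-scale: the benchmark is 100 contigs of
12–20 kbp; profiles have 140–280 match states; the planted pangenome is 41
genomes × 41 clusters (~900 proteins); oracle suites run 110 random
instances each (Viterbi enumeration at L ≤ 4, sequences ≤ 6; repeat oracle
on 120–300 bp sequences; UPGMA on 7 leaves; spacer oracle on 300–600 bp
targets). The full test suite and the acceptance script each run in a few
minutes on one CPU.
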