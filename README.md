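# apvhunter

Detection and characterization of pR1SE-like haloarchaeal plasmids
(apHPVs) — mobile genetic elements that are disseminated between cells in
self-encoded plasmid vesicles — in assembled contigs from genomes or
metagenomes.

These elements are defined by a conserved core region: two syntenic gene
clusters (cluster 1: ORF6–ORF9; cluster 2: ORF17, ORF21, ORF23–ORF25,
numbering after the reference plasmid annotation) separated by a variable
region of a few genes. `apvhunter` implements the full discovery pipeline as
a reusable, tested R package:

* **Profile HMMs of six marker proteins** (ORF6, ORF8, ORF17, ORF21, ORF23,
  ORF24). Profiles are built from seed alignments — match states are
  alignment columns with gap fraction ≤ 0.5, emissions and transitions are
  pseudocount-smoothed counts — and scored against proteins with a glocal
  Viterbi algorithm: the score of a hit is
  `bits = log2 P(x, π* | M) − log2 P(x | null)`,
  the log-odds of the best state path against a background that emits the
  same residues. Hits must clear a bitscore threshold (default 50) and a
  profile-coverage threshold (fraction of match states aligned, default
  0.7). An iterative refinement loop (search → project hits onto the
  profile → automated trimming → rebuild) with an accession blacklist grows
  each marker family until a fixed point.
* **Element classification**: contigs longer than 10,000 bp with ≥ 5 of 6
  distinct markers are *complete* elements, with 3–4 markers *incomplete*,
  otherwise negative; a synteny check requires all cluster-1 markers to
  precede all cluster-2 markers in one consistent orientation (all
  rotations for circular contigs).
* **Circularity and replication origins**: exact terminal repeats longer
  than 30 bp mark circular contigs; direct, interspersed direct and
  palindromic repeats longer than 25 bp with at most one mismatch,
  positioned directly before cluster 1 or just after cluster 2, are
  reported as origin candidates.
* **Pangenome**: greedy incremental protein clustering at 15% identity
  (Needleman–Wunsch, BLOSUM62, gap open 11 / extend 1, identity over the
  shorter sequence, with a positive-score gate standing in for BLAST
  significance), partitioned into core (> 90% of genomes), shell (50–90%)
  and cloud (10–50%); Jaccard distances on the presence/absence matrix feed
  an average-linkage (UPGMA) dendrogram with Newick export.
* **Functional comparison**: per-category COG relative abundance
  `rel(set)_cat = n_cat / n_tot(set)` and the difference profile
  `Δrel_cat = rel(element) − rel(reference)`; CRISPR-spacer matching against
  core regions (> 97% identity, length > 30 nt); plasmid counts normalized
  per genome count by taxon class.
* **A fully seeded synthetic benchmark** that generates every input with
  machine-readable ground truth: contigs with planted core regions (marker
  homologs mutated to 45–75% identity, GC drawn from the 57.6–64.8% band),
  single-cluster fragments, marker-free decoys, terminal and origin
  repeats, spacers, COG tables and a 41-genome pangenome with known
  core/shell/cloud labels.

## Worked example

```r
library(apvhunter)

bench <- generate_benchmark(generator_config(seed = 1))
det   <- detect_elements(bench$contigs, bench$profiles)
table(det$calls_table$status)
#>   complete incomplete   negative
#>         20          4         76
```

The 20 planted complete elements are exactly the 20 complete calls, every
one of them syntenic. (Fragments carrying only cluster 1 hold just two of
the six *searched* markers, so under the three-marker rule they classify as
negative; the four incomplete calls are the cluster-2 fragments.)

```r
subset(det$calls_table, status == "complete")[1:3, 1:5]
#>    contig_id   status n_markers length synteny_ok
#> 1 element_01 complete         6  19505       TRUE
#> 2 element_02 complete         6  16497       TRUE
#> 3 element_03 complete         6  16451       TRUE
```

Circularity and origin candidates (the two rows are the two maximal
mismatch-windows of the same planted repeat):

```r
detect_terminal_repeats(bench$contigs$element_01)$circular
#> [1] TRUE
reps <- find_repeats(bench$contigs$element_01$sequence,
                     min_len = 26, max_mismatch = 1)
locate_putative_ori(reps, det$calls$element_01,
                    contig_length = nchar(bench$contigs$element_01$sequence),
                    circular = TRUE)$placement
#> [1] "before_cluster1" "before_cluster1"
```

Pangenome partition on the planted 41-genome truth set:

```r
cl <- classify_clusters(greedy_cluster(bench$pangenome$proteins, 0.15), 41)
table(cluster_table(cl)$label)
#>             cloud              core             shell singleton_or_rare
#>                20                10                 8                 3
```

which recovers all 41 planted clusters exactly (membership and label). The
COG difference profile recovers the planted enrichment of ±0.10:

```r
ap  <- cog_relative_abundance(bench$cog$table, "apHPV")
ref <- cog_relative_abundance(bench$cog$table, "reference")
head(sort(abs(cog_delta(ap, ref)), decreasing = TRUE), 2)
#>     V     E
#> 0.111 0.106
```

The numbered scripts under `analysis/` run these stages as a narrative
workflow (`01_generate_benchmark.R` … `06_functional_profiles.R`), writing
their tables under `results/`.

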