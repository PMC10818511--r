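Package: apvhunter
Title: Detection and Characterization of Vesicle-Transferred Haloarchaeal Plasmids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering pR1SE-like archaeal plasmids (apHPVs) in
    assembled metagenomic or genomic contigs. Builds position-specific profile
    models of six marker proteins from seed alignments, refines them iteratively
    against a protein database with an accession blacklist, scans contig open
    reading frames for marker homologs, classifies contigs as complete or
    incomplete elements using marker-count, length and synteny rules, decides
    circularity from terminal repeats, locates putative replication origins as
    direct, interspersed or palindromic repeats flanking the conserved core
    region, partitions element proteomes into core, shell and cloud pangenome
    fractions with an average-linkage presence/absence dendrogram, compares COG
    functional profiles between gene sets, and matches CRISPR spacers against
    core regions. Ships a fully seeded synthetic-data generator with machine
    readable ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
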