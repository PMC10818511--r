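#!/usr/bin/env Rscript
# Stage 1: generate the synthetic benchmark with ground truth.
#
# Produces 20 contigs carrying a complete two-cluster core region, 20
# single-cluster fragments, and 60 marker-free decoys, together with the
# bundled seed alignments, spacer sets, COG tables and a planted 41-genome
# pangenome. Everything is derived from one seed; outputs land in results/.

library(apvhunter)

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
bench <- generate_benchmark(cfg)

write_fasta(bench$contigs, file.path(out, "contigs.fasta"))
write.table(bench$truth_contigs, file.path(out, "truth_contigs.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_fasta(bench$spacers, file.path(out, "spacers.fasta"))
write.table(bench$truth_spacers, file.path(out, "truth_spacers.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(bench$cog$table, file.path(out, "cog_annotations.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(bench$pangenome$truth, file.path(out, "truth_pangenome.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
pg_prot <- bench$pangenome$proteins
write_fasta(setNames(pg_prot$seq, pg_prot$protein_id),
            file.path(out, "pangenome_proteins.fasta"))
for (aln in bench$seed_alignments) {
  write_fasta(setNames(aln$rows, aln$ids),
              file.path(out, sprintf("seed_%s.fasta", aln$name)))
}

tt <- bench$truth_contigs
cat(sprintf("generated %d contigs (%d complete, %d fragments, %d decoys)\n",
            nrow(tt), sum(tt$planted_status == "complete"),
            sum(grepl("incomplete", tt$planted_status)),
            sum(tt$planted_status == "negative")))
cat(sprintf("planted circular contigs: %d; planted ORI repeats: %d\n",
            sum(tt$circular), sum(tt$ori_kind != "none")))
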