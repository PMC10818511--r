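#!/usr/bin/env Rscript
# Stage 2: build the six marker profiles from their seed alignments and
# exercise the iterative refinement loop against a protein database that
# contains planted homolog ladders, decoys and a fusion protein.
#
# The refinement loop mirrors the original cluster-building procedure:
# build profile -> search -> project new hits -> apply trimming rules
# (overhang / insertion limits, replacing visual curation) -> rebuild, with
# a blacklist that only grows.

library(apvhunter)

set.seed(2L)
out <- "results"
dir.create(out, showWarnings = FALSE)

seeds <- toy_seed_alignments()
parents <- toy_seed_proteins()

for (mk in names(seeds)) {
  pf <- build_profile(seeds[[mk]])
  write_profile(pf, file.path(out, sprintf("profile_%s.tsv", mk)))
}

# refinement demonstration on one marker: a 70->50->35% identity ladder is
# recruited tier by tier, and a fusion protein is blacklisted
mk <- "ORF17"
h70 <- mutate_protein(parents[[mk]], 0.70)
h50 <- mutate_protein(h70, 0.70)
h35 <- mutate_protein(h50, 0.70)
L <- build_profile(seeds[[mk]])$L
db <- c(setNames(seeds[[mk]]$rows, seeds[[mk]]$ids),
        ladder70 = h70, ladder50 = h50, ladder35 = h35,
        fusion = paste0(mutate_protein(parents[[mk]], 0.7),
                        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                              "")[[1]],
                                     2L * L, TRUE), collapse = "")),
        decoy1 = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              190, TRUE), collapse = ""))
ref <- refine_profile(seeds[[mk]], db, max_iter = 8L)
cat(sprintf("refined %s: %d iterations, members = %s\n", mk, ref$n_iter,
            paste(ref$member_ids, collapse = ", ")))
cat(sprintf("blacklist: %s\n", paste(ref$blacklist, collapse = ", ")))
write_profile(ref$profile, file.path(out, sprintf("profile_%s_refined.tsv",
                                                  mk)))
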