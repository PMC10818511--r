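# helper: fabricate a marker hit table from an ordered marker layout
hits_from_layout <- function(markers, gap_orfs = 0L, start0 = 1000L) {
  n <- length(markers)
  idx <- seq_len(n)
  if (gap_orfs > 0L) idx[markers %in% c("ORF17", "ORF21", "ORF23", "ORF24")] <-
    idx[markers %in% c("ORF17", "ORF21", "ORF23", "ORF24")] + gap_orfs
  starts <- start0 + (idx - 1L) * 1500L
  data.frame(contig_id = "c", marker = markers, orf_index = idx,
             start = starts, end = starts + 900L, strand = "+",
             bitscore = 100, coverage = 0.9, stringsAsFactors = FALSE)
}

test_that("classification applies the marker-count and length thresholds", {
  six <- c("ORF6", "ORF8", "ORF17", "ORF21", "ORF23", "ORF24")
  mk <- function(n) hits_from_layout(six[seq_len(n)])
  ct_long <- contig("c", rand_dna(20000))
  ct_11k <- contig("c", rand_dna(11000))
  ct_9k <- contig("c", rand_dna(9000))
  ct_50k <- contig("c", rand_dna(50000))

  expect_equal(classify_contig(mk(5), ct_long)$status, "complete")
  expect_equal(classify_contig(mk(3), ct_11k)$status, "incomplete")
  expect_equal(classify_contig(mk(6), ct_9k)$status, "negative")
  expect_equal(classify_contig(mk(2), ct_50k)$status, "negative")
  # strict boundary: exactly 10,000 bp is not "longer than 10,000 bp"
  ct_10k <- contig("c", rand_dna(10000))
  expect_equal(classify_contig(mk(6), ct_10k)$status, "negative")
  # distinctness over marker names, not raw hits
  dup <- rbind(mk(2), mk(2))
  dup$orf_index <- seq_len(nrow(dup))
  expect_equal(classify_contig(dup, ct_50k)$n_distinct_markers, 2L)
})

test_that("scan_contig keeps one best marker per ORF and rejects decoys", {
  set.seed(21)
  seeds <- toy_seed_alignments()
  profiles <- lapply(seeds, build_profile)
  parents <- toy_seed_proteins()
  orfs <- data.frame(
    contig_id = "c",
    start = c(0L, 3000L, 6000L), end = c(900L, 3900L, 6900L),
    strand = "+", frame = 0L,
    protein = c(mutate_protein(parents[["ORF21"]], 0.6),
                rand_prot(150), rand_prot(200)),
    orf_index = 1:3, stringsAsFactors = FALSE)
  ht <- scan_contig(orfs, profiles)
  expect_equal(ht$marker, "ORF21")
  expect_equal(ht$orf_index, 1L)

  # decoy-only contig: empty table
  orfs_dec <- orfs; orfs_dec$protein <- vapply(c(150, 160, 170), rand_prot, "")
  expect_equal(nrow(scan_contig(orfs_dec, profiles)), 0L)
})

test_that("synteny honors cluster order, orientation and rotations", {
  m <- synteny_model()
  ok <- hits_from_layout(c("ORF6", "ORF8", "ORF17", "ORF21", "ORF23", "ORF24"))
  expect_true(check_synteny(ok, m)$synteny_ok)

  bad <- hits_from_layout(c("ORF17", "ORF6", "ORF8", "ORF21"))
  expect_false(check_synteny(bad, m)$synteny_ok)

  # reverse orientation of a valid layout is still syntenic
  rev_ok <- hits_from_layout(rev(c("ORF6", "ORF8", "ORF17", "ORF21",
                                   "ORF23", "ORF24")))
  expect_true(check_synteny(rev_ok, m)$synteny_ok)

  # within-cluster order violation
  bad2 <- hits_from_layout(c("ORF8", "ORF6", "ORF17", "ORF21", "ORF23",
                             "ORF24"))
  expect_false(check_synteny(bad2, m)$synteny_ok)

  # circular rotation: cluster 2 before cluster 1 in linear coordinates
  rot <- hits_from_layout(c("ORF23", "ORF24", "ORF6", "ORF8", "ORF17",
                            "ORF21"))
  expect_false(check_synteny(rot, m)$synteny_ok)
  expect_true(check_synteny(rot, m, circular = TRUE)$synteny_ok)
})

test_that("variable-region gene count is the strict inter-cluster ORF count", {
  layout <- c("ORF6", "ORF8", "ORF17", "ORF21", "ORF23", "ORF24")
  ht <- hits_from_layout(layout, gap_orfs = 7L)
  orfs <- data.frame(contig_id = "c", start = seq(0, by = 1500,
                                                  length.out = 13L),
                     end = seq(900, by = 1500, length.out = 13L),
                     strand = "+", frame = 0L, protein = "M",
                     orf_index = 1:13, stringsAsFactors = FALSE)
  syn <- check_synteny(ht, synteny_model(), orfs = orfs)
  expect_true(syn$synteny_ok)
  expect_equal(syn$variable_region_gene_count, 7L)
  expect_gte(syn$variable_region_gene_count, 3L)
  expect_lte(syn$variable_region_gene_count, 11L)
})

test_that("classification is invariant under reverse complement", {
  set.seed(31)
  cfg <- generator_config(seed = 31, circular_fraction = 0)
  seeds <- toy_seed_alignments()
  profiles <- lapply(seeds, build_profile)
  r <- make_element_contig(cfg, "complete", id = "fw")
  rc <- contig("rc", revcomp_h(r$contig$sequence))
  d1 <- detect_elements(list(r$contig), profiles)
  d2 <- detect_elements(list(rc), profiles)
  expect_equal(d1$calls_table$status, d2$calls_table$status)
  expect_equal(d1$calls_table$n_markers, d2$calls_table$n_markers)
  expect_equal(d1$calls_table$synteny_ok, d2$calls_table$synteny_ok)
})

test_that("raising profile thresholds never promotes a call", {
  set.seed(33)
  cfg <- generator_config(seed = 33, circular_fraction = 0)
  seeds <- toy_seed_alignments()
  profiles <- lapply(seeds, build_profile)
  r <- make_element_contig(cfg, "incomplete_cluster1", id = "f1")
  rank <- c(negative = 0L, incomplete = 1L, complete = 2L)
  base <- detect_elements(list(r$contig), profiles)$calls_table$status
  stricter <- lapply(profiles, function(pf) {
    pf$score_threshold <- pf$score_threshold + 100; pf
  })
  harder <- detect_elements(list(r$contig), stricter)$calls_table$status
  expect_lte(rank[[harder]], rank[[base]])
})

test_that("core region extraction respects flanks, truncation and wrap", {
  set.seed(35)
  cfg <- generator_config(seed = 35, circular_fraction = 0)
  seeds <- toy_seed_alignments()
  profiles <- lapply(seeds, build_profile)
  r <- make_element_contig(cfg, "complete", id = "e1")
  det <- detect_elements(list(r$contig), profiles)
  call <- det$calls[[1]]
  orfs <- det$orfs
  core <- extract_core_region(call, r$contig, orfs, flank_genes = 10L)
  expect_equal(nrow(core$flank_upstream), 10L)
  expect_equal(nrow(core$flank_downstream), 10L)
  expect_true(nchar(core$sequence) >=
                call$core_span[2] - call$core_span[1])
  core3 <- extract_core_region(call, r$contig, orfs, flank_genes = 3L)
  expect_equal(nrow(core3$flank_upstream), 3L)
  expect_lt(nchar(core3$sequence), nchar(core$sequence))

  neg <- call; neg$status <- "negative"
  expect_error(extract_core_region(neg, r$contig, orfs), "negative")
})

test_that("a circular contig with the core crossing the origin still works", {
  set.seed(37)
  cfg <- generator_config(seed = 37, circular_fraction = 1)
  seeds <- toy_seed_alignments()
  profiles <- lapply(seeds, build_profile)
  r <- make_element_contig(cfg, "complete", id = "circ")
  s <- r$contig$sequence
  tr <- r$truth$terminal_repeat_len
  n <- nchar(s)
  # re-linearize the circle so the cut lands inside the core region
  body <- substr(s, 1, n - tr)             # one terminal-repeat copy removed
  cut <- floor((r$truth$core_lo + r$truth$core_hi) / 2) %% nchar(body)
  rot <- paste0(substr(body, cut + 1, nchar(body)), substr(body, 1, cut))
  rot <- paste0(rot, substr(rot, 1, tr))   # restore the duplicated end
  ctr <- contig("circ_rot", rot)
  ctr <- detect_terminal_repeats(ctr)$contig
  expect_true(ctr$circular)
  det <- detect_elements(list(ctr), profiles)
  expect_equal(det$calls_table$status, "complete")
  call <- det$calls[[1]]
  core <- extract_core_region(call, ctr, det$orfs)
  expect_true(core$wrapped)
  expect_gt(nchar(core$sequence), 0)
})
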