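test_that("build_profile retains the right columns and normalizes", {
  aln <- seed_alignment("t", "s1", "MKV")
  pf <- build_profile(aln)
  expect_equal(pf$L, 3L)
  expect_true(all(abs(rowSums(pf$match_emissions) - 1) < 1e-9))
  # emissions concentrated on the observed residues
  expect_equal(unname(apply(pf$match_emissions, 1L, function(r)
    names(which.max(r)))), c("M", "K", "V"))

  # boundary inclusion: gap fraction 0.5 <= 0.5 keeps the column
  aln2 <- seed_alignment("t2", c("s1", "s2"), c("MKV", "M-V"))
  pf2 <- build_profile(aln2, gap_fraction_max = 0.5)
  expect_equal(pf2$L, 3L)

  # random alignments: every emission row and transition group sums to 1
  set.seed(11)
  for (r in 1:5) {
    rows <- replicate(3, rand_prot(12))
    rows[2] <- paste0(substr(rows[2], 1, 5), "-", substr(rows[2], 7, 12))
    pfr <- build_profile(seed_alignment("r", paste0("s", 1:3), rows))
    expect_true(all(abs(rowSums(pfr$match_emissions) - 1) < 1e-9))
    tr <- pfr$transitions
    expect_true(all(abs(tr$mm + tr$mi + tr$md - 1) < 1e-9))
    expect_true(all(abs(tr$im + tr$ii - 1) < 1e-9))
    expect_true(all(abs(tr$dm + tr$dd - 1) < 1e-9))
    expect_equal(unname(sum(tr$begin)), 1, tolerance = 1e-9)
  }

  expect_error(build_profile(seed_alignment("g", c("a", "b", "c"),
                                            c("M--", "-K-", "--V")),
                             gap_fraction_max = 0.2),
               "match columns")
})

test_that("viterbi glocal score equals exhaustive path enumeration", {
  set.seed(101)
  n_cases <- 0L
  for (rep in 1:120) {
    L <- sample(2:4, 1L)
    nrow_aln <- sample(2:3, 1L)
    rows <- replicate(nrow_aln, rand_prot(L, alphabet = c("A", "C", "D")))
    if (runif(1) < 0.4 && L >= 3) {
      # introduce a gap to diversify transitions
      i <- sample(nrow_aln, 1L); p <- sample(2:L, 1L)
      substr(rows[i], p, p) <- "-"
    }
    pf <- build_profile(seed_alignment("t", paste0("s", seq_len(nrow_aln)),
                                       rows),
                        gap_fraction_max = 0.6)
    prot <- rand_prot(sample(1:6, 1L), alphabet = c("A", "C", "D", "K"))
    got <- viterbi_score(pf, prot)$bitscore
    want <- viterbi_enumerate(pf, prot)
    expect_equal(got, want, tolerance = 1e-9)
    n_cases <- n_cases + 1L
  }
  expect_gte(n_cases, 100L)
})

test_that("flat profile scores zero and self-hits dominate", {
  # match emissions equal to the background at every position
  aln <- seed_alignment("flat", "s1", "AAAA")
  pf <- build_profile(aln, background = "uniform")
  pf$match_emissions[] <- 1 / 20
  pf <- apvhunter:::.profile_precompute(pf)
  h <- viterbi_score(pf, "CCCC")
  # an all-match path emits at background odds: only transitions contribute;
  # the match-state log-odds part is exactly 0
  expect_true(all(pf$lodds[, "C"] == 0))

  seqp <- rand_prot(40)
  pfs <- build_profile(seed_alignment("self", "s1", seqp))
  hs <- viterbi_score(pfs, seqp)
  expect_gt(hs$bitscore, 0)
  expect_equal(hs$coverage, 1.0)
})

test_that("scores are invariant to id relabeling and monotone in emissions", {
  set.seed(202)
  seqp <- rand_prot(30)
  pf <- build_profile(seed_alignment("m", "id_one", seqp))
  pf2 <- build_profile(seed_alignment("m", "completely_different_id", seqp))
  q <- rand_prot(25)
  expect_equal(viterbi_score(pf, q)$bitscore, viterbi_score(pf2, q)$bitscore)

  # decrease the emission probability of the residue the first match state
  # aligns; redistribute mass: score cannot increase
  h <- viterbi_score(pf, seqp)
  res <- substr(seqp, 1, 1)
  pf3 <- pf
  taken <- pf3$match_emissions[1, res] * 0.5
  pf3$match_emissions[1, res] <- taken
  others <- setdiff(colnames(pf3$match_emissions), res)
  pf3$match_emissions[1, others] <- pf3$match_emissions[1, others] +
    taken / length(others)
  pf3 <- apvhunter:::.profile_precompute(pf3)
  expect_lte(viterbi_score(pf3, seqp)$bitscore, h$bitscore)
})

test_that("align_to_profile projects onto match states", {
  seqp <- rand_prot(25)
  pf <- build_profile(seed_alignment("p", "s1", seqp))
  expect_equal(align_to_profile(pf, seqp), seqp)

  # one deleted residue: exactly one gap in the projection
  del <- paste0(substr(seqp, 1, 9), substr(seqp, 11, 25))
  row <- align_to_profile(pf, del)
  expect_equal(nchar(row), pf$L)
  expect_equal(sum(strsplit(row, "")[[1]] == "-"), 1L)

  # stacked projections form a rectangular alignment of width L
  set.seed(7)
  members <- vapply(1:4, function(i) mutate_protein(seqp, 0.7), character(1))
  rows <- vapply(members, function(m) align_to_profile(pf, m), character(1))
  expect_true(all(nchar(rows) == pf$L))
})

test_that("search_database filters, excludes blacklist and sorts", {
  set.seed(303)
  seeds <- toy_seed_alignments()
  pf <- build_profile(seeds$ORF21)
  parents <- toy_seed_proteins()
  db <- c(
    stats::setNames(as.list(seeds$ORF21$rows), seeds$ORF21$ids),
    hom60 = mutate_protein(parents[["ORF21"]], 0.60),
    dec1 = rand_prot(140), dec2 = rand_prot(140), dec3 = rand_prot(150))
  db <- vapply(db, identity, character(1))
  hits <- search_database(pf, db)
  expect_true(all(seeds$ORF21$ids %in% hits$sequence_id))   # self-recovery
  expect_true("hom60" %in% hits$sequence_id)                # planted homolog
  expect_false(any(c("dec1", "dec2", "dec3") %in% hits$sequence_id))
  expect_false(is.unsorted(rev(hits$bitscore)))

  bl <- seeds$ORF21$ids[1]
  hits2 <- search_database(pf, db, blacklist = bl)
  expect_false(bl %in% hits2$sequence_id)
})

test_that("refine_profile converges, recruits ladders and blacklists fusions", {
  set.seed(404)
  parent <- toy_seed_proteins()[["ORF17"]]
  seeds <- toy_seed_alignments()
  seed <- seeds$ORF17

  # fixed point: database containing only the seeds adds nothing
  db0 <- stats::setNames(seed$rows, seed$ids)
  r0 <- refine_profile(seed, db0)
  expect_setequal(r0$member_ids, seed$ids)
  expect_length(r0$blacklist, 0L)

  # identity ladder: the distant tier is only reachable through intermediates
  h70 <- mutate_protein(parent, 0.70)
  h50 <- mutate_protein(h70, 0.70)     # ~50% of parent
  h35 <- mutate_protein(h50, 0.70)     # ~35% of parent
  db <- c(db0, lad70 = h70, lad50 = h50, lad35 = h35)
  r <- refine_profile(seed, db, max_iter = 8L)
  expect_true(all(c("lad70", "lad50") %in% r$member_ids))
  expect_gte(r$n_iter, 2L)
  if ("lad35" %in% r$member_ids) expect_gt(r$n_iter, 1L)

  # fusion: homolog plus 2L unrelated residues trips the overhang rule
  L <- build_profile(seed)$L
  fusion <- paste0(mutate_protein(parent, 0.7), rand_prot(2L * L))
  rf <- refine_profile(seed, c(db0, fusion1 = fusion), max_iter = 5L)
  expect_true("fusion1" %in% rf$blacklist)
  expect_false("fusion1" %in% rf$member_ids)

  # idempotence at the fixed point
  r2 <- refine_profile(r$alignment, db, max_iter = 5L)
  expect_setequal(r2$member_ids, r$member_ids)
  # empty database returns the seed-only profile
  re <- refine_profile(seed, stats::setNames(character(0), character(0)))
  expect_setequal(re$member_ids, seed$ids)
})

test_that("profile text serialization round-trips", {
  pf <- build_profile(toy_seed_alignments()$ORF24)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile(pf, p)
  pf2 <- read_profile(p)
  expect_equal(pf2$L, pf$L)
  expect_equal(pf2$match_emissions, pf$match_emissions, tolerance = 1e-6)
  q <- mutate_protein(toy_seed_proteins()[["ORF24"]], 0.6)
  expect_equal(viterbi_score(pf2, q)$bitscore, viterbi_score(pf, q)$bitscore,
               tolerance = 1e-4)
})
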