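test_that("global alignment identity matches hand-verified cases", {
  expect_equal(global_align_identity("ACDEF", "ACDEF"), 1.0)
  expect_equal(global_align_identity("ACDEF", "ACDFF"), 0.8)
  set.seed(61)
  for (rep in 1:10) {
    a <- rand_prot(sample(30:80, 1)); b <- rand_prot(sample(30:80, 1))
    expect_equal(global_align_identity(a, b), global_align_identity(b, a))
  }
})

test_that("pangenome thresholds reproduce the printed 37/21/5 for 41", {
  expect_equal(pangenome_threshold(41, 0.90), 37L)
  expect_equal(pangenome_threshold(41, 0.50), 21L)
  expect_equal(pangenome_threshold(41, 0.10), 5L)
  expect_equal(pangenome_threshold(10, 0.90), 10L)  # 9/10 is not > 90%
  # strict-exceed property over a large range, robust to float representation
  for (n in c(1:200, 997, 1000, 4096, 9999, 10000)) {
    for (f in c(0.1, 0.5, 0.9)) {
      k <- pangenome_threshold(n, f)
      expect_gt(k / n, f)
      expect_lte((k - 1) / n, f)
    }
  }
})

test_that("cluster labels follow the core/shell/cloud bands", {
  mk <- function(n) structure(list(cluster_id = "x", representative = "r",
                                   members = data.frame(), n_genomes = n,
                                   label = NA), class = "pangenome_cluster")
  lab <- function(n) classify_clusters(list(mk(n)), 41L)[[1]]$label
  expect_equal(lab(38), "core")
  expect_equal(lab(37), "core")
  expect_equal(lab(36), "shell")
  expect_equal(lab(21), "shell")
  expect_equal(lab(20), "cloud")
  expect_equal(lab(5), "cloud")
  expect_equal(lab(4), "singleton_or_rare")
})

test_that("greedy clustering partitions deterministically", {
  set.seed(62)
  p <- rand_prot(120)
  fam <- data.frame(
    genome_id = c("g1", "g2", "g3", "g4"),
    protein_id = c("a1", "a2", "a3", "b1"),
    seq = c(p, mutate_protein(p, 0.6), mutate_protein(p, 0.6),
            rand_prot(100)),
    stringsAsFactors = FALSE)
  cl <- greedy_cluster(fam, identity_threshold = 0.15)
  expect_length(cl, 2L)
  sizes <- sort(vapply(cl, function(x) nrow(x$members), integer(1)))
  expect_equal(sizes, c(1L, 3L))
  # partition property: every protein in exactly one cluster
  all_ids <- unlist(lapply(cl, function(x) x$members$protein_id))
  expect_setequal(all_ids, fam$protein_id)
  expect_equal(length(all_ids), nrow(fam))

  # identical proteins collapse; threshold 1.0 on distinct sequences -> singletons
  same <- data.frame(genome_id = c("g1", "g2", "g3"),
                     protein_id = c("s1", "s2", "s3"),
                     seq = rep(p, 3), stringsAsFactors = FALSE)
  expect_length(greedy_cluster(same, 0.5), 1L)
  distinct <- data.frame(genome_id = c("g1", "g2"),
                         protein_id = c("d1", "d2"),
                         seq = c(rand_prot(90), rand_prot(95)),
                         stringsAsFactors = FALSE)
  expect_length(greedy_cluster(distinct, 1.0), 2L)

  # determinism
  cl2 <- greedy_cluster(fam[sample(nrow(fam)), ], identity_threshold = 0.15)
  expect_equal(cluster_table(cl)$n_members, cluster_table(cl2)$n_members)
})

test_that("presence/absence matrix conserves membership counts", {
  set.seed(63)
  pg <- make_pangenome_truth(n_genomes = 10L, n_core = 2L, n_shell = 2L,
                             n_cloud = 3L, n_rare = 1L)
  cl <- greedy_cluster(pg$proteins, 0.15)
  cl <- classify_clusters(cl, 10L)
  m <- presence_absence(cl, pg$genomes,
                        labels = c("core", "shell", "cloud",
                                   "singleton_or_rare"))
  keep <- vapply(cl, function(x)
    x$label %in% c("core", "shell", "cloud", "singleton_or_rare"), TRUE)
  expect_equal(unname(colSums(m)),
               vapply(cl[keep], function(x) x$n_genomes, integer(1)))
  # an all-ones column for a cluster present everywhere
  full <- which(colSums(m) == 10L)
  if (length(full)) expect_true(all(m[, full[1]] == 1L))
})

test_that("Jaccard distance handles edge cases", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 0, 0),
             d = c(0, 0, 0, 0), e = c(0, 0, 0, 0))
  d <- binary_distance(m)
  expect_equal(d["a", "b"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["d", "e"], 1)      # empty union convention
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(isSymmetric(unname(d)))
  expect_error(binary_distance(m[1, , drop = FALSE]), "two genomes")
})

test_that("average linkage reproduces hand UPGMA and matches hclust", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 5
  tr <- average_linkage(d)
  expect_equal(tr$merges$height, c(1, 4.5))

  dup <- matrix(c(0, 0, 0, 0), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(average_linkage(dup)$merges$height, 0)

  set.seed(64)
  for (rep in 1:110) {
    n <- sample(5:7, 1)
    pts <- matrix(runif(n * 3), n)
    rownames(pts) <- sprintf("L%02d", seq_len(n))
    dm <- as.matrix(dist(pts))
    mine <- average_linkage(dm)
    ref <- stats::hclust(stats::as.dist(dm), method = "average")
    expect_equal(sort(mine$merges$height), sort(ref$height),
                 tolerance = 1e-10)
    co_ref <- as.matrix(stats::cophenetic(ref))
    co_mine <- cophenetic_distance(mine)
    expect_equal(co_mine[rownames(co_ref), colnames(co_ref)], co_ref,
                 tolerance = 1e-10)
    expect_false(is.unsorted(mine$merges$height))
  }
  dn <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  expect_error(average_linkage(dn), "NA")
})

test_that("Newick export round-trips through ape", {
  skip_if_not_installed("ape")
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  nw <- to_newick(average_linkage(d2))
  expect_match(nw, "^\\(A:0\\.8,B:0\\.8\\);$")

  # labels with spaces or metacharacters are quoted
  dq <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("tip one", "b:c"), c("tip one", "b:c")))
  expect_match(to_newick(average_linkage(dq)), "'tip one'", fixed = TRUE)
  expect_match(to_newick(average_linkage(dq)), "'b:c'", fixed = TRUE)

  set.seed(65)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(n * 2), n)
    labs <- sprintf("tip%02d", seq_len(n))
    rownames(pts) <- labs
    dm <- as.matrix(dist(pts)); dimnames(dm) <- list(labs, labs)
    tr <- average_linkage(dm)
    ph <- ape::read.tree(text = to_newick(tr))
    expect_setequal(ph$tip.label, labs)
    # cophenetic structure survives the round trip: the patristic distance
    # between two leaves of an ultrametric tree is twice the merge height
    co <- cophenetic_distance(tr)
    co_ape <- ape::cophenetic.phylo(ph)
    expect_equal(co_ape[labs, labs], 2 * co[labs, labs], tolerance = 1e-6)
  }
})

test_that("cluster mean pairwise AAI recovers the generator target", {
  set.seed(66)
  mk <- function(members) structure(
    list(cluster_id = "c", representative = "r",
         members = data.frame(genome_id = seq_along(members),
                              protein_id = paste0("p", seq_along(members)),
                              seq = members, stringsAsFactors = FALSE),
         n_genomes = length(members), label = NA),
    class = "pangenome_cluster")
  p <- rand_prot(150)
  expect_equal(cluster_mean_pairwise_aai(mk(rep(p, 3))), 1.0)
  # controlled pair: parent + one mutant at 40% target identity
  vals <- replicate(6, cluster_mean_pairwise_aai(
    mk(c(p, mutate_protein(p, 0.40)))))
  expect_lt(max(abs(vals - 0.40)), 0.05)
  # invariant to member order
  mem <- c(p, mutate_protein(p, 0.5), mutate_protein(p, 0.7))
  expect_equal(cluster_mean_pairwise_aai(mk(mem)),
               cluster_mean_pairwise_aai(mk(rev(mem))))
  expect_true(is.na(cluster_mean_pairwise_aai(mk(p))))
})
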