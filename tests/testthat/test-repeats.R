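test_that("terminal repeats decide circularity with a strict 30 bp bound", {
  set.seed(51)
  r35 <- rand_dna(35)
  ct <- contig("c", paste0(r35, rand_dna(3000), r35))
  res <- detect_terminal_repeats(ct)
  expect_true(res$circular)
  expect_equal(res$repeat_hit$length, 35L)

  r30 <- rand_dna(30)
  ct2 <- contig("c2", paste0(r30, rand_dna(3000), r30))
  expect_false(detect_terminal_repeats(ct2)$circular)

  ct3 <- contig("c3", rand_dna(5000))
  expect_false(detect_terminal_repeats(ct3)$circular)

  # contig shorter than twice the minimum: false, no error
  expect_false(detect_terminal_repeats(contig("c4", rand_dna(50)))$circular)
})

test_that("re-linearizing a synthetic circle at any cut stays circular", {
  set.seed(52)
  tr <- 40L
  body <- rand_dna(2000)
  for (cut in c(0L, 113L, 999L, 1501L)) {
    rot <- paste0(substr(body, cut + 1, nchar(body)), substr(body, 1, cut))
    ct <- contig("r", paste0(rot, substr(rot, 1, tr)))
    expect_true(detect_terminal_repeats(ct)$circular)
  }
})

test_that("planted repeats near the literature boundaries behave strictly", {
  set.seed(53)
  u <- rand_dna(26)
  u2 <- u
  substr(u2, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                substr(u, 13, 13))[1]
  s <- paste0(rand_dna(300), u, u2, rand_dna(300))
  hits <- find_repeats(s, min_len = 26L, max_mismatch = 1L)
  direct <- hits[hits$kind == "direct", ]
  expect_true(any(direct$pos1 <= 300 & direct$pos2 >= 300 &
                    direct$length >= 26 & direct$mismatches <= 1))

  v <- rand_dna(25)
  s2 <- paste0(rand_dna(200), v, v, rand_dna(200))
  expect_equal(nrow(find_repeats(s2, 26L, 1L)), 0L)

  w <- rand_dna(30)
  s3 <- paste0(rand_dna(150), w, rand_dna(200), revcomp_h(w), rand_dna(150))
  pal <- find_repeats(s3, 26L, 1L, kinds = "palindromic")
  expect_gt(nrow(pal), 0L)
  expect_true(all(pal$orientation == "reverse_complement"))
})

test_that("repeat finder matches the definitional oracle on random inputs", {
  set.seed(54)
  n_cases <- 0L
  for (rep in 1:110) {
    n <- sample(c(120, 180, 250), 1L)
    gc <- runif(1, 0.4, 0.65)
    s <- rand_dna(n, gc)
    # plant something half the time to stress non-trivial structure
    if (rep %% 2 == 0) {
      u <- rand_dna(sample(12:20, 1))
      mode <- sample(3, 1)
      ins <- switch(mode, paste0(u, u),
                    paste0(u, rand_dna(15), u),
                    paste0(u, rand_dna(10), revcomp_h(u)))
      at <- sample(n - 10, 1)
      s <- paste0(substr(s, 1, at), ins, substr(s, at + 1, n))
    }
    mm <- sample(0:1, 1L)
    ml <- sample(10:14, 1L)
    got <- find_repeats(s, min_len = ml, max_mismatch = mm, max_span = 10000L)
    want <- repeat_oracle(s, min_len = ml, max_mismatch = mm)
    expect_equal(repeat_key(got), repeat_key(want))
    # seeded and full-scan modes agree
    got2 <- find_repeats(s, min_len = ml, max_mismatch = mm,
                         max_span = 10000L, use_seeds = FALSE)
    expect_equal(repeat_key(got), repeat_key(got2))
    n_cases <- n_cases + 1L
  }
  expect_gte(n_cases, 100L)
})

test_that("reverse-complementing the input reflects the hit sets", {
  set.seed(55)
  for (rep in 1:10) {
    s <- rand_dna(200)
    u <- rand_dna(14)
    s <- paste0(substr(s, 1, 60), u, rand_dna(12), u,
                rand_dna(30), u, rand_dna(8), revcomp_h(u),
                substr(s, 61, 200))
    n <- nchar(s)
    a <- find_repeats(s, 12L, 1L, max_span = 10000L)
    b <- find_repeats(revcomp_h(s), 12L, 1L, max_span = 10000L)
    expect_equal(table(a$kind), table(b$kind))
    # coordinates reflect: (p1, p2, len) -> (n - p2 - len, n - p1 - len)
    refl <- data.frame(pos1 = n - b$pos2 - b$length,
                       pos2 = n - b$pos1 - b$length,
                       length = b$length, mismatches = b$mismatches,
                       kind = b$kind)
    expect_equal(repeat_key(a), repeat_key(refl))
  }
})

test_that("no reported repeat can be extended without breaking the budget", {
  set.seed(56)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  for (rep in 1:5) {
    u <- rand_dna(18)
    s <- paste0(rand_dna(100), u, rand_dna(20), u, rand_dna(100))
    hits <- find_repeats(s, 12L, 1L, max_span = 10000L)
    dir <- hits[hits$kind != "palindromic", ]
    for (i in seq_len(nrow(dir))) {
      p1 <- dir$pos1[i]; p2 <- dir$pos2[i]; len <- dir$length[i]
      sub <- function(p, l) substr(s, p + 1, p + l)
      can_left <- p1 - 1 >= 0 && len + 1 <= p2 - (p1 - 1) &&
        ham(sub(p1 - 1, len + 1), sub(p2 - 1, len + 1)) <= 1
      can_right <- p2 + len < nchar(s) && len + 1 <= p2 - p1 &&
        ham(sub(p1, len + 1), sub(p2, len + 1)) <= 1
      expect_false(can_left || can_right)
    }
  }
})

test_that("origin placement labels repeats relative to the core region", {
  call <- structure(list(contig_id = "c", status = "complete",
                         cluster1_span = c(10000L, 14000L),
                         cluster2_span = c(18000L, 22000L),
                         core_span = c(10000L, 22000L),
                         contig_length = 30000L),
                    class = "element_call")
  reps <- data.frame(pos1 = c(9400L, 15000L, 22500L, 2000L),
                     pos2 = c(9500L, 15100L, 22600L, 2100L),
                     length = c(30L, 30L, 30L, 30L),
                     mismatches = 0L, kind = "interspersed_direct",
                     orientation = "same")
  out <- locate_putative_ori(reps, call, window = 2000L,
                             contig_length = 30000L)
  expect_equal(out$placement,
               c("before_cluster1", "other", "after_cluster2", "other"))

  # circular wrap: a repeat just before the origin is upstream of an early
  # cluster 1 once distances are taken modulo the contig length
  call2 <- call
  call2$cluster1_span <- c(500L, 4000L)
  call2$cluster2_span <- c(8000L, 12000L)
  reps2 <- data.frame(pos1 = 29500L, pos2 = 29600L, length = 30L,
                      mismatches = 0L, kind = "interspersed_direct",
                      orientation = "same")
  out2 <- locate_putative_ori(reps2, call2, window = 2000L,
                              contig_length = 30000L, circular = TRUE)
  expect_equal(out2$placement, "before_cluster1")
})
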