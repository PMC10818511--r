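# Independent reference implementations used to validate the fast paths.

AA20h <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_prot <- function(n, alphabet = AA20h) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

revcomp_h <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# ---- Viterbi oracle: exhaustive enumeration of all legal glocal state paths

viterbi_enumerate <- function(profile, protein) {
  L <- profile$L
  lod <- profile$lodds
  lt <- profile$ltrans
  chars <- strsplit(protein, "")[[1]]
  ci <- match(chars, AA20h)
  ci[is.na(ci)] <- 21L
  n <- length(ci)
  best <- -Inf

  # state in {"M","I","D"}; k = profile position of the state; i = number of
  # residues consumed so far (window is contiguous; flanks are free)
  step <- function(state, k, i, sc) {
    if (k == L && state != "I") {
      best <<- max(best, sc)            # exit to E from M_L / D_L
      return(invisible())
    }
    if (state == "M" || state == "D") {
      pre <- if (state == "M") "m" else "d"
      if (k < L) {
        if (i < n) step("M", k + 1L, i + 1L,
                        sc + lt[[paste0(pre, "m")]][k] + lod[k + 1L, ci[i + 1L]])
        step("D", k + 1L, i, sc + lt[[paste0(pre, "d")]][k])
        if (state == "M" && i < n) step("I", k, i + 1L, sc + lt$mi[k])
      }
    } else if (i < n) {                 # insert at k (dead end once i == n)
      step("I", k, i + 1L, sc + lt$ii[k])
      step("M", k + 1L, i + 1L, sc + lt$im[k] + lod[k + 1L, ci[i + 1L]])
    }
  }
  for (a in 0:n) {                      # a = residues skipped before the window
    if (a < n) step("M", 1L, a + 1L, lt$bm + lod[1L, ci[a + 1L]])
  }
  for (a in 0:n) step("D", 1L, a, lt$bd)
  best
}

# ---- repeat oracle: definitional maximal-pair enumeration (small sequences)

repeat_oracle <- function(s, min_len, max_mismatch, max_span = 10000L) {
  v <- strsplit(toupper(s), "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", v)
  n <- length(v)
  valid_n <- v %in% c("A", "C", "G", "T")
  hits <- list()
  add <- function(p1, p2, len, mm, kind) {
    hits[[length(hits) + 1L]] <<- data.frame(
      pos1 = p1, pos2 = p2, length = len, mismatches = mm, kind = kind)
  }
  # direct orientation: diagonal d = p2 - p1
  for (d in seq_len(n - 1)) {
    len_d <- n - d
    if (min(len_d, d) < min_len) next
    mis <- !(valid_n[1:len_d] & valid_n[(1 + d):(len_d + d)] &
               v[1:len_d] == v[(1 + d):(len_d + d)])
    C <- c(0L, cumsum(mis))
    cnt <- function(p1, len) C[p1 + len + 1L] - C[p1 + 1L]  # p1 0-based
    for (len in min_len:min(len_d, d)) {
      for (p1 in 0:(len_d - len)) {
        if (cnt(p1, len) > max_mismatch) next
        if (d - len > max_span) next
        # extension checks (validity includes non-overlap len <= d)
        ext_l <- p1 - 1L >= 0L && len + 1L <= d &&
          cnt(p1 - 1L, len + 1L) <= max_mismatch
        ext_r <- p1 + len < len_d && len + 1L <= d &&
          cnt(p1, len + 1L) <= max_mismatch
        if (ext_l || ext_r) next
        add(p1, p1 + d, len, cnt(p1, len),
            if (d == len) "direct" else "interspersed_direct")
      }
    }
  }
  # palindromic orientation: anti-diagonal c = p1 + p2 + len - 1
  for (cc in 1:(2 * n - 3)) {
    a_lo <- max(0L, cc - (n - 1L))
    a_hi <- (cc - 1L) %/% 2L
    if (a_hi < a_lo) next
    aa <- a_lo:a_hi
    m_ok <- valid_n[aa + 1L] & valid_n[cc - aa + 1L] &
      v[aa + 1L] == comp[cc - aa + 1L]
    mis <- !m_ok
    C <- c(0L, cumsum(mis))
    w <- length(aa)
    cnt <- function(o, len) C[o + len + 1L] - C[o + 1L]     # o = offset in aa
    if (w < min_len) next
    for (len in min_len:w) {
      for (o in 0:(w - len)) {
        if (cnt(o, len) > max_mismatch) next
        p1 <- a_lo + o
        e  <- a_lo + o + len - 1L
        p2 <- cc - e
        if (p2 - (p1 + len) > max_span) next
        ext_l <- o - 1L >= 0L && cnt(o - 1L, len + 1L) <= max_mismatch
        ext_r <- o + len <= w - 1L && cnt(o, len + 1L) <= max_mismatch
        if (ext_l || ext_r) next
        add(p1, p2, len, cnt(o, len), "palindromic")
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(pos1 = integer(), pos2 = integer(), length = integer(),
                      mismatches = integer(), kind = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$kind, out$pos1, out$pos2, out$length), , drop = FALSE]
}

repeat_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(sprintf("%s:%d:%d:%d:%d", df$kind, df$pos1, df$pos2,
               df$length, df$mismatches))
}

# ---- spacer oracle: sliding-window Hamming distance, both strands

spacer_oracle <- function(spacers, targets, min_identity = 0.97,
                          min_len = 30L) {
  rows <- list()
  for (sid in names(spacers)) {
    sp <- toupper(spacers[[sid]])
    len <- nchar(sp)
    if (len <= min_len) next
    spv <- strsplit(sp, "")[[1]]
    rcv <- strsplit(revcomp_h(sp), "")[[1]]
    for (tid in names(targets)) {
      tv <- strsplit(toupper(targets[[tid]]), "")[[1]]
      nt <- length(tv)
      if (nt < len) next
      for (at in 0:(nt - len)) {
        win <- tv[(at + 1):(at + len)]
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") spv else rcv
          ident <- sum(win == pat) / len
          if (ident > min_identity) {
            rows[[length(rows) + 1L]] <- data.frame(
              spacer_id = sid, target_contig = tid, start = at,
              end = at + len, identity = ident, match_length = len,
              strand = strand, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer_id = character(), target_contig = character(),
                      start = integer(), end = integer(),
                      identity = numeric(), match_length = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$target_contig, out$start, out$spacer_id), , drop = FALSE]
}

spacer_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(sprintf("%s:%s:%d:%s:%.6f", df$spacer_id, df$target_contig, df$start,
               df$strand, df$identity))
}
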