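#' Translate a nucleotide sequence (translation table 11)
#'
#' Stops are rendered as `*`; codons containing N (or any character without a
#' table entry) translate to `X`.
#'
#' @param dna Nucleotide string whose length is divisible by 3.
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

STOP_CODONS  <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# ORFs for one reading frame of one strand; returns codon-index coordinates.
.orfs_one_frame <- function(codons, min_protein_len) {
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  stop_idx <- which(aa == "*")
  if (!length(stop_idx)) return(NULL)
  start_ok <- codons %in% START_CODONS
  out <- vector("list", length(stop_idx))
  prev_stop <- 0L
  for (j in seq_along(stop_idx)) {
    s <- stop_idx[[j]]
    if (s - prev_stop >= 2L) {
      rng <- (prev_stop + 1L):(s - 1L)
      cand <- rng[start_ok[rng]]
      if (length(cand)) {
        a <- cand[[1L]]                       # maximal ORF: first start
        plen <- s - a
        if (plen >= min_protein_len) {
          out[[j]] <- c(a, s, plen)
        }
      }
    }
    prev_stop <- s
  }
  do.call(rbind, out)
}

#' Find open reading frames on both strands of a contig
#'
#' A simple six-frame maximal-ORF caller: ORFs begin at the first in-frame
#' start codon (ATG/GTG/TTG) after the previous stop and end at the first
#' in-frame stop (TAA/TAG/TGA). Reverse-strand ORFs are reported in forward
#' 0-based half-open coordinates. ORFs are not split at Ns (N translates
#' to X).
#'
#' @param ct A [contig()].
#' @param min_protein_len Minimum protein length (stop excluded); default 60.
#' @return A data frame with columns contig_id, start, end, strand, frame,
#'   protein, orf_index (orf_index strictly increasing with start).
#' @export
find_orfs <- function(ct, min_protein_len = 60L) {
  stopifnot(inherits(ct, "contig"), min_protein_len >= 1L)
  n <- nchar(ct$sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") ct$sequence else revcomp_dna(ct$sequence)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      starts <- seq(f + 1L, by = 3L, length.out = ncod)
      codons <- substring(s, starts, starts + 2L)
      m <- .orfs_one_frame(codons, min_protein_len)
      if (is.null(m)) next
      for (i in seq_len(nrow(m))) {
        a <- m[i, 1L]; e <- m[i, 2L]
        st0 <- f + 3L * (a - 1L)              # 0-based on scanned strand
        en0 <- f + 3L * e
        if (strand == "-") { tmp <- st0; st0 <- n - en0; en0 <- n - tmp }
        prot <- translate_dna(if (strand == "+")
          substr(ct$sequence, st0 + 1L, en0 - 3L) else
          substr(s, f + 3L * (a - 1L) + 1L, f + 3L * (e - 1L)))
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = ct$id, start = st0, end = en0, strand = strand,
          frame = f, protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      orf_index = integer(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  orfs$orf_index <- seq_len(nrow(orfs))
  rownames(orfs) <- NULL
  orfs
}
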