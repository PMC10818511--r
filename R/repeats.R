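REPEAT_KINDS <- c("terminal", "direct", "interspersed_direct", "palindromic")

#' Decide contig circularity from terminal repeats
#'
#' A contig is called circular when an exact prefix of at least `min_len` bp
#' equals a suffix of the same length; the longest such match is reported.
#' The default `min_len = 31` implements "terminal repeats longer than 30 bp".
#'
#' @param ct A [contig()].
#' @param min_len Minimum terminal repeat length in bp.
#' @return List: circular (logical), repeat_hit (one-row data frame or NULL),
#'   contig (the input with its `circular` flag set).
#' @export
detect_terminal_repeats <- function(ct, min_len = 31L) {
  stopifnot(inherits(ct, "contig"), min_len >= 1L)
  s <- ct$sequence
  n <- nchar(s)
  best <- 0L
  if (n >= 2L * min_len) {
    first <- substr(s, 1L, 1L)
    for (len in seq.int(n %/% 2L, min_len)) {
      if (substr(s, n - len + 1L, n - len + 1L) != first) next
      if (substr(s, 1L, len) == substr(s, n - len + 1L, n)) { best <- len; break }
    }
  }
  ct$circular <- best > 0L
  hit <- NULL
  if (best > 0L) {
    hit <- data.frame(contig_id = ct$id, kind = "terminal",
                      pos1 = 0L, pos2 = n - best, length = best,
                      mismatches = 0L, orientation = "same",
                      stringsAsFactors = FALSE)
  }
  list(circular = ct$circular, repeat_hit = hit, contig = ct)
}

#' Find direct, interspersed direct and palindromic repeats
#'
#' Reports all maximal pairs (p1, p2, len) with Hamming distance at most
#' `max_mismatch` between `seq[p1, p1+len)` and either `seq[p2, p2+len)`
#' (same orientation) or its reverse complement (palindromic), with
#' `len >= min_len` and non-overlapping copies. Direct means adjacent copies
#' (p2 = p1 + len); interspersed direct means separated same-orientation
#' copies. Maximality: no one-base extension on either side keeps the
#' distance within `max_mismatch`. The default `min_len = 26` implements
#' "repeats > 25 bp with a maximum of 1 mismatch".
#'
#' @param seq Nucleotide string (or a [contig()]).
#' @param min_len Minimum repeat length (>= 8).
#' @param max_mismatch 0 or 1.
#' @param kinds Subset of direct / interspersed_direct / palindromic.
#' @param max_span Maximum separation between copies in bp.
#' @param use_seeds Use k-mer seeding (pigeonhole-complete); set FALSE to
#'   force the full diagonal scan.
#' @return Data frame (pos1, pos2, length, mismatches, kind, orientation),
#'   0-based positions, sorted by pos1, pos2.
#' @export
find_repeats <- function(seq, min_len = 26L, max_mismatch = 1L,
                         kinds = c("direct", "interspersed_direct", "palindromic"),
                         max_span = 5000L, use_seeds = TRUE) {
  if (inherits(seq, "contig")) seq <- seq$sequence
  stopifnot(min_len >= 8L, max_mismatch %in% c(0L, 1L))
  kinds <- match.arg(kinds, several.ok = TRUE)
  do_dir <- any(c("direct", "interspersed_direct") %in% kinds)
  do_pal <- "palindromic" %in% kinds
  df <- repeat_pairs_cpp(toupper(seq), as.integer(min_len),
                         as.integer(max_mismatch), as.integer(max_span),
                         do_dir, do_pal, isTRUE(use_seeds))
  df$kind <- c("direct", "interspersed_direct", "palindromic")[df$kind_code + 1L]
  df$kind_code <- NULL
  df <- unique(df)                 # tandem sub-pairs can arise from two windows
  df <- df[df$kind %in% kinds, , drop = FALSE]
  df$orientation <- ifelse(df$kind == "palindromic", "reverse_complement", "same")
  df <- df[order(df$pos1, df$pos2, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Place repeats relative to an element's core region
#'
#' Labels each repeat by the position of its midpoint relative to the core
#' region, in the element's reading orientation: within `window` bp upstream
#' of the cluster-1 start it is a candidate origin `before_cluster1`; within
#' `window` bp downstream of the cluster-2 end, `after_cluster2`; anything
#' else is `other`. For elements read on the minus strand
#' (`call$strand == "-"`) upstream/downstream are mirrored in contig
#' coordinates. On circular contigs distances are computed modulo the contig
#' length.
#'
#' @param repeats Data frame from [find_repeats()].
#' @param call An `element_call` with cluster spans.
#' @param window Flanking window in bp (default 2000).
#' @param contig_length Required for circular wrap-around.
#' @param circular Is the contig circular?
#' @return The repeats data frame with a `placement` column.
#' @export
locate_putative_ori <- function(repeats, call, window = 2000L,
                                contig_length = call$contig_length,
                                circular = FALSE) {
  if (is.null(call$cluster1_span) && is.null(call$cluster2_span)) {
    stop("element call carries no cluster spans")
  }
  mid <- (repeats$pos1 + repeats$pos2 + repeats$length) / 2
  place <- rep("other", nrow(repeats))
  n <- contig_length
  minus <- identical(call$strand, "-")
  updist <- function(from, to) if (circular) (from - to) %% n else from - to
  if (!is.null(call$cluster1_span)) {
    d <- if (minus) updist(mid, call$cluster1_span[[2L]]) else
      updist(call$cluster1_span[[1L]], mid)
    place[d > 0 & d <= window] <- "before_cluster1"
  }
  if (!is.null(call$cluster2_span)) {
    d <- if (minus) updist(call$cluster2_span[[1L]], mid) else
      updist(mid, call$cluster2_span[[2L]])
    place[d > 0 & d <= window & place == "other"] <- "after_cluster2"
  }
  repeats$placement <- place
  repeats
}
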