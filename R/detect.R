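MARKERS_CLUSTER1 <- c("ORF6", "ORF8")
MARKERS_CLUSTER2 <- c("ORF17", "ORF21", "ORF23", "ORF24")
MARKERS6 <- c(MARKERS_CLUSTER1, MARKERS_CLUSTER2)

#' Synteny model for the two conserved gene clusters
#'
#' Cluster 1 (ORF6-ORF9) must precede cluster 2 (ORF17, ORF21, ORF23-ORF25)
#' in one consistent orientation, with within-cluster gene order conserved.
#' Only the six searched markers drive classification; neighbors such as
#' ORF7/ORF9/ORF25 participate when profiles or annotations for them are
#' supplied.
#'
#' @param cluster1_markers,cluster2_markers Ordered marker name vectors.
#' @return A `synteny_model` list.
#' @export
synteny_model <- function(cluster1_markers = MARKERS_CLUSTER1,
                          cluster2_markers = MARKERS_CLUSTER2) {
  structure(list(cluster1 = cluster1_markers, cluster2 = cluster2_markers),
            class = "synteny_model")
}

#' Scan a contig's ORFs with marker profiles
#'
#' Every ORF x profile pairing above both the bitscore and coverage threshold
#' is recorded; when one ORF passes several profiles only the highest-bitscore
#' marker is kept for that ORF (ties broken alphabetically by marker name).
#' Reported start/end are the matched envelope (the contig span of the
#' residues aligned to match states), not the full ORF: the simple maximal-ORF
#' caller can fuse a marker gene with an upstream stop-free stretch, and the
#' envelope keeps marker coordinates honest for synteny and span logic.
#'
#' @param orfs ORF table from [find_orfs()] (one contig).
#' @param profiles List of [build_profile()] results.
#' @return Marker hit table: data frame (contig_id, marker, orf_index, start,
#'   end, strand, bitscore, coverage), where start/end delimit the matched
#'   envelope within the ORF.
#' @export
scan_contig <- function(orfs, profiles) {
  empty <- data.frame(contig_id = character(), marker = character(),
                      orf_index = integer(), start = integer(),
                      end = integer(), strand = character(),
                      bitscore = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(orfs) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    best <- NULL
    for (pf in profiles) {
      if (nchar(orfs$protein[[i]]) < pf$coverage_threshold * pf$L) next
      h <- viterbi_score(pf, orfs$protein[[i]])
      if (h$bitscore >= pf$score_threshold &&
          h$coverage >= pf$coverage_threshold) {
        if (is.null(best) || h$bitscore > best$bitscore ||
            (h$bitscore == best$bitscore &&
             pf$name < best$profile_name)) {
          best <- h
        }
      }
    }
    if (!is.null(best)) {
      os <- orfs$start[[i]]; oe <- orfs$end[[i]]
      if (best$first_emit > 0L) {
        if (orfs$strand[[i]] == "+") {
          hs <- os + 3L * (best$first_emit - 1L)
          he <- os + 3L * best$last_emit
        } else {
          hs <- oe - 3L * best$last_emit
          he <- oe - 3L * (best$first_emit - 1L)
        }
      } else {
        hs <- os; he <- oe
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = orfs$contig_id[[i]], marker = best$profile_name,
        orf_index = orfs$orf_index[[i]], start = hs, end = he,
        strand = orfs$strand[[i]],
        bitscore = best$bitscore, coverage = best$coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a contig from its marker hit table
#'
#' A contig is a complete element when it carries at least five of the six
#' distinct markers and is longer than 10,000 bp; an incomplete element when
#' it carries three or four distinct markers above the same length; negative
#' otherwise. Distinctness is counted over marker names, not raw hits.
#'
#' @param hit_table Output of [scan_contig()] for this contig.
#' @param ct The [contig()].
#' @param min_contig_len Strict length threshold in bp (default 10000:
#'   "longer than 10,000 bp").
#' @param min_markers_incomplete,min_markers_complete Distinct-marker counts.
#' @return An `element_call` list: contig_id, status, n_distinct_markers,
#'   contig_length, plus synteny/span slots filled by [check_synteny()] and
#'   [detect_elements()].
#' @export
classify_contig <- function(hit_table, ct, min_contig_len = 10000L,
                            min_markers_incomplete = 3L,
                            min_markers_complete = 5L) {
  n <- length(unique(hit_table$marker))
  len <- nchar(ct$sequence)
  status <- if (len > min_contig_len && n >= min_markers_complete) "complete"
            else if (len > min_contig_len && n >= min_markers_incomplete) "incomplete"
            else "negative"
  structure(list(contig_id = ct$id, status = status, n_distinct_markers = n,
                 contig_length = len, synteny_ok = NA,
                 cluster1_span = NULL, cluster2_span = NULL, core_span = NULL,
                 variable_region_gene_count = NA_integer_),
            class = "element_call")
}

#' @export
print.element_call <- function(x, ...) {
  cat(sprintf("<element_call %s: %s, %d markers, %d bp, synteny_ok=%s>\n",
              x$contig_id, x$status, x$n_distinct_markers, x$contig_length,
              as.character(x$synteny_ok)))
  invisible(x)
}

# is `x` a subsequence of `ref` (order conserved)?
.is_subseq <- function(x, ref) {
  pos <- match(x, ref)
  !anyNA(pos) && !is.unsorted(pos, strictly = TRUE)
}

# one linear orientation check: all cluster-1 markers precede all cluster-2
# markers and within-cluster orders follow the model
.synteny_linear <- function(markers, model) {
  in1 <- markers %in% model$cluster1
  in2 <- markers %in% model$cluster2
  if (any(!(in1 | in2))) return(FALSE)
  if (any(in1) && any(in2) && max(which(in1)) > min(which(in2))) return(FALSE)
  .is_subseq(markers[in1], model$cluster1) &&
    .is_subseq(markers[in2], model$cluster2)
}

#' Check marker synteny along a contig
#'
#' Reads the markers in contig order and tests whether, in one consistent
#' orientation, all present cluster-1 markers precede all present cluster-2
#' markers with conserved within-cluster order. Linear contigs are tested in
#' both orientations; circular contigs over all rotations of both
#' orientations.
#'
#' @param hit_table Output of [scan_contig()].
#' @param model A [synteny_model()].
#' @param orfs ORF table of the contig (for variable-region gene counting).
#' @param circular Is the contig circular?
#' @return List: synteny_ok, cluster1_span, cluster2_span (0-based bp spans),
#'   variable_region_gene_count (ORFs strictly between the clusters; NA when
#'   either cluster is absent).
#' @export
check_synteny <- function(hit_table, model = synteny_model(), orfs = NULL,
                          circular = FALSE) {
  ht <- hit_table[order(hit_table$start), , drop = FALSE]
  markers <- ht$marker
  n <- length(markers)
  ok <- FALSE
  if (n > 0L) {
    orientations <- list(seq_len(n), rev(seq_len(n)))
    rotations <- if (isTRUE(circular)) seq_len(n) else 1L
    for (ori in orientations) {
      for (r in rotations) {
        idx <- ori[((seq_len(n) + r - 2L) %% n) + 1L]
        if (.synteny_linear(markers[idx], model)) { ok <- TRUE; break }
      }
      if (ok) break
    }
  }
  h1 <- ht[ht$marker %in% model$cluster1, , drop = FALSE]
  h2 <- ht[ht$marker %in% model$cluster2, , drop = FALSE]
  span1 <- if (nrow(h1)) c(min(h1$start), max(h1$end)) else NULL
  span2 <- if (nrow(h2)) c(min(h2$start), max(h2$end)) else NULL
  vr <- NA_integer_
  if (!is.null(orfs) && nrow(h1) && nrow(h2)) {
    i1 <- range(h1$orf_index); i2 <- range(h2$orf_index)
    if (i1[[2L]] < i2[[1L]]) {
      vr <- i2[[1L]] - i1[[2L]] - 1L
    } else if (i2[[2L]] < i1[[1L]]) {
      vr <- i1[[1L]] - i2[[2L]] - 1L
    } else if (isTRUE(circular)) {
      # clusters wrap the origin: count from the last cluster-1 ORF to the
      # first cluster-2 ORF going forward with wrap-around
      vr <- (i2[[1L]] - i1[[2L]] - 1L) %% nrow(orfs)
    }
  }
  list(synteny_ok = ok, cluster1_span = span1, cluster2_span = span2,
       variable_region_gene_count = vr)
}

#' Extract the core region and flanking genes of a called element
#'
#' The core span runs from the first cluster-1 hit to the last cluster-2 hit
#' (positionally), extended by `flank_genes` ORFs on each side (truncated at
#' the ends of linear contigs, wrapped on circular contigs).
#'
#' @param call An `element_call` with spans filled (see [detect_elements()]).
#' @param ct The [contig()].
#' @param orfs ORF table of the contig.
#' @param flank_genes Number of flanking ORFs on each side (default 10).
#' @return List: sequence (core nucleotide sequence), span (0-based,
#'   half-open; end may exceed contig length when the core wraps a circular
#'   origin), core_orfs, flank_upstream, flank_downstream (ORF tables).
#' @export
extract_core_region <- function(call, ct, orfs, flank_genes = 10L) {
  if (call$status == "negative") stop("cannot extract core region of a negative call")
  if (is.null(call$cluster1_span) && is.null(call$cluster2_span)) {
    stop("element call has neither cluster span")
  }
  spans <- rbind(call$cluster1_span, call$cluster2_span)
  n <- nchar(ct$sequence)
  wrap <- FALSE
  if (!is.null(call$cluster1_span) && !is.null(call$cluster2_span) &&
      isTRUE(ct$circular) &&
      call$cluster2_span[[2L]] < call$cluster1_span[[1L]]) {
    # core crosses the origin of a circular contig
    wrap <- TRUE
    lo <- call$cluster1_span[[1L]]
    hi <- call$cluster2_span[[2L]] + n
  } else {
    lo <- min(spans[, 1L]); hi <- max(spans[, 2L])
  }
  pos_mid <- function(o) (o$start + o$end) / 2
  omid <- pos_mid(orfs)
  if (wrap) omid <- ifelse(omid < lo - n / 2 + 0, omid + n, omid)
  inside <- omid >= lo & omid <= hi
  before <- which(!inside & omid < lo)
  after  <- which(!inside & omid > hi)
  before <- before[order(omid[before])]
  after  <- after[order(omid[after])]
  up <- utils::tail(before, flank_genes)
  dn <- utils::head(after, flank_genes)
  ext_lo <- if (length(up)) min(c(lo, omid[up] - (orfs$end[up] - orfs$start[up]) / 2)) else lo
  ext_hi <- if (length(dn)) max(c(hi, omid[dn] + (orfs$end[dn] - orfs$start[dn]) / 2)) else hi
  ext_lo <- max(0, floor(ext_lo))
  ext_hi <- min(if (wrap) lo + n - 1 else n, ceiling(ext_hi))
  s2 <- paste0(ct$sequence, ct$sequence)
  seqn <- substr(s2, ext_lo + 1L, ext_hi)
  list(sequence = seqn, span = c(ext_lo, ext_hi),
       core_span = c(lo, hi), wrapped = wrap,
       core_orfs = orfs[inside, , drop = FALSE],
       flank_upstream = orfs[up, , drop = FALSE],
       flank_downstream = orfs[dn, , drop = FALSE])
}

#' Run marker detection over a set of contigs
#'
#' Calls ORFs (unless supplied), scans them with the six marker profiles,
#' classifies every contig, checks synteny and fills cluster/core spans.
#'
#' @param contigs List of [contig()]s.
#' @param profiles List of profiles (named by marker).
#' @param orf_table Optional pre-computed ORF table for all contigs.
#' @param model A [synteny_model()].
#' @param min_protein_len ORF caller threshold.
#' @param ... Passed to [classify_contig()].
#' @return List with `calls` (list of element_call), `calls_table` (data
#'   frame summary), `hits` (combined marker hit table), `orfs`.
#' @export
detect_elements <- function(contigs, profiles, orf_table = NULL,
                            model = synteny_model(), min_protein_len = 60L,
                            ...) {
  calls <- list(); hits_all <- list(); orfs_all <- list()
  for (ct in contigs) {
    orfs <- if (is.null(orf_table)) find_orfs(ct, min_protein_len) else
      orf_table[orf_table$contig_id == ct$id, , drop = FALSE]
    ht <- scan_contig(orfs, profiles)
    call <- classify_contig(ht, ct, ...)
    if (call$status != "negative") {
      # reading orientation of the element on the contig (majority strand)
      call$strand <- if (nrow(ht) && mean(ht$strand == "-") > 0.5) "-" else "+"
      syn <- check_synteny(ht, model, orfs, circular = isTRUE(ct$circular))
      call$synteny_ok <- syn$synteny_ok
      call$cluster1_span <- syn$cluster1_span
      call$cluster2_span <- syn$cluster2_span
      call$variable_region_gene_count <- syn$variable_region_gene_count
      if (!is.null(syn$cluster1_span) || !is.null(syn$cluster2_span)) {
        sp <- rbind(syn$cluster1_span, syn$cluster2_span)
        call$core_span <- c(min(sp[, 1L]), max(sp[, 2L]))
      }
    }
    calls[[ct$id]] <- call
    hits_all[[ct$id]] <- ht
    orfs_all[[ct$id]] <- orfs
  }
  tb <- do.call(rbind, lapply(calls, function(x) data.frame(
    contig_id = x$contig_id, status = x$status,
    n_markers = x$n_distinct_markers, length = x$contig_length,
    synteny_ok = x$synteny_ok,
    variable_region_genes = x$variable_region_gene_count,
    stringsAsFactors = FALSE)))
  rownames(tb) <- NULL
  list(calls = calls, calls_table = tb,
       hits = do.call(rbind, hits_all), orfs = do.call(rbind, orfs_all))
}
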