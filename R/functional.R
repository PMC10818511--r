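#' Per-category COG relative abundance of one gene set
#'
#' Counts unique (gene, category) assignments per one-letter COG category and
#' normalizes by the set's total number of assignments:
#' `rel(set)_cat = n_cat / n_tot(set)`. A gene carrying several categories
#' contributes one count to each.
#'
#' @param table Data frame with columns gene_id, set_label, categories
#'   (comma-separated one-letter codes, or a list column).
#' @param set_label Which set to profile.
#' @param universe Optional category universe (character vector); categories
#'   absent from the set get rel = 0.
#' @return A `cog_profile`: list with set_label, n_c (named counts), n_tot,
#'   rel (named fractions).
#' @export
cog_relative_abundance <- function(table, set_label, universe = NULL) {
  rows <- table[table$set_label == set_label, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no genes with set_label '", set_label, "'")
  cats <- rows$categories
  if (!is.list(cats)) cats <- strsplit(as.character(cats), "[,;]\\s*")
  pairs <- unique(data.frame(
    gene = rep(rows$gene_id, lengths(cats)),
    cat = unlist(cats), stringsAsFactors = FALSE))
  if (is.null(universe)) universe <- sort(unique(pairs$cat))
  n_c <- table(factor(pairs$cat, levels = universe))
  n_c <- stats::setNames(as.integer(n_c), universe)
  n_tot <- sum(n_c)
  structure(list(set_label = set_label, n_c = n_c, n_tot = n_tot,
                 rel = n_c / n_tot),
            class = "cog_profile")
}

#' Difference in COG relative abundance between two gene sets
#'
#' `delta_rel_cat = rel(query) - rel(reference)` over the union of the two
#' category universes (missing categories count as 0). Positive values mean
#' the category is enriched in the query set.
#'
#' @param query,reference `cog_profile`s from [cog_relative_abundance()].
#' @return Named numeric vector of signed differences (sums to 0 over the
#'   shared universe).
#' @export
cog_delta <- function(query, reference) {
  universe <- sort(union(names(query$rel), names(reference$rel)))
  q <- stats::setNames(rep(0, length(universe)), universe)
  r <- q
  q[names(query$rel)] <- query$rel
  r[names(reference$rel)] <- reference$rel
  q - r
}

#' Match CRISPR spacers against target sequences
#'
#' Full-length ungapped alignment of each spacer at every position of each
#' target, both strands; identity is matches over the spacer length. Only
#' matches with identity strictly above `min_identity` and length strictly
#' above `min_len` are reported ("> 97% identity and length > 30").
#'
#' @param spacers Named character vector of spacer sequences.
#' @param targets List of [contig()]s (e.g. extracted core regions) or a
#'   named character vector.
#' @param min_identity Strict identity threshold (default 0.97).
#' @param min_len Strict length threshold in nt (default 30).
#' @return Data frame (spacer_id, target_contig, start, end, identity,
#'   match_length, strand), 0-based half-open, ordered by target then start.
#' @export
match_spacers <- function(spacers, targets, min_identity = 0.97,
                          min_len = 30L) {
  if (is.list(targets) && length(targets) && inherits(targets[[1L]], "contig")) {
    tv <- vapply(targets, `[[`, "", "sequence")
    names(tv) <- vapply(targets, `[[`, "", "id")
    targets <- tv
  }
  stopifnot(!is.null(names(spacers)), !is.null(names(targets)))
  rows <- list()
  for (si in seq_along(spacers)) {
    sp <- toupper(spacers[[si]])
    len <- nchar(sp)
    if (len <= min_len) next
    # largest mismatch count m with (len - m) / len > min_identity
    mm_max <- 0L
    while ((len - (mm_max + 1L)) / len > min_identity) mm_max <- mm_max + 1L
    for (ti in seq_along(targets)) {
      tgt <- Biostrings::DNAString(targets[[ti]])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else revcomp_dna(sp)
        m <- Biostrings::matchPattern(pat, tgt, max.mismatch = mm_max,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        nmis <- vapply(seq_along(m), function(k) {
          Biostrings::neditStartingAt(pat, tgt, starting.at =
                                        Biostrings::start(m)[[k]])
        }, numeric(1L))
        for (k in seq_along(m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = names(spacers)[[si]],
            target_contig = names(targets)[[ti]],
            start = Biostrings::start(m)[[k]] - 1L,
            end = Biostrings::end(m)[[k]],
            identity = (len - nmis[[k]]) / len,
            match_length = len, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer_id = character(), target_contig = character(),
                      start = integer(), end = integer(), identity = numeric(),
                      match_length = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[out$identity > min_identity, , drop = FALSE]
  out <- out[order(out$target_contig, out$start, out$spacer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plasmid counts normalized per genome count, by taxon class
#'
#' @param plasmid_counts Named numeric vector: class to plasmid count.
#' @param genome_counts Named numeric vector: class to genome count (must be
#'   strictly positive for every reported class).
#' @return Named numeric vector of ratios over the shared classes; classes
#'   missing from either input are omitted with a warning.
#' @export
plasmids_per_genome <- function(plasmid_counts, genome_counts) {
  shared <- intersect(names(plasmid_counts), names(genome_counts))
  missing <- setdiff(union(names(plasmid_counts), names(genome_counts)), shared)
  if (length(missing)) {
    warning("class(es) missing from one input omitted: ",
            paste(missing, collapse = ", "))
  }
  bad <- shared[genome_counts[shared] <= 0]
  if (length(bad)) stop("zero genome count for class: ", paste(bad, collapse = ", "))
  plasmid_counts[shared] / genome_counts[shared]
}
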