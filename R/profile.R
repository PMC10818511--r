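#' Seed alignment constructor
#'
#' A named multiple alignment of one marker protein family. Rows are equal
#' width over the 20 amino acids, X and `-`; all-gap columns are dropped on
#' construction.
#'
#' @param name Marker label (e.g. "ORF6").
#' @param ids Character vector of sequence ids.
#' @param rows Aligned amino-acid strings (with `-` gaps), one per id.
#' @return An object of class `seed_alignment`.
#' @export
seed_alignment <- function(name, ids, rows) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1L)
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("aligned rows must all have the same width")
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(mat != "-") > 0L
  mat <- mat[, keep, drop = FALSE]
  structure(list(name = name, ids = as.character(ids),
                 rows = apply(mat, 1L, paste, collapse = "")),
            class = "seed_alignment")
}

#' Read a seed alignment from aligned FASTA
#' @param path Aligned FASTA path.
#' @param name Marker label; defaults to the file name without extension.
#' @return A [seed_alignment()].
#' @export
read_seed_alignment <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment: ", path)
  seed_alignment(name, sub("\\s.*$", "", names(set)), as.character(set))
}

.aln_matrix <- function(aln) do.call(rbind, strsplit(aln$rows, ""))

#' Build a profile HMM from a seed alignment
#'
#' Alignment columns whose gap fraction does not exceed `gap_fraction_max`
#' become match states; the remaining columns are treated as insertions.
#' Match emissions are pseudocount-smoothed residue counts; transition
#' probabilities for \{M,I,D\} are estimated from the observed state paths of
#' the rows with the same pseudocount. Insert states emit the background, so
#' insertions cost transitions only.
#'
#' @param aln A [seed_alignment()].
#' @param gap_fraction_max Maximum column gap fraction for a match state.
#' @param pseudocount Laplace-style pseudocount added per amino acid and per
#'   transition.
#' @param background Length-20 probability vector, `"from-alignment"`
#'   (frequencies of the alignment residues) or `"uniform"`.
#' @param score_threshold Reporting threshold in bits (default 50).
#' @param coverage_threshold Minimum fraction of match states aligned.
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(aln, gap_fraction_max = 0.5, pseudocount = 0.1,
                          background = "from-alignment",
                          score_threshold = 50, coverage_threshold = 0.7) {
  stopifnot(inherits(aln, "seed_alignment"))
  mat <- .aln_matrix(aln)
  nr <- nrow(mat)
  gapfrac <- colSums(mat == "-") / nr
  match_cols <- which(gapfrac <= gap_fraction_max)
  L <- length(match_cols)
  if (L == 0L) stop("alignment '", aln$name, "' has no retained match columns")

  if (identical(background, "from-alignment")) {
    res <- mat[mat %in% AA20]
    if (!length(res)) {
      bg <- aa_background_default()
    } else {
      cnt <- table(factor(res, levels = AA20))
      bg <- (as.numeric(cnt) + pseudocount) / (length(res) + 20 * pseudocount)
      names(bg) <- AA20
    }
  } else if (identical(background, "uniform")) {
    bg <- stats::setNames(rep(1 / 20, 20), AA20)
  } else {
    stopifnot(is.numeric(background), length(background) == 20L,
              all(background > 0))
    bg <- background / sum(background)
    names(bg) <- AA20
  }

  em <- matrix(pseudocount, nrow = L, ncol = 20,
               dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- mat[, match_cols[[k]]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    em[k, ] <- em[k, ] + as.numeric(cnt)
  }
  em <- em / rowSums(em)

  # state paths: match column + residue -> M, match column + gap -> D;
  # residues in non-match columns between match columns k and k+1 -> I_k.
  # The architecture has no D-I adjacency; insert runs bordered by a delete
  # are credited to the delete's direct transition instead.
  begin_cnt <- c(M = pseudocount, D = pseudocount)
  if (L >= 2L) {
    mm <- rep(pseudocount, L - 1L); mi <- mm; md <- mm
    im <- rep(pseudocount, L - 1L); ii <- im
    dm <- rep(pseudocount, L - 1L); dd <- dm
  } else {
    mm <- mi <- md <- im <- ii <- dm <- dd <- numeric(0)
  }
  is_match <- logical(ncol(mat)); is_match[match_cols] <- TRUE
  for (r in seq_len(nr)) {
    row <- mat[r, ]
    st <- ifelse(row[match_cols] == "-", "D", "M")
    begin_cnt[[st[[1L]]]] <- begin_cnt[[st[[1L]]]] + 1
    if (L >= 2L) {
      for (k in seq_len(L - 1L)) {
        between <- if (match_cols[[k + 1L]] - match_cols[[k]] > 1L)
          row[(match_cols[[k]] + 1L):(match_cols[[k + 1L]] - 1L)] else character(0)
        nins <- sum(between != "-")
        a <- st[[k]]; b <- st[[k + 1L]]
        if (nins > 0L && a == "M" && b == "M") {
          mi[[k]] <- mi[[k]] + 1
          ii[[k]] <- ii[[k]] + (nins - 1L)
          im[[k]] <- im[[k]] + 1
        } else {
          if (a == "M" && b == "M") mm[[k]] <- mm[[k]] + 1
          if (a == "M" && b == "D") md[[k]] <- md[[k]] + 1
          if (a == "D" && b == "M") dm[[k]] <- dm[[k]] + 1
          if (a == "D" && b == "D") dd[[k]] <- dd[[k]] + 1
        }
      }
    }
  }
  trans <- list(
    begin = begin_cnt / sum(begin_cnt),
    mm = mm / (mm + mi + md), mi = mi / (mm + mi + md), md = md / (mm + mi + md),
    im = im / (im + ii), ii = ii / (im + ii),
    dm = dm / (dm + dd), dd = dd / (dm + dd))

  pf <- structure(list(name = aln$name, L = L, match_emissions = em,
                       insert_emissions = bg, background = bg,
                       transitions = trans,
                       score_threshold = score_threshold,
                       coverage_threshold = coverage_threshold),
                  class = "profile_hmm")
  .profile_precompute(pf)
}

# cache the log-odds emission matrix and log2 transitions used by the scorer
.profile_precompute <- function(pf) {
  tr <- pf$transitions
  pf$lodds <- cbind(log2(sweep(pf$match_emissions, 2L, pf$background, "/")),
                    X = 0)
  pf$ltrans <- list(bm = log2(tr$begin[["M"]]), bd = log2(tr$begin[["D"]]),
                    mm = log2(tr$mm), mi = log2(tr$mi), md = log2(tr$md),
                    im = log2(tr$im), ii = log2(tr$ii),
                    dm = log2(tr$dm), dd = log2(tr$dd))
  pf
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm %s: L=%d, score>=%.1f bits, coverage>=%.2f>\n",
              x$name, x$L, x$score_threshold, x$coverage_threshold))
  invisible(x)
}

.encode_protein <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1L]]
  idx <- match(chars, AA20)
  idx[is.na(idx)] <- 21L     # X and anything non-standard: background column
  idx - 1L
}


#' Score a protein against a profile (glocal Viterbi)
#'
#' Maximum log2-odds path score in bits over a glocal alignment: the full
#' profile is traversed, the alignment is local in the sequence. Residues
#' outside the 20-letter alphabet are scored as background. Ties prefer match
#' over delete over insert states, making the traceback deterministic.
#'
#' @param profile A [build_profile()] result.
#' @param protein Amino-acid string.
#' @param sequence_id Optional id recorded in the hit.
#' @return A `profile_hit`: list with profile_name, sequence_id, bitscore,
#'   coverage, aligned_row (match-state projection, width L), n_insert and the
#'   left/right unaligned overhangs in residues.
#' @export
viterbi_score <- function(profile, protein, sequence_id = NA_character_) {
  stopifnot(inherits(profile, "profile_hmm"), nzchar(protein))
  if (is.null(profile$lodds)) profile <- .profile_precompute(profile)
  lt <- profile$ltrans
  res <- viterbi_glocal_cpp(
    profile$lodds, .encode_protein(protein),
    lt$bm, lt$bd, lt$mm, lt$mi, lt$md, lt$im, lt$ii, lt$dm, lt$dd)
  chars <- strsplit(toupper(protein), "")[[1L]]
  row <- ifelse(res$emit > 0L, chars[pmax(res$emit, 1L)], "-")
  n_match <- sum(res$emit > 0L)
  n <- length(chars)
  structure(list(
    profile_name = profile$name, sequence_id = sequence_id,
    bitscore = res$score, coverage = n_match / profile$L,
    aligned_row = paste(row, collapse = ""),
    n_insert = res$n_insert,
    first_emit = res$first_emit, last_emit = res$last_emit,
    overhang_left = if (n_match) res$first_emit - 1L else 0L,
    overhang_right = if (n_match) n - res$last_emit else n),
    class = "profile_hit")
}

#' Project a protein onto a profile's match states
#'
#' Returns the match-column projection of the optimal Viterbi path: a string
#' of width L over amino acids and `-` (deleted match states). Stacking
#' projections of several members yields a rectangular alignment.
#'
#' @inheritParams viterbi_score
#' @return Character scalar of width `profile$L`.
#' @export
align_to_profile <- function(profile, protein) {
  viterbi_score(profile, protein)$aligned_row
}

#' Search a protein database with a profile
#'
#' @param profile A [build_profile()] result carrying thresholds.
#' @param db Named character vector: ids to protein sequences.
#' @param blacklist Character vector of ids to exclude.
#' @return Data frame (profile_name, sequence_id, bitscore, coverage,
#'   aligned_row, n_insert, overhang) of hits passing both thresholds, sorted
#'   by bitscore descending then id ascending.
#' @export
search_database <- function(profile, db, blacklist = character(0)) {
  stopifnot(inherits(profile, "profile_hmm"), !is.null(names(db)))
  keep <- !(names(db) %in% blacklist)
  ids <- names(db)[keep]
  rows <- list()
  for (id in ids) {
    p <- db[[id]]
    # a sequence shorter than coverage_threshold * L cannot pass coverage
    if (nchar(p) < profile$coverage_threshold * profile$L) next
    h <- viterbi_score(profile, p, sequence_id = id)
    if (h$bitscore >= profile$score_threshold &&
        h$coverage >= profile$coverage_threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        profile_name = profile$name, sequence_id = id,
        bitscore = h$bitscore, coverage = h$coverage,
        aligned_row = h$aligned_row, n_insert = h$n_insert,
        overhang = h$overhang_left + h$overhang_right,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(profile_name = character(), sequence_id = character(),
                      bitscore = numeric(), coverage = numeric(),
                      aligned_row = character(), n_insert = integer(),
                      overhang = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$bitscore, out$sequence_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative profile refinement with an accession blacklist
#'
#' Implements the iterative recruit-and-rebuild loop: build a profile from the
#' current member alignment, search the database, project new hits onto the
#' profile, apply automated trimming rules, and rebuild, until an iteration
#' adds no members or `max_iter` is reached. A candidate is blacklisted (and
#' never re-admitted) when its unaligned overhang beyond the profile ends
#' exceeds `overhang_max * L` or its inserted (non-match) residues exceed
#' `gap_insert_max * L`; these quantitative rules stand in for visual
#' alignment curation.
#'
#' @param seed A [seed_alignment()].
#' @param db Named character vector of proteins.
#' @param max_iter Maximum refinement iterations.
#' @param overhang_max,gap_insert_max Trimming-rule fractions of L.
#' @param ... Passed to [build_profile()] (thresholds, pseudocount,
#'   background, gap_fraction_max).
#' @return List with `profile` (final), `member_ids`, `blacklist`,
#'   `alignment` (the final [seed_alignment()]) and `n_iter`.
#' @export
refine_profile <- function(seed, db, max_iter = 10L,
                           overhang_max = 0.30, gap_insert_max = 0.30, ...) {
  stopifnot(inherits(seed, "seed_alignment"), max_iter >= 1L)
  profile <- build_profile(seed, ...)
  # re-express the alignment on the profile's match columns (width L)
  dots <- list(...)
  gfm <- if (is.null(dots$gap_fraction_max)) 0.5 else dots$gap_fraction_max
  mat <- .aln_matrix(seed)
  gapfrac <- colSums(mat == "-") / nrow(mat)
  keep <- gapfrac <= gfm
  member_ids <- seed$ids
  member_rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  blacklist <- character(0)
  n_iter <- 0L
  if (length(db)) {
    for (it in seq_len(max_iter)) {
      n_iter <- it
      aln <- seed_alignment(seed$name, member_ids, member_rows)
      profile <- build_profile(aln, ...)
      hits <- search_database(profile, db, blacklist = c(blacklist, member_ids))
      added <- 0L
      for (i in seq_len(nrow(hits))) {
        id <- hits$sequence_id[[i]]
        if (hits$overhang[[i]] > overhang_max * profile$L ||
            hits$n_insert[[i]] > gap_insert_max * profile$L) {
          blacklist <- union(blacklist, id)
        } else {
          member_ids <- c(member_ids, id)
          member_rows <- c(member_rows, hits$aligned_row[[i]])
          added <- added + 1L
        }
      }
      if (added == 0L) break
    }
    aln <- seed_alignment(seed$name, member_ids, member_rows)
    profile <- build_profile(aln, ...)
  } else {
    aln <- seed_alignment(seed$name, member_ids, member_rows)
  }
  list(profile = profile, member_ids = member_ids, blacklist = blacklist,
       alignment = aln, n_iter = n_iter)
}

#' Serialize a profile to a tab-delimited text file
#' @param profile A `profile_hmm`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("profile\t%s\t%d\t%.6g\t%.6g", profile$name, profile$L,
                     profile$score_threshold, profile$coverage_threshold), con)
  writeLines(paste(c("background", sprintf("%.8g", profile$background)),
                   collapse = "\t"), con)
  writeLines(paste(c("begin", sprintf("%.8g", profile$transitions$begin)),
                   collapse = "\t"), con)
  for (k in seq_len(profile$L)) {
    writeLines(paste(c(sprintf("emission\t%d", k),
                       sprintf("%.8g", profile$match_emissions[k, ])),
                     collapse = "\t"), con)
  }
  tr <- profile$transitions
  for (k in seq_len(max(profile$L - 1L, 0L))) {
    writeLines(sprintf("transition\t%d\t%.8g\t%.8g\t%.8g\t%.8g\t%.8g\t%.8g\t%.8g",
                       k, tr$mm[[k]], tr$mi[[k]], tr$md[[k]],
                       tr$im[[k]], tr$ii[[k]], tr$dm[[k]], tr$dd[[k]]), con)
  }
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path Profile text file.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  hd <- parts[[1L]]
  stopifnot(hd[[1L]] == "profile")
  L <- as.integer(hd[[3L]])
  bg <- stats::setNames(as.numeric(parts[[2L]][-1L]), AA20)
  begin <- stats::setNames(as.numeric(parts[[3L]][-1L]), c("M", "D"))
  em <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA20))
  tr <- matrix(NA_real_, max(L - 1L, 0L), 7)
  for (p in parts[-(1:3)]) {
    if (p[[1L]] == "emission") {
      em[as.integer(p[[2L]]), ] <- as.numeric(p[-(1:2)])
    } else if (p[[1L]] == "transition") {
      tr[as.integer(p[[2L]]), ] <- as.numeric(p[-(1:2)])
    }
  }
  structure(list(name = hd[[2L]], L = L, match_emissions = em,
                 insert_emissions = bg, background = bg,
                 transitions = list(begin = begin,
                                    mm = tr[, 1L], mi = tr[, 2L], md = tr[, 3L],
                                    im = tr[, 4L], ii = tr[, 5L],
                                    dm = tr[, 6L], dd = tr[, 7L]),
                 score_threshold = as.numeric(hd[[4L]]),
                 coverage_threshold = as.numeric(hd[[5L]])),
            class = "profile_hmm")
}
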