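#' Contig constructor
#'
#' A contig is a nucleotide sequence record with an identifier, a provenance
#' label and an (initially unknown) circularity flag. Sequences are restricted
#' to the alphabet A, C, G, T, N; U is mapped to T and any other IUPAC
#' ambiguity code is collapsed to N on input.
#'
#' @param id Character scalar, unique within a run.
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @param source Free-text provenance label (file or sample name).
#' @param circular Logical or NA; NA until circularity has been tested.
#' @return An object of class `contig`.
#' @export
contig <- function(id, sequence, source = "", circular = NA) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("contig '", id, "': empty sequence")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("contig '", id, "': non-ACGTN character '",
         substr(sequence, bad, bad), "' at position ", bad)
  }
  structure(list(id = id, sequence = sequence, source = source,
                 circular = circular),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s: %d bp, circular=%s, source=%s>\n",
              x$id, nchar(x$sequence), as.character(x$circular), x$source))
  invisible(x)
}

normalize_nt <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  # collapse IUPAC ambiguity codes (other than N) to N
  gsub("[RYSWKMBDHV]", "N", x)
}

#' Read nucleotide contigs from a FASTA file
#'
#' Headers are truncated at the first whitespace to form the contig id.
#' Sequences are upper-cased, U is mapped to T, and IUPAC ambiguity codes are
#' collapsed to N. Duplicate ids and non-IUPAC characters are errors.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance label stored on each contig (defaults to the file
#'   name).
#' @return A list of [contig()] objects.
#' @export
read_fasta <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: '", dup[[1L]], "'")
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTUNRYSWKMBDHV]", seqs[[i]])
    if (bad > 0L) {
      stop("record '", ids[[i]], "': non-IUPAC character '",
           substr(seqs[[i]], bad, bad), "' at position ", bad)
    }
  }
  mapply(function(id, s) contig(id, normalize_nt(s), source = source),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a list of [contig()]s.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1L]], "contig")) {
    v <- vapply(seqs, function(ct) ct$sequence, character(1L))
    names(v) <- vapply(seqs, function(ct) ct$id, character(1L))
    seqs <- v
  }
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read externally supplied gene calls
#'
#' Accepts a TSV with columns contig_id, start, end, strand (and optionally
#' orf_index); coordinates 0-based half-open on the forward strand. Proteins
#' are re-translated from the contig slice.
#'
#' @param path TSV path.
#' @param contigs List of contigs the calls refer to.
#' @return ORF table as returned by [find_orfs()].
#' @export
read_gene_calls <- function(path, contigs) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "start", "end", "strand")
  if (!all(need %in% names(tb))) {
    stop("gene-call TSV must have columns: ", paste(need, collapse = ", "))
  }
  byid <- stats::setNames(contigs, vapply(contigs, `[[`, "", "id"))
  out <- lapply(seq_len(nrow(tb)), function(i) {
    ct <- byid[[tb$contig_id[[i]]]]
    if (is.null(ct)) stop("gene call references unknown contig: ", tb$contig_id[[i]])
    s <- tb$start[[i]]; e <- tb$end[[i]]
    slice <- substr(ct$sequence, s + 1L, e)
    if (tb$strand[[i]] == "-") slice <- revcomp_dna(slice)
    aa <- translate_dna(slice)
    data.frame(contig_id = ct$id, start = s, end = e, strand = tb$strand[[i]],
               frame = s %% 3L, protein = sub("\\*$", "", aa),
               stringsAsFactors = FALSE)
  })
  orfs <- do.call(rbind, out)
  orfs <- orfs[order(orfs$contig_id, orfs$start, orfs$end), , drop = FALSE]
  orfs$orf_index <- stats::ave(orfs$start, orfs$contig_id,
                               FUN = seq_along)
  rownames(orfs) <- NULL
  orfs
}

#' Export an ORF table as GFF3 (1-based, inclusive coordinates)
#'
#' @param orfs ORF table from [find_orfs()].
#' @param path Output path.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    lines <- sprintf("%s\tapvhunter\tCDS\t%d\t%d\t.\t%s\t0\tID=%s_orf%d",
                     orfs$contig_id, orfs$start + 1L, orfs$end, orfs$strand,
                     orfs$contig_id, orfs$orf_index)
    writeLines(lines, con)
  }
  invisible(path)
}
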