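# Internal alphabets and lookup tables shared across modules.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.pkg_cache <- new.env(parent = emptyenv())

# Translation table 11 (bacteria/archaea); identical to the standard code at the
# codon->residue level, start-codon permissiveness is handled by the ORF caller.
codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    .pkg_cache$codons <- Biostrings::getGeneticCode("11")
  }
  .pkg_cache$codons
}

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

# Background amino-acid frequencies (Robinson-Robinson style), used when no
# database is supplied to estimate a background from.
aa_background_default <- function() {
  f <- c(A = 0.0787, C = 0.0151, D = 0.0535, E = 0.0668, F = 0.0397,
         G = 0.0695, H = 0.0229, I = 0.0590, K = 0.0594, L = 0.0963,
         M = 0.0238, N = 0.0414, P = 0.0484, Q = 0.0396, R = 0.0540,
         S = 0.0683, T = 0.0541, V = 0.0673, W = 0.0114, Y = 0.0308)
  f[AA20] / sum(f)
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

rand_string <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
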