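# Synthetic-data generator: produces every input the pipeline consumes, with
# machine-readable ground truth, emulating haloarchaeal contigs that carry a
# planted two-cluster core region.

#' Generator configuration
#'
#' Defaults define the benchmark conditions: 20 complete elements, 20
#' single-cluster fragments, 60 decoys; marker homologs mutated to 45-75%
#' identity; a 3-11 gene variable region; half of the element contigs
#' circular with 40 bp terminal repeats; 30 bp origin repeats; GC drawn from
#' the 57.6-64.8% band.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_complete,n_incomplete,n_decoys Contig counts.
#' @param contig_len_range Decoy/padding contig length range (bp).
#' @param marker_identity_range Target amino-acid identity of planted marker
#'   homologs relative to the seed parents.
#' @param variable_region_genes Integer interval for the inter-cluster gene
#'   count.
#' @param circular_fraction Fraction of element contigs built circular.
#' @param ori_repeat_len Planted origin-repeat unit length (bp).
#' @param terminal_repeat_len Terminal repeat length on circular contigs.
#' @param gc_range GC-content interval for back-translation.
#' @param pangenome Planted pangenome dimensions (n_genomes and cluster
#'   counts per band).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_complete = 20L, n_incomplete = 20L,
                             n_decoys = 60L,
                             contig_len_range = c(12000L, 20000L),
                             marker_identity_range = c(0.45, 0.75),
                             variable_region_genes = c(3L, 11L),
                             circular_fraction = 0.5,
                             ori_repeat_len = 30L,
                             terminal_repeat_len = 40L,
                             gc_range = c(0.576, 0.648),
                             pangenome = list(n_genomes = 41L, n_core = 10L,
                                              n_shell = 8L, n_cloud = 20L,
                                              n_rare = 3L)) {
  stopifnot(contig_len_range[1L] <= contig_len_range[2L],
            marker_identity_range[1L] > 0, marker_identity_range[2L] <= 1,
            variable_region_genes[1L] <= variable_region_genes[2L],
            circular_fraction >= 0, circular_fraction <= 1,
            gc_range[1L] <= gc_range[2L])
  structure(as.list(environment()), class = "generator_config")
}

# run expr under a fixed private seed without disturbing the caller's stream
.with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

MARKER_LENGTHS <- c(ORF6 = 280L, ORF7 = 150L, ORF8 = 200L, ORF9 = 170L,
                    ORF17 = 190L, ORF21 = 140L, ORF23 = 210L, ORF24 = 160L,
                    ORF25 = 240L)

.random_protein <- function(len) {
  paste0("M", rand_string(len - 1L, AA20, prob = aa_background_default()))
}

#' Bundled synthetic marker seed proteins
#'
#' Deterministic synthetic stand-ins for the nine core-region marker proteins
#' (lengths roughly echoing the real ORF sizes); these are generated, not
#' copied from any database.
#'
#' @return Named character vector of parent proteins.
#' @export
toy_seed_proteins <- function() {
  if (is.null(.pkg_cache$toy_parents)) {
    .pkg_cache$toy_parents <- .with_private_seed(20231219L, {
      vapply(MARKER_LENGTHS, .random_protein, character(1L))
    })
  }
  .pkg_cache$toy_parents
}

#' Bundled synthetic seed alignments for the six searched markers
#'
#' Four homologs per marker (the parent plus three species homologs at about
#' 65% identity), substitution-only, hence trivially aligned.
#'
#' @return Named list of [seed_alignment()]s for ORF6, ORF8, ORF17, ORF21,
#'   ORF23, ORF24.
#' @export
toy_seed_alignments <- function() {
  if (is.null(.pkg_cache$toy_seeds)) {
    parents <- toy_seed_proteins()
    .pkg_cache$toy_seeds <- .with_private_seed(3141593L, {
      out <- list()
      for (mk in MARKERS6) {
        rows <- c(parents[[mk]],
                  vapply(1:3, function(i)
                    mutate_protein(parents[[mk]], 0.65), character(1L)))
        out[[mk]] <- seed_alignment(
          mk, paste0(c("pR1SE", "Hsac", "Htur", "Hxan"), "_", mk), rows)
      }
      out
    })
  }
  .pkg_cache$toy_seeds
}

#' Mutate a protein to a target ungapped identity
#'
#' Substitutes residues at `ceiling((1 - target_identity) * len)` positions
#' (never the initial methionine), choosing replacements with
#' BLOSUM62-biased probabilities; optional short indels. The realized
#' ungapped identity equals `1 - n_sub / len` exactly when `indel_prob = 0`.
#'
#' @param seq Protein string.
#' @param target_identity Fraction in (0, 1].
#' @param indel_prob Per-sequence probability of one short (1-3 aa) indel.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(seq, target_identity, indel_prob = 0) {
  stopifnot(target_identity > 0, target_identity <= 1)
  chars <- strsplit(seq, "")[[1L]]
  len <- length(chars)
  n_sub <- min(ceiling((1 - target_identity) * len), len - 1L)
  if (n_sub > 0L) {
    pos <- sample(2:len, n_sub)
    B <- blosum62()[AA20, AA20]
    for (p in pos) {
      a <- chars[[p]]
      w <- 2^(B[a, ] / 2)
      w[[a]] <- 0
      chars[[p]] <- sample(AA20, 1L, prob = w)
    }
  }
  if (indel_prob > 0 && stats::runif(1L) < indel_prob) {
    k <- sample(1:3, 1L)
    at <- sample(2:(len - k), 1L)
    if (stats::runif(1L) < 0.5) {
      chars <- append(chars, sample(AA20, k, replace = TRUE,
                                    prob = aa_background_default()), after = at)
    } else {
      chars <- chars[-(at:(at + k - 1L))]
    }
  }
  paste(chars, collapse = "")
}

# reverse codon table: residue -> codon vector (table 11)
.codons_by_aa <- function() {
  if (is.null(.pkg_cache$rev_codons)) {
    ct <- codon_table()
    .pkg_cache$rev_codons <- split(names(ct), ct)
  }
  .pkg_cache$rev_codons
}

# per-residue codon GC counts, cached
.codon_gc_counts <- function() {
  if (is.null(.pkg_cache$codon_gc)) {
    rev <- .codons_by_aa()
    .pkg_cache$codon_gc <- lapply(rev, function(cods)
      vapply(cods, function(cd)
        sum(strsplit(cd, "")[[1L]] %in% c("G", "C")), numeric(1L)))
  }
  .pkg_cache$codon_gc
}

# expected codon GC count per residue on a lambda grid, cached; weights are
# exp(lambda * gc_count)
.gc_lambda_grid <- function() {
  if (is.null(.pkg_cache$gc_grid)) {
    grid <- seq(-8, 8, by = 0.05)
    gcs <- .codon_gc_counts()
    E <- vapply(gcs, function(g)
      vapply(grid, function(l) {
        w <- exp(l * g); sum(w * g) / sum(w)
      }, numeric(1L)), numeric(length(grid)))
    .pkg_cache$gc_grid <- list(grid = grid, E = E)   # |grid| x |residues|
  }
  .pkg_cache$gc_grid
}

# solve the codon-weight exponent so expected GC matches the target, given
# the residue composition of `protein`
.solve_gc_lambda <- function(protein, gc) {
  gg <- .gc_lambda_grid()
  chars <- c(strsplit(protein, "")[[1L]], "*")
  chars[!chars %in% colnames(gg$E)] <- "*"
  comp <- table(chars)
  exp_gc <- as.numeric(gg$E[, names(comp), drop = FALSE] %*% as.numeric(comp)) /
    (3 * sum(comp))
  i <- which.min(abs(exp_gc - gc))
  gg$grid[[i]]
}

#' Back-translate a protein with GC-biased codon choice
#'
#' Codons are drawn with weights `exp(lambda * gc_count)`, with `lambda`
#' calibrated so the expected GC content of the gene matches `gc`. A start
#' codon is not forced (proteins are expected to begin with M, giving ATG)
#' and a stop codon is appended.
#'
#' @param protein Protein string (standard residues; X maps to a random
#'   codon).
#' @param gc Target GC fraction.
#' @return Nucleotide coding sequence including the stop codon.
#' @export
back_translate <- function(protein, gc) {
  rev <- .codons_by_aa()
  gcs <- .codon_gc_counts()
  lambda <- .solve_gc_lambda(protein, gc)
  chars <- c(strsplit(protein, "")[[1L]], "*")
  out <- character(length(chars))
  for (aa in unique(chars)) {
    at <- which(chars == aa)
    cods <- rev[[aa]]
    if (is.null(cods)) {            # X / unknown: any codon
      out[at] <- sample(names(codon_table()), length(at), replace = TRUE)
    } else if (length(cods) == 1L) {
      out[at] <- cods
    } else {
      w <- exp(lambda * gcs[[aa]])
      out[at] <- sample(cods, length(at), replace = TRUE, prob = w)
    }
  }
  paste(out, collapse = "")
}

.random_intergenic <- function(len, gc) {
  if (len <= 0L) return("")
  s <- rand_string(len, c("A", "C", "G", "T"),
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  # avoid stray stop-free start contexts mattering: plain random is fine
  s
}

# assemble genes (named protein list) into DNA with intergenic spacers;
# returns sequence plus a table of gene coordinates (0-based half-open)
.assemble_genes <- function(proteins, gc, intergenic = function() sample(20:80, 1L)) {
  seqs <- character(0)
  rows <- list()
  pos <- 0L
  for (i in seq_along(proteins)) {
    gap <- .random_intergenic(intergenic(), gc)
    seqs <- c(seqs, gap)
    pos <- pos + nchar(gap)
    gene <- back_translate(proteins[[i]], gc)
    rows[[i]] <- data.frame(gene = names(proteins)[[i]], start = pos,
                            end = pos + nchar(gene), stringsAsFactors = FALSE)
    seqs <- c(seqs, gene)
    pos <- pos + nchar(gene)
  }
  tail_gap <- .random_intergenic(intergenic(), gc)
  list(sequence = paste(c(seqs, tail_gap), collapse = ""),
       genes = do.call(rbind, rows))
}

.make_ori_construct <- function(kind, unit_len, gc) {
  unit <- rand_string(unit_len, c("A", "C", "G", "T"),
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  spacer_len <- if (kind == "direct") 0L else sample(50:300, 1L)
  spacer <- .random_intergenic(spacer_len, gc)
  second <- if (kind == "palindromic") revcomp_dna(unit) else unit
  list(sequence = paste0(unit, spacer, second),
       pos2_offset = unit_len + spacer_len, length = unit_len)
}

#' Generate one element-carrying contig with ground truth
#'
#' Builds a contig encoding cluster 1 (ORF6-ORF9), a variable region of
#' 3-11 random genes, cluster 2 (ORF17, ORF21, ORF23-ORF25) and ten flanking
#' genes on each side, back-translated at a GC target drawn from the
#' configured band. Marker proteins are mutants of the bundled seed parents
#' at drawn identities. An origin-like repeat is planted directly before the
#' first cluster or just after the second; circular contigs get terminal
#' repeats. Incomplete variants carry a single cluster.
#'
#' @param cfg A [generator_config()].
#' @param status One of "complete", "incomplete_cluster1",
#'   "incomplete_cluster2".
#' @param id Contig id.
#' @param flank_each Flanking genes per side.
#' @return List: `contig` ([contig()]) and `truth` (one-row data frame).
#' @export
make_element_contig <- function(cfg, status = c("complete",
                                                "incomplete_cluster1",
                                                "incomplete_cluster2"),
                                id = "element_01", flank_each = 10L) {
  status <- match.arg(status)
  parents <- toy_seed_proteins()
  gc <- stats::runif(1L, cfg$gc_range[[1L]], cfg$gc_range[[2L]])

  idents <- stats::setNames(stats::runif(length(MARKERS6),
                                         cfg$marker_identity_range[[1L]],
                                         cfg$marker_identity_range[[2L]]),
                            MARKERS6)
  mut <- function(mk) {
    t <- if (mk %in% MARKERS6) idents[[mk]] else
      stats::runif(1L, cfg$marker_identity_range[[1L]],
                   cfg$marker_identity_range[[2L]])
    mutate_protein(parents[[mk]], t)
  }
  cluster1 <- c("ORF6", "ORF7", "ORF8", "ORF9")
  cluster2 <- c("ORF17", "ORF21", "ORF23", "ORF24", "ORF25")
  k <- sample(cfg$variable_region_genes[[1L]]:cfg$variable_region_genes[[2L]], 1L)

  flank <- function(side, m) {
    p <- lapply(seq_len(m), function(i)
      .random_protein(sample(80:220, 1L)))
    names(p) <- paste0(side, "_", seq_len(m))
    p
  }
  variable <- lapply(seq_len(k), function(i) .random_protein(sample(80:200, 1L)))
  names(variable) <- paste0("var_", seq_len(k))

  genes <- switch(status,
    complete = c(flank("up", flank_each),
                 stats::setNames(lapply(cluster1, mut), cluster1),
                 variable,
                 stats::setNames(lapply(cluster2, mut), cluster2),
                 flank("down", flank_each)),
    incomplete_cluster1 = c(flank("up", flank_each),
                            stats::setNames(lapply(cluster1, mut), cluster1),
                            flank("down", flank_each)),
    incomplete_cluster2 = c(flank("up", flank_each),
                            stats::setNames(lapply(cluster2, mut), cluster2),
                            flank("down", flank_each)))

  asm <- .assemble_genes(genes, gc)
  body <- asm$sequence
  gtab <- asm$genes

  # plant the origin-like repeat next to the core region
  ori_kind <- sample(c("direct", "interspersed_direct", "palindromic"), 1L)
  ori_side <- if (status == "incomplete_cluster2" || stats::runif(1L) < 0.5)
    "after_cluster2" else "before_cluster1"
  if (status == "incomplete_cluster2") ori_side <- "after_cluster2"
  if (status == "incomplete_cluster1") ori_side <- "before_cluster1"
  ori <- .make_ori_construct(ori_kind, cfg$ori_repeat_len, gc)
  first_core <- if (status == "incomplete_cluster2") "ORF17" else "ORF6"
  last_core <- if (status == "incomplete_cluster1") "ORF9" else "ORF25"
  at <- if (ori_side == "before_cluster1")
    gtab$start[gtab$gene == first_core] - 5L else
    gtab$end[gtab$gene == last_core] + 5L
  body <- paste0(substr(body, 1L, at), ori$sequence,
                 substr(body, at + 1L, nchar(body)))
  ins_len <- nchar(ori$sequence)
  shift <- function(x) ifelse(x >= at, x + ins_len, x)
  gtab$start <- shift(gtab$start); gtab$end <- shift(gtab$end)
  ori_pos1 <- at
  ori_pos2 <- at + ori$pos2_offset

  circular <- stats::runif(1L) < cfg$circular_fraction
  tr <- 0L
  if (circular) {
    tr <- cfg$terminal_repeat_len
    TR <- rand_string(tr, c("A", "C", "G", "T"),
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    body <- paste0(TR, body, TR)
    gtab$start <- gtab$start + tr; gtab$end <- gtab$end + tr
    ori_pos1 <- ori_pos1 + tr; ori_pos2 <- ori_pos2 + tr
  }

  flipped <- stats::runif(1L) < 0.5
  if (flipped) {
    n <- nchar(body)
    body <- revcomp_dna(body)
    new_start <- n - gtab$end
    gtab$end <- n - gtab$start
    gtab$start <- new_start
    p1 <- n - (ori_pos2 + ori$length)
    ori_pos2 <- n - (ori_pos1 + ori$length)
    ori_pos1 <- p1
  }

  core_genes <- intersect(gtab$gene, c(cluster1, cluster2))
  core_lo <- min(gtab$start[gtab$gene %in% core_genes])
  core_hi <- max(gtab$end[gtab$gene %in% core_genes])

  ct <- contig(id, body, source = "synthetic", circular = NA)
  truth <- data.frame(
    contig_id = id, planted_status = status,
    planted_markers = paste(intersect(names(genes), MARKERS6), collapse = ","),
    marker_identities = paste(sprintf("%s:%.3f", MARKERS6, idents),
                              collapse = ","),
    n_variable_genes = if (status == "complete") k else NA_integer_,
    circular = circular, terminal_repeat_len = tr,
    ori_kind = ori_kind, ori_side = ori_side,
    ori_pos1 = ori_pos1, ori_pos2 = ori_pos2, ori_len = ori$length,
    core_lo = core_lo, core_hi = core_hi,
    gc_target = gc, flipped = flipped, stringsAsFactors = FALSE)
  list(contig = ct, truth = truth)
}

#' Generate a decoy contig free of marker homology
#'
#' Random genes with length and GC matched to the element contigs; the
#' contig is rejection-sampled so every ORF scores at least 10 bits below
#' every profile's reporting threshold.
#'
#' @param cfg A [generator_config()].
#' @param profiles Marker profiles used for rejection sampling.
#' @param id Contig id.
#' @return List: `contig` and `truth` row.
#' @export
make_decoy_contig <- function(cfg, profiles, id = "decoy_01") {
  gc <- stats::runif(1L, cfg$gc_range[[1L]], cfg$gc_range[[2L]])
  target <- sample(cfg$contig_len_range[[1L]]:cfg$contig_len_range[[2L]], 1L)
  for (try in 1:20) {
    prot <- list(); total <- 0L
    while (total < target) {
      p <- .random_protein(sample(80:220, 1L))
      prot[[length(prot) + 1L]] <- p
      total <- total + 3L * (nchar(p) + 1L) + 50L
    }
    names(prot) <- paste0("dg_", seq_along(prot))
    asm <- .assemble_genes(prot, gc)
    ct <- contig(id, asm$sequence, source = "synthetic")
    orfs <- find_orfs(ct)
    ok <- TRUE
    for (pf in profiles) {
      margin <- pf$score_threshold - 10
      for (i in seq_len(nrow(orfs))) {
        if (nchar(orfs$protein[[i]]) < pf$coverage_threshold * pf$L) next
        if (viterbi_score(pf, orfs$protein[[i]])$bitscore >= margin) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      truth <- data.frame(contig_id = id, planted_status = "negative",
                          planted_markers = "", marker_identities = "",
                          n_variable_genes = NA_integer_, circular = FALSE,
                          terminal_repeat_len = 0L, ori_kind = "none",
                          ori_side = "none", ori_pos1 = NA_integer_,
                          ori_pos2 = NA_integer_, ori_len = NA_integer_,
                          core_lo = NA_integer_, core_hi = NA_integer_,
                          gc_target = gc, flipped = FALSE,
                          stringsAsFactors = FALSE)
      return(list(contig = ct, truth = truth))
    }
  }
  stop("decoy rejection sampling failed 20 times (should be essentially impossible)")
}

#' Generate a pangenome with planted core/shell/cloud truth
#'
#' For each planted cluster a genome-membership count is drawn uniformly
#' inside its band (for n genomes the bands are the strict->90%, 50-90%,
#' 10-50% and <10% count intervals); member proteins are substitution-only
#' mutants of a cluster parent at 55-90% identity. Each cluster's greedy
#' representative is fixed by construction and all members are
#' rejection-sampled so that score-gated identity to their own representative
#' stays comfortably above the 15% clustering threshold and to every other
#' representative below it, making the planted partition recoverable by
#' design.
#'
#' @param n_genomes Number of genomes (default 41).
#' @param n_core,n_shell,n_cloud,n_rare Planted cluster counts per band.
#' @return List: `proteins` (data frame genome_id, protein_id, seq),
#'   `truth` (cluster_id, label, n_genomes, member protein ids).
#' @export
make_pangenome_truth <- function(n_genomes = 41L, n_core = 10L, n_shell = 8L,
                                 n_cloud = 20L, n_rare = 3L) {
  t_core <- pangenome_threshold(n_genomes, 0.9)
  t_shell <- pangenome_threshold(n_genomes, 0.5)
  t_cloud <- pangenome_threshold(n_genomes, 0.1)
  bands <- list(core = c(t_core, n_genomes),
                shell = c(t_shell, t_core - 1L),
                cloud = c(t_cloud, t_shell - 1L),
                singleton_or_rare = c(1L, t_cloud - 1L))
  plan <- rep(names(bands), c(n_core, n_shell, n_cloud, n_rare))
  genomes <- sprintf("g%02d", seq_len(n_genomes))

  # Cluster parents and per-cluster representatives are constructed so that
  # the clustering guarantee holds by design: representatives are mutually
  # unalignable below the threshold (gated identity < 0.12), every member
  # aligns to its own representative comfortably above it (>= 0.18) and to no
  # other representative (< 0.12). Members are substitution-only mutants, so
  # all members of a cluster share their parent's length and the smallest
  # protein id (the first genome) is the deterministic greedy representative.
  parents <- character(length(plan))
  member_sets <- vector("list", length(plan))
  reps <- character(0)
  memberships <- lapply(seq_along(plan), function(j) {
    band <- bands[[plan[[j]]]]
    sort(sample(genomes, sample(band[[1L]]:band[[2L]], 1L)))
  })
  for (j in seq_along(plan)) {
    ok <- FALSE
    for (try in 1:200) {
      parent <- .random_protein(sample(90:200, 1L))
      rep_seq <- mutate_protein(parent, stats::runif(1L, 0.70, 0.90))
      if (!length(reps) || all(.gated_identity_many(reps, rep_seq) < 0.12)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not sample a separated cluster representative")
    parents[[j]] <- parent
    reps <- c(reps, rep_seq)
    member_sets[[j]] <- rep_seq        # first member = representative
  }

  rows <- list(); truth <- list()
  for (j in seq_along(plan)) {
    gs <- memberships[[j]]
    m <- length(gs)
    pids <- sprintf("%s|pc%03d", gs, j)
    seqs <- character(m)
    seqs[[1L]] <- member_sets[[j]][[1L]]
    for (gi in seq.int(2L, length.out = m - 1L)) {
      for (try in 1:100) {
        mutant <- mutate_protein(parents[[j]], stats::runif(1L, 0.55, 0.90))
        ident <- .gated_identity_many(reps, mutant)
        if (ident[[j]] >= 0.18 && all(ident[-j] < 0.12)) break
        mutant <- NA_character_
      }
      if (is.na(mutant)) stop("could not sample a separable cluster member")
      seqs[[gi]] <- mutant
    }
    for (gi in seq_len(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gs[[gi]], protein_id = pids[[gi]], seq = seqs[[gi]],
        stringsAsFactors = FALSE)
    }
    truth[[j]] <- data.frame(planted_cluster = sprintf("pc%03d", j),
                             label = plan[[j]], n_genomes = m,
                             member_ids = paste(pids, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  list(proteins = do.call(rbind, rows), truth = do.call(rbind, truth),
       genomes = genomes)
}

COG_BASE_DISTRIBUTION <- c(
  J = 0.07, K = 0.09, L = 0.08, D = 0.02, V = 0.03, T = 0.04, M = 0.05,
  N = 0.01, U = 0.02, O = 0.04, C = 0.06, G = 0.06, E = 0.12, F = 0.03,
  H = 0.04, I = 0.03, P = 0.05, Q = 0.02, R = 0.08, S = 0.06)

#' Generate COG annotation tables with a planted enrichment
#'
#' The reference set draws categories from a fixed base distribution; the
#' query (apHPV) set draws from base + planted_delta. One category per gene
#' (multinomial sampling), so the estimated delta is an unbiased
#' multinomial-proportion difference.
#'
#' @param n_genes_per_set Genes per set.
#' @param planted_delta Named signed fractions summing to 0 (categories must
#'   exist in the base distribution and stay non-negative).
#' @param base Base category distribution (defaults to a haloarchaea-like
#'   mix normalized to 1).
#' @return List: `table` (gene_id, set_label, categories), `planted_delta`,
#'   `base`.
#' @export
make_cog_tables <- function(n_genes_per_set = 2000L,
                            planted_delta = c(V = 0.10, E = -0.10),
                            base = NULL) {
  if (is.null(base)) base <- COG_BASE_DISTRIBUTION / sum(COG_BASE_DISTRIBUTION)
  if (abs(sum(planted_delta)) > 1e-9) stop("planted deltas must sum to 0")
  if (!all(names(planted_delta) %in% names(base))) {
    stop("planted delta names must be categories of the base distribution")
  }
  shifted <- base
  shifted[names(planted_delta)] <- shifted[names(planted_delta)] + planted_delta
  if (any(shifted < 0)) stop("infeasible planted delta: negative probability")
  draw <- function(set, prob) {
    data.frame(gene_id = sprintf("%s_gene%05d", set, seq_len(n_genes_per_set)),
               set_label = set,
               categories = sample(names(prob), n_genes_per_set,
                                   replace = TRUE, prob = prob),
               stringsAsFactors = FALSE)
  }
  list(table = rbind(draw("apHPV", shifted), draw("reference", base)),
       planted_delta = planted_delta, base = base)
}

#' Generate the full synthetic benchmark
#'
#' Seeds the RNG and produces contigs (complete, incomplete, decoy) with a
#' truth table, the bundled seed alignments and their profiles, CRISPR
#' spacers (planted positives drawn from core regions plus random decoy
#' spacers), COG tables and a planted pangenome.
#'
#' @param cfg A [generator_config()].
#' @param components Subset of "contigs", "pangenome", "cog", "spacers".
#' @return Named list with the requested components and their truth tables.
#' @export
generate_benchmark <- function(cfg = generator_config(),
                               components = c("contigs", "pangenome",
                                              "cog", "spacers")) {
  set.seed(cfg$seed)
  seeds <- toy_seed_alignments()
  profiles <- lapply(seeds, build_profile)
  out <- list(config = cfg, seed_alignments = seeds, profiles = profiles)

  if ("contigs" %in% components) {
    contigs <- list(); truth <- list()
    n1 <- ceiling(0.8 * cfg$n_incomplete)   # most fragments carry cluster 1
    specs <- c(rep("complete", cfg$n_complete),
               rep("incomplete_cluster1", n1),
               rep("incomplete_cluster2", cfg$n_incomplete - n1))
    ids <- c(sprintf("element_%02d", seq_len(cfg$n_complete)),
             sprintf("fragment_%02d", seq_len(cfg$n_incomplete)))
    for (i in seq_along(specs)) {
      r <- make_element_contig(cfg, specs[[i]], id = ids[[i]])
      contigs[[r$contig$id]] <- r$contig
      truth[[r$contig$id]] <- r$truth
    }
    for (i in seq_len(cfg$n_decoys)) {
      r <- make_decoy_contig(cfg, profiles, id = sprintf("decoy_%02d", i))
      contigs[[r$contig$id]] <- r$contig
      truth[[r$contig$id]] <- r$truth
    }
    out$contigs <- contigs
    out$truth_contigs <- do.call(rbind, truth)
    rownames(out$truth_contigs) <- NULL
  }

  if ("spacers" %in% components) {
    stopifnot("contigs" %in% components)
    tt <- out$truth_contigs
    complete_ids <- tt$contig_id[tt$planted_status == "complete"]
    n_pos <- min(7L, length(complete_ids))
    srcs <- sample(complete_ids, n_pos)
    spacers <- character(0); struth <- list()
    for (i in seq_along(srcs)) {
      s <- out$contigs[[srcs[[i]]]]$sequence
      row <- tt[tt$contig_id == srcs[[i]], ]
      len <- sample(32:40, 1L)
      # protospacer drawn from inside the planted core region
      at <- sample(seq.int(row$core_lo + 1L, row$core_hi - len), 1L)
      sp <- substr(s, at, at + len - 1L)
      if (stats::runif(1L) < 0.5) sp <- revcomp_dna(sp)
      id <- sprintf("spacer_pos_%02d", i)
      spacers[[id]] <- sp
      struth[[id]] <- data.frame(spacer_id = id, source_contig = srcs[[i]],
                                 planted = TRUE, stringsAsFactors = FALSE)
    }
    for (i in 1:20) {
      id <- sprintf("spacer_neg_%02d", i)
      spacers[[id]] <- rand_string(35L, c("A", "C", "G", "T"))
      struth[[id]] <- data.frame(spacer_id = id, source_contig = NA_character_,
                                 planted = FALSE, stringsAsFactors = FALSE)
    }
    out$spacers <- spacers
    out$truth_spacers <- do.call(rbind, struth)
    rownames(out$truth_spacers) <- NULL
  }

  if ("pangenome" %in% components) {
    pgc <- cfg$pangenome
    out$pangenome <- make_pangenome_truth(pgc$n_genomes, pgc$n_core,
                                          pgc$n_shell, pgc$n_cloud,
                                          pgc$n_rare)
  }
  if ("cog" %in% components) {
    out$cog <- make_cog_tables()
  }
  out
}
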