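#' Pairwise amino-acid identity from a global alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap costs
#' (open 11, extend 1); identity is the number of identical aligned residue
#' pairs divided by the length of the shorter sequence (the cd-hit
#' convention).
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_align_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

# vectorized variant: identity of each of `xs` against one subject
.align_identity_many <- function(xs, b) {
  if (!length(xs)) return(numeric(0))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(xs), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(pa) / pmin(nchar(xs), nchar(b))
}

# identity gated on a positive alignment score: a forced global alignment of
# unrelated proteins still shows ~20% coincidental identity, so (like the
# BLAST-backed clustering this mirrors) pairs whose best global alignment
# scores at or below `min_score` are treated as sharing no identity at all
.gated_identity_many <- function(xs, b, min_score = 0) {
  if (!length(xs)) return(numeric(0))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(xs), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  ident <- Biostrings::nmatch(pa) / pmin(nchar(xs), nchar(b))
  ifelse(Biostrings::score(pa) > min_score, ident, 0)
}

#' Greedy incremental protein clustering
#'
#' Proteins are sorted by length descending (ties: id ascending); each
#' protein joins the first existing cluster (in founding order) whose
#' representative aligns at identity >= `identity_threshold`, otherwise it
#' founds a new cluster with itself as representative. Deterministic.
#'
#' Because a forced global alignment of unrelated proteins still yields about
#' 20% coincidental identity, identity only counts towards the threshold when
#' the alignment score is positive (`min_score`); pairs at or below it are
#' treated as unalignable, mirroring the no-significant-alignment behaviour
#' of BLAST-backed low-threshold clustering.
#'
#' @param proteins Data frame with columns genome_id, protein_id, seq.
#' @param identity_threshold Identity cutoff in (0, 1]; default 0.15.
#' @param min_score Alignment-score gate in BLOSUM62 units (set to `-Inf` to
#'   threshold on raw identity alone).
#' @return List of `pangenome_cluster` lists: cluster_id, representative,
#'   members (data frame genome_id, protein_id), n_genomes.
#' @export
greedy_cluster <- function(proteins, identity_threshold = 0.15,
                           min_score = 0) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            all(c("genome_id", "protein_id", "seq") %in% names(proteins)))
  ord <- order(-nchar(proteins$seq), proteins$protein_id)
  proteins <- proteins[ord, , drop = FALSE]
  reps <- character(0)          # representative sequences, founding order
  founders <- character(0)
  assign <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$seq[[i]]
    hit <- 0L
    if (length(reps)) {
      ident <- .gated_identity_many(reps, s, min_score = min_score)
      ok <- which(ident >= identity_threshold)
      if (length(ok)) hit <- ok[[1L]]
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      founders <- c(founders, proteins$protein_id[[i]])
      hit <- length(reps)
    }
    assign[[i]] <- hit
  }
  lapply(seq_along(reps), function(j) {
    m <- proteins[assign == j, c("genome_id", "protein_id", "seq"), drop = FALSE]
    rownames(m) <- NULL
    structure(list(cluster_id = sprintf("cluster_%04d", j),
                   representative = founders[[j]], members = m,
                   n_genomes = length(unique(m$genome_id)),
                   label = NA_character_),
              class = "pangenome_cluster")
  })
}

#' Smallest genome count strictly exceeding a fraction
#'
#' Returns `floor(fraction * n_genomes) + 1`, the smallest integer count that
#' strictly exceeds the fraction; e.g. for 41 genomes the >90%, >50% and >10%
#' thresholds are 37, 21 and 5. Robust to floating-point representation of
#' `fraction * n_genomes`.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param fraction Fraction in (0, 1).
#' @return Integer threshold.
#' @export
pangenome_threshold <- function(n_genomes, fraction) {
  stopifnot(n_genomes >= 1, fraction > 0, fraction < 1)
  as.integer(floor(fraction * n_genomes + 1e-9)) + 1L
}

#' Label clusters as core, shell, cloud or rare
#'
#' Core: present in more than 90% of genomes; shell: 50-90%; cloud: 10-50%;
#' anything rarer is `singleton_or_rare`. Band edges use the strict-exceed
#' thresholds of [pangenome_threshold()].
#'
#' @param clusters List from [greedy_cluster()].
#' @param n_genomes Total genomes in the run.
#' @param core_frac,shell_frac,cloud_frac Band fractions.
#' @return The clusters with `label` filled.
#' @export
classify_clusters <- function(clusters, n_genomes, core_frac = 0.9,
                              shell_frac = 0.5, cloud_frac = 0.1) {
  t_core  <- pangenome_threshold(n_genomes, core_frac)
  t_shell <- pangenome_threshold(n_genomes, shell_frac)
  t_cloud <- pangenome_threshold(n_genomes, cloud_frac)
  lapply(clusters, function(cl) {
    n <- cl$n_genomes
    cl$label <- if (n >= t_core) "core"
                else if (n >= t_shell) "shell"
                else if (n >= t_cloud) "cloud"
                else "singleton_or_rare"
    cl
  })
}

#' Cluster summary table
#' @param clusters Labeled clusters.
#' @return Data frame (cluster_id, representative, n_genomes, n_members,
#'   label).
#' @export
cluster_table <- function(clusters) {
  out <- do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster_id = cl$cluster_id, representative = cl$representative,
    n_genomes = cl$n_genomes, n_members = nrow(cl$members),
    label = cl$label, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Presence/absence matrix of clusters across genomes
#'
#' Binary genomes x clusters matrix restricted to the requested labels
#' (default: everything in the pangenome proper, i.e. clusters present in
#' more than 10% of genomes).
#'
#' @param clusters Labeled clusters.
#' @param genomes Ordered genome ids (rows).
#' @param labels Cluster labels to retain.
#' @return Binary matrix with genome rownames and cluster colnames.
#' @export
presence_absence <- function(clusters, genomes,
                             labels = c("core", "shell", "cloud")) {
  keep <- Filter(function(cl) cl$label %in% labels, clusters)
  m <- matrix(0L, nrow = length(genomes), ncol = length(keep),
              dimnames = list(genomes,
                              vapply(keep, `[[`, "", "cluster_id")))
  for (cl in keep) {
    g <- intersect(unique(cl$members$genome_id), genomes)
    m[g, cl$cluster_id] <- 1L
  }
  empty <- rownames(m)[rowSums(m) == 0L]
  if (length(empty)) {
    warning("genome(s) with no clustered proteins retained as all-zero rows: ",
            paste(empty, collapse = ", "))
  }
  m
}

#' Jaccard distance on presence/absence profiles
#'
#' `1 - |intersection| / |union|` over the presence sets of each genome pair;
#' pairs with an empty union get distance 1.
#'
#' @param m Binary presence/absence matrix (genomes in rows).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(m) {
  if (nrow(m) < 2L) stop("need at least two genomes")
  m <- (m > 0) * 1L
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- ifelse(uni > 0, 1 - inter / uni, 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Iteratively merges the closest pair of clusters; the distance between two
#' clusters is the unweighted mean of all cross-pair leaf distances. Ties are
#' broken by the lexicographically smallest pair of cluster labels (a
#' cluster's label is its smallest member label).
#'
#' @param d Symmetric distance matrix with zero diagonal (labels required).
#' @return A `dendrogram_al` list: labels, merges (data frame a, b, height;
#'   negative entries index leaves, positive entries earlier merges, the
#'   hclust convention) and heights.
#' @export
average_linkage <- function(d) {
  if (any(is.na(d))) stop("NA/NaN in distance matrix")
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("L%03d", seq_len(nrow(d)))
  }
  labs <- rownames(d)
  n <- nrow(d)
  members <- stats::setNames(as.list(seq_len(n)), labs)  # leaves per cluster
  ids <- stats::setNames(as.list(-seq_len(n)), labs)     # hclust node codes
  active <- labs
  D <- d
  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       height = numeric(n - 1L))
  sizes <- stats::setNames(rep(1L, n), labs)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      la <- active[[i]]; lb <- active[[j]]
      pair <- sort(c(la, lb))
      dij <- D[la, lb]
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (pair[[1L]] < best$pair[[1L]] ||
            (pair[[1L]] == best$pair[[1L]] && pair[[2L]] < best$pair[[2L]])))) {
        best <- list(d = dij, i = la, j = lb, pair = pair)
      }
    }
    la <- best$i; lb <- best$j
    new_lab <- min(la, lb)
    merges$a[[step]] <- ids[[la]]; merges$b[[step]] <- ids[[lb]]
    merges$height[[step]] <- best$d
    # unweighted average linkage update
    others <- setdiff(active, c(la, lb))
    na <- sizes[[la]]; nb <- sizes[[lb]]
    for (lo in others) {
      D[new_lab, lo] <- D[lo, new_lab] <-
        (na * D[la, lo] + nb * D[lb, lo]) / (na + nb)
    }
    members[[new_lab]] <- c(members[[la]], members[[lb]])
    sizes[[new_lab]] <- na + nb
    drop_lab <- setdiff(c(la, lb), new_lab)
    active <- setdiff(active, drop_lab)
    ids[[new_lab]] <- step
  }
  structure(list(labels = labs, merges = merges, heights = merges$height),
            class = "dendrogram_al")
}

#' Convert an average-linkage dendrogram to an hclust object
#' @param tree A `dendrogram_al`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  structure(list(merge = as.matrix(tree$merges[, c("a", "b")]),
                 height = tree$merges$height,
                 order = .leaf_order(tree), labels = tree$labels,
                 method = "average", call = match.call(),
                 dist.method = "jaccard"),
            class = "hclust")
}

.leaf_order <- function(tree) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(tree$merges$a[[node]]), rec(tree$merges$b[[node]]))
  }
  rec(nrow(tree$merges))
}

#' Cophenetic distances implied by a dendrogram
#' @param tree A `dendrogram_al`.
#' @return Symmetric matrix of merge heights between leaf pairs.
#' @export
cophenetic_distance <- function(tree) {
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- vector("list", nrow(tree$merges))
  get_leaves <- function(node) if (node < 0L) -node else sets[[node]]
  for (s in seq_len(nrow(tree$merges))) {
    A <- get_leaves(tree$merges$a[[s]])
    B <- get_leaves(tree$merges$b[[s]])
    cm[A, B] <- cm[B, A] <- tree$merges$height[[s]]
    sets[[s]] <- c(A, B)
  }
  cm
}

.newick_quote <- function(x) {
  if (grepl("[][\\s():;,']", x, perl = TRUE)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

#' Serialize a dendrogram to Newick text
#'
#' Branch lengths are height differences between a node and its parent
#' (ultrametric); labels containing spaces or Newick metacharacters are
#' quoted.
#'
#' @param tree A `dendrogram_al`.
#' @param digits Branch-length precision.
#' @return Newick string (terminated with `;`).
#' @export
to_newick <- function(tree, digits = 8) {
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node, parent_h) {
    if (node < 0L) {
      return(paste0(.newick_quote(tree$labels[[-node]]), ":", fmt(parent_h)))
    }
    h <- tree$merges$height[[node]]
    paste0("(", rec(tree$merges$a[[node]], h), ",",
           rec(tree$merges$b[[node]], h), "):", fmt(parent_h - h))
  }
  root <- nrow(tree$merges)
  h <- tree$merges$height[[root]]
  paste0("(", rec(tree$merges$a[[root]], h), ",",
         rec(tree$merges$b[[root]], h), ");")
}

#' Mean pairwise amino-acid identity within a cluster
#'
#' @param cluster A `pangenome_cluster` with at least two members.
#' @return Mean of [global_align_identity()] over all member pairs; NA for
#'   singletons.
#' @export
cluster_mean_pairwise_aai <- function(cluster) {
  seqs <- cluster$members$seq
  m <- length(seqs)
  if (m < 2L) return(NA_real_)
  tot <- 0; cnt <- 0L
  for (i in seq_len(m - 1L)) {
    ident <- .align_identity_many(seqs[(i + 1L):m], seqs[[i]])
    tot <- tot + sum(ident); cnt <- cnt + length(ident)
  }
  tot / cnt
}
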