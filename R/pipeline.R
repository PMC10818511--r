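#' Pipeline run configuration
#'
#' Aggregates every stage parameter with its literature default: contigs
#' must be longer than 10,000 bp; incomplete elements need 3 and complete
#' elements 5 distinct markers of 6; profile bitscore threshold 50; terminal
#' repeats longer than 30 bp; origin repeats longer than 25 bp with at most
#' 1 mismatch; protein clustering at 15% identity; core/shell/cloud
#' fractions 0.9/0.5/0.1; spacer hits above 97% identity and longer than
#' 30 nt.
#'
#' @param seed RNG seed for the generated benchmark.
#' @param out_dir Run directory for stage outputs.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param min_contig_len,min_markers_incomplete,min_markers_complete
#'   Detection thresholds.
#' @param score_threshold,coverage_threshold Profile reporting thresholds.
#' @param terminal_repeat_min,ori_repeat_min,ori_max_mismatch,ori_window
#'   Repeat-stage thresholds (bp / count).
#' @param identity_threshold,core_frac,shell_frac,cloud_frac Pangenome
#'   parameters.
#' @param spacer_min_identity,spacer_min_len Spacer-match thresholds.
#' @param flank_genes Core-region flank size in genes.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("apvhunter_run_"),
                            generator = generator_config(seed = seed),
                            min_contig_len = 10000L,
                            min_markers_incomplete = 3L,
                            min_markers_complete = 5L,
                            score_threshold = 50, coverage_threshold = 0.7,
                            terminal_repeat_min = 31L, ori_repeat_min = 26L,
                            ori_max_mismatch = 1L, ori_window = 2000L,
                            identity_threshold = 0.15, core_frac = 0.9,
                            shell_frac = 0.5, cloud_frac = 0.1,
                            spacer_min_identity = 0.97, spacer_min_len = 30L,
                            flank_genes = 10L) {
  generator$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on the synthetic benchmark
#'
#' Stages in dependency order: generate (synthetic benchmark with truth),
#' profiles (build from seed alignments), detect (ORF calling, marker scan,
#' classification, synteny), repeats (circularity and origin candidates for
#' non-negative calls), pangenome (core-region proteomes of complete
#' elements are generated separately with planted truth), cogdelta and
#' spacers. All tabular outputs are written under `config$out_dir`; the
#' returned run report carries per-stage counts, the parameter echo and
#' wall-clock times.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (also serialized to `run_report.txt` in the
#'   run directory).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = config, stages = list(), warnings = character(0))
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  bench <- generate_benchmark(config$generator)
  profiles <- lapply(bench$profiles, function(pf) {
    pf$score_threshold <- config$score_threshold
    pf$coverage_threshold <- config$coverage_threshold
    pf
  })
  write_fasta(bench$contigs, file.path(config$out_dir, "contigs.fasta"))
  utils::write.table(bench$truth_contigs,
                     file.path(config$out_dir, "truth_contigs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (pf in profiles) {
    write_profile(pf, file.path(config$out_dir,
                                paste0("profile_", pf$name, ".tsv")))
  }
  report$stages$generate <- list(
    n_contigs = length(bench$contigs), seconds = tic() - t0)

  t0 <- tic()
  det <- detect_elements(bench$contigs, profiles,
                         min_contig_len = config$min_contig_len,
                         min_markers_incomplete = config$min_markers_incomplete,
                         min_markers_complete = config$min_markers_complete)
  utils::write.table(det$calls_table, file.path(config$out_dir, "calls.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_orfs_gff3(det$orfs, file.path(config$out_dir, "orfs.gff3"))
  report$stages$detect <- list(
    n_complete = sum(det$calls_table$status == "complete"),
    n_incomplete = sum(det$calls_table$status == "incomplete"),
    n_negative = sum(det$calls_table$status == "negative"),
    seconds = tic() - t0)

  t0 <- tic()
  repeat_rows <- list(); core_seqs <- character(0)
  for (id in names(det$calls)) {
    call <- det$calls[[id]]
    if (call$status == "negative") next
    ct <- bench$contigs[[id]]
    tr <- detect_terminal_repeats(ct, min_len = config$terminal_repeat_min)
    ct <- tr$contig
    reps <- find_repeats(ct$sequence, min_len = config$ori_repeat_min,
                         max_mismatch = config$ori_max_mismatch)
    if (nrow(reps)) {
      reps <- locate_putative_ori(reps, call, window = config$ori_window,
                                  contig_length = nchar(ct$sequence),
                                  circular = ct$circular)
      reps <- cbind(contig_id = id, reps, circular = ct$circular)
      repeat_rows[[id]] <- reps
    }
    orfs <- det$orfs[det$orfs$contig_id == id, , drop = FALSE]
    core <- extract_core_region(call, ct, orfs,
                                flank_genes = config$flank_genes)
    core_seqs[[paste0(id, "_core")]] <- core$sequence
    det$calls[[id]]$circular <- ct$circular
  }
  repeats_tab <- if (length(repeat_rows)) do.call(rbind, repeat_rows) else NULL
  if (!is.null(repeats_tab)) {
    utils::write.table(repeats_tab, file.path(config$out_dir, "repeats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_fasta(core_seqs, file.path(config$out_dir, "core_regions.fasta"))
  report$stages$repeats <- list(
    n_circular = sum(vapply(det$calls, function(x)
      isTRUE(x$circular), logical(1L))),
    n_repeat_hits = if (is.null(repeats_tab)) 0L else nrow(repeats_tab),
    seconds = tic() - t0)

  t0 <- tic()
  pg <- bench$pangenome
  clusters <- greedy_cluster(pg$proteins,
                             identity_threshold = config$identity_threshold)
  clusters <- classify_clusters(clusters, length(pg$genomes),
                                core_frac = config$core_frac,
                                shell_frac = config$shell_frac,
                                cloud_frac = config$cloud_frac)
  ctab <- cluster_table(clusters)
  utils::write.table(ctab, file.path(config$out_dir, "pangenome_clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  pam <- presence_absence(clusters, pg$genomes)
  utils::write.table(pam, file.path(config$out_dir, "presence_absence.tsv"),
                     sep = "\t", quote = FALSE)
  d <- binary_distance(pam)
  tree <- average_linkage(d)
  writeLines(to_newick(tree), file.path(config$out_dir, "pangenome_tree.nwk"))
  report$stages$pangenome <- list(
    n_clusters = length(clusters),
    n_core = sum(ctab$label == "core"), n_shell = sum(ctab$label == "shell"),
    n_cloud = sum(ctab$label == "cloud"), seconds = tic() - t0)

  t0 <- tic()
  prof_ap <- cog_relative_abundance(bench$cog$table, "apHPV")
  prof_ref <- cog_relative_abundance(bench$cog$table, "reference")
  dl <- cog_delta(prof_ap, prof_ref)
  dtab <- data.frame(category = names(dl), delta_rel = as.numeric(dl))
  dtab <- dtab[order(-abs(dtab$delta_rel)), ]
  utils::write.table(dtab, file.path(config$out_dir, "cog_delta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report$stages$cogdelta <- list(
    n_categories = length(dl), max_abs_delta = max(abs(dl)),
    seconds = tic() - t0)

  t0 <- tic()
  sm <- match_spacers(bench$spacers,
                      stats::setNames(core_seqs, names(core_seqs)),
                      min_identity = config$spacer_min_identity,
                      min_len = config$spacer_min_len)
  utils::write.table(sm, file.path(config$out_dir, "spacer_matches.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report$stages$spacers <- list(
    n_spacers = length(bench$spacers), n_matches = nrow(sm),
    n_targeted_elements = length(unique(sm$target_contig)),
    seconds = tic() - t0)

  report$benchmark <- bench
  report$detection <- det
  report$repeats <- repeats_tab
  report$clusters <- clusters
  report$cog_delta <- dl
  report$spacer_matches <- sm
  class(report) <- "run_report"

  txt <- c("apvhunter run report",
           paste0("out_dir: ", config$out_dir),
           paste0("seed: ", config$seed),
           vapply(names(report$stages), function(s) {
             st <- report$stages[[s]]
             paste0(s, ": ",
                    paste(sprintf("%s=%s", names(st),
                                  vapply(st, function(v)
                                    format(v, digits = 4), "")),
                          collapse = " "))
           }, ""))
  writeLines(txt, file.path(config$out_dir, "run_report.txt"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("apvhunter run report\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %s\n", s,
                paste(sprintf("%s=%s", names(st),
                              vapply(st, function(v)
                                format(v, digits = 4), "")),
                      collapse = " ")))
  }
  invisible(x)
}
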