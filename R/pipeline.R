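#' Pipeline configuration
#'
#' Collects stage parameters and input manifests for the two recipes;
#' every parameter is echoed into the run log for provenance.
#'
#' @param ... named fields (see [run_prokaryote_recipe()] and
#'   [run_metal_subtree_recipe()] for the fields each consumes).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  defaults <- list(
    occupancy_threshold = 0.5, mask_preset = "medium",
    model = "LG", gamma_shape = 1, bootstrap_n = 100L,
    n_decoys = 600L, min_gap_orders = 3, seed = 1L,
    est_min_bits = 20, est_min_match_states = 50, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("proteome_files"))
    if (!is.null(cfg[[nm]]) && !all(file.exists(cfg[[nm]])))
      stop("missing input file(s): ",
           paste(cfg[[nm]][!file.exists(cfg[[nm]])], collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

# tiny FNV-1a hash for provenance stamps (no external digest dependency)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- bitwAnd((bitwXor(h, b) * 16777619),
                                       4294967295)
  sprintf("%08x", h)
}

write_provenance <- function(cfg, out_dir, stage_log) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "run_log.txt"), "w")
  on.exit(close(con))
  cat("metalphylo run\nconfig_hash:",
      config_hash(cfg[!vapply(cfg, is.function, logical(1L))]),
      "\nseed:", cfg$seed, "\n\nparameters:\n", file = con)
  for (nm in setdiff(names(cfg), c("proteomes", "seed_alignment",
                                   "family_sequences", "ests")))
    if (is.atomic(cfg[[nm]]))
      cat("  ", nm, "= ", paste(cfg[[nm]], collapse = " "), "\n",
          file = con)
  cat("\nstages:\n", file = con)
  for (ln in stage_log) cat("  ", ln, "\n", file = con)
  invisible(NULL)
}

#' Prokaryote-style recipe: search, threshold, mask, tree, census
#'
#' Profile construction from a seed alignment, decoy calibration,
#' proteome screening with automatic threshold detection, alignment
#' and masking of the retrieved family, NJ tree on ML distances,
#' specificity annotation by reference panel, and per-genome census.
#'
#' @param config [pipeline_config()] with fields: `proteomes` (named
#'   list of named sequence vectors, or `proteome_files`),
#'   `seed_alignment` (named aligned vector), `panel` (optional
#'   [reference_panel()]), `taxonomy` (optional [taxonomy_table()]),
#'   `genome_map` (protein -> genome; defaults to the screening
#'   proteome ids), plus the tuning fields of [pipeline_config()].
#' @return list: `profile`, `threshold`, `hits`, `alignment` (masked),
#'   `tree`, `labels`, `census_matrix`.
#' @export
run_prokaryote_recipe <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else do.call(pipeline_config, config)
  log <- character(0)
  proteomes <- cfg$proteomes
  if (is.null(proteomes) && !is.null(cfg$proteome_files))
    proteomes <- lapply(cfg$proteome_files, read_fasta)
  if (is.null(proteomes) || length(proteomes) == 0L)
    stop("no input proteomes")
  if (is.null(cfg$seed_alignment)) stop("no seed alignment")

  prof <- build_profile(cfg$seed_alignment,
                        occupancy_threshold = cfg$occupancy_threshold)
  decoys <- simulate_background(cfg$n_decoys, seed = cfg$seed + 101L)
  prof <- calibrate_evalues(prof, decoys)
  log <- c(log, sprintf("profile: %d match states; calibrated on %d decoys",
                        prof$match_state_count, cfg$n_decoys))

  all_hits <- screen_proteomes(prof, proteomes, evalue_cutoff = Inf)
  br <- detect_threshold_break(all_hits,
                               min_gap_orders = cfg$min_gap_orders)
  if (is.null(br)) stop("no E-value breakdown detected")
  hits <- all_hits[all_hits$evalue <= br$threshold, , drop = FALSE]
  log <- c(log, sprintf("threshold %.3g (gap %.1f orders): %d hits",
                        br$threshold, br$gap_orders, nrow(hits)))

  seqs <- unlist(lapply(names(proteomes), function(p)
    proteomes[[p]]), recursive = FALSE)
  fam <- seqs[hits$seq_id]
  aln <- align_progressive(fam)
  aln <- drop_insertion_columns(aln, cfg$occupancy_threshold)
  aln <- select_blocks(aln, cfg$mask_preset)
  log <- c(log, sprintf("alignment: %d x %d kept columns",
                        length(aln$rows), length(aln$index_map)))

  model <- substitution_model(cfg$model, gamma_shape = cfg$gamma_shape)
  tree <- build_nj(ml_distance_matrix(aln, model))

  labels <- NULL; cens <- NULL
  if (!is.null(cfg$panel)) {
    labels <- label_sequences(fam, cfg$panel,
                              min_score = cfg$min_label_bits %||% 30)
    genome_map <- cfg$genome_map %||%
      setNames(hits$proteome_id, hits$seq_id)
    cens <- census(data.frame(seq_id = labels$seq_id,
                              category = labels$specificity,
                              stringsAsFactors = FALSE), genome_map)
  }
  if (!is.null(cfg$taxonomy) && !is.null(cens))
    tree <- annotate_tree(tree, cfg$taxonomy, labels = labels)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile(prof, file.path(cfg$out_dir, "profile.txt"))
    write_hit_table(hits, file.path(cfg$out_dir, "hits.tsv"))
    write_fasta(aln$rows, file.path(cfg$out_dir, "family_masked.fasta"))
    write_mask_tsv(aln, file.path(cfg$out_dir, "mask.tsv"))
    export_newick(tree, file.path(cfg$out_dir, "tree.nwk"))
    if (!is.null(cens))
      write.table(unclass(cens), file.path(cfg$out_dir, "census.tsv"),
                  sep = "\t", quote = FALSE)
    write_provenance(cfg, cfg$out_dir, log)
  }
  list(profile = prof, threshold = br, hits = hits, alignment = aln,
       tree = tree, labels = labels, census_matrix = cens, log = log)
}

#' Metal-subtree recipe: subgroup trees, motifs, logos
#'
#' Alignment (or import) of the metal-family sequences, optional EST
#' augmentation, masking, NJ tree with bootstrap, outgroup rooting,
#' anchor-based subgroup assignment, motif calls at the
#' reference-anchored TM6 columns, and per-subgroup logos.
#'
#' @param config [pipeline_config()] with fields: `family_sequences`
#'   (named unaligned vector) or `family_alignment`; `anchors` (named
#'   list subgroup -> anchor leaf ids); `motif_reference` (list
#'   `id`, `position` in ungapped reference coordinates); optional
#'   `taxonomy`, `outgroup` (tip labels), `ests` + `est_organisms` +
#'   `ortholog_panel` + `paralog_panel`, `collapse_rank`; plus tuning
#'   fields of [pipeline_config()].
#' @return list: `alignment`, `est_report`, `tree` (rooted, bootstrap
#'   supports), `assignment`, `motifs`, `logos` (per subgroup).
#' @export
run_metal_subtree_recipe <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else do.call(pipeline_config, config)
  log <- character(0)
  aln <- if (!is.null(cfg$family_alignment))
    masked_alignment(cfg$family_alignment)
  else {
    if (is.null(cfg$family_sequences)) stop("no family input")
    align_progressive(cfg$family_sequences)
  }

  est_report <- NULL
  if (!is.null(cfg$ests)) {
    prof <- build_profile(aln$rows,
                          occupancy_threshold = cfg$occupancy_threshold)
    prof <- calibrate_evalues(
      prof, simulate_background(cfg$n_decoys, seed = cfg$seed + 211L))
    est <- integrate_ests(aln, prof, cfg$ests, cfg$est_organisms,
                          cfg$ortholog_panel, cfg$paralog_panel,
                          min_bits = cfg$est_min_bits,
                          min_match_states = cfg$est_min_match_states)
    aln <- est$alignment
    est_report <- est$report
    log <- c(log, sprintf("EST stage: %d fragments inserted",
                          sum(est_report$action == "inserted")))
  }

  masked <- drop_insertion_columns(aln, cfg$occupancy_threshold)
  masked <- select_blocks(masked, cfg$mask_preset)
  # partial-sequence filtering is skipped when EST fragments are in
  # (they are partial by nature)
  if (is.null(cfg$ests)) masked <- drop_partial_sequences(masked)
  log <- c(log, sprintf("masked alignment: %d x %d",
                        length(masked$rows), length(masked$index_map)))

  model <- substitution_model(cfg$model, gamma_shape = cfg$gamma_shape)
  tree <- bootstrap_support(masked, model,
                            n_replicates = cfg$bootstrap_n,
                            seed = cfg$seed + 997L)
  if (!is.null(cfg$outgroup))
    tree <- {
      rt <- root_with_outgroup(tree, cfg$outgroup)
      rt$bipartition_support <- tree$bipartition_support
      rt
    }
  tree <- ladderize_tree(tree)

  assignment <- NULL
  if (!is.null(cfg$anchors))
    assignment <- assign_subgroups(tree, cfg$anchors)

  # motif columns are located on the UNMASKED alignment: block
  # filtering changes the reference's ungapped coordinate frame
  motifs <- NULL; logos <- NULL
  full_aln <- masked_alignment(aln)
  if (!is.null(cfg$motif_reference)) {
    motifs <- call_tm6_motif(full_aln, cfg$motif_reference$id,
                             cfg$motif_reference$position)
    if (!is.null(assignment)) {
      logos <- list()
      cols <- unlist(motifs[1L, c("col1", "col2", "col3")])
      for (g in names(cfg$anchors)) {
        members <- names(assignment$assignments)[
          assignment$assignments == g]
        members <- intersect(members, names(full_aln$rows))
        if (length(members) == 0L) next
        m <- aln_matrix(full_aln$rows[members])[, cols, drop = FALSE]
        logos[[g]] <- logo(matrix_aln(m))
      }
    }
  }
  if (!is.null(cfg$taxonomy)) {
    tree <- annotate_tree(tree, cfg$taxonomy,
                          labels = if (!is.null(assignment))
                            setNames(assignment$assignments,
                                     names(assignment$assignments)),
                          motifs = motifs)
    if (!is.null(cfg$collapse_rank))
      tree_collapsed <- collapse_clades(tree, cfg$collapse_rank)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(masked$rows, file.path(cfg$out_dir,
                                       "subtree_masked.fasta"))
    write_annotated_nexus(tree, file.path(cfg$out_dir,
                                          "subtree_annotated.nex"))
    if (!is.null(motifs))
      write.table(motifs, file.path(cfg$out_dir, "motifs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(assignment))
      write.table(data.frame(leaf = names(assignment$assignments),
                             subgroup = assignment$assignments),
                  file.path(cfg$out_dir, "subgroups.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(est_report))
      write.table(est_report, file.path(cfg$out_dir, "est_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(cfg, cfg$out_dir, log)
  }
  out <- list(alignment = masked, est_report = est_report, tree = tree,
              assignment = assignment, motifs = motifs, logos = logos,
              log = log)
  if (exists("tree_collapsed", inherits = FALSE))
    out$tree_collapsed <- tree_collapsed
  out
}
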