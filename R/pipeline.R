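#' Analysis configuration for an end-to-end run
#'
#' Bundles the constants of the comparative analysis: the CNE thresholds
#' (65 percent identity over at least 50 bp), the repeat-search thresholds
#' (70 percent arm identity, 100 bp long-arm cutoff), the significance tiers
#' (0.01, 0.05), the clade priority order, the species roles, and one master
#' seed from which every stage derives its own.
#'
#' @param reference reference species for CNE calling.
#' @param ingroups ingroup species for the relative rate tests.
#' @param outgroup outgroup species for the relative rate tests.
#' @param diagnostic_species named list mapping `gnathostome`,
#'   `osteichthyan`, `sarcopterygian` to diagnostic species names (those
#'   present in the run; entries may be omitted).
#' @param thresholds a [conservation_thresholds()].
#' @param repeat_params a [repeat_search_params()].
#' @param sig_high,sig_low significance tier boundaries.
#' @param clade_priority permutation of the four group labels, deepest
#'   first.
#' @param sim optional [simulation_config()]; when supplied,
#'   [run_pipeline()] simulates its inputs instead of reading files.
#' @param seed master seed.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(reference, ingroups, outgroup,
                            diagnostic_species = list(),
                            thresholds = conservation_thresholds(),
                            repeat_params = repeat_search_params(),
                            sig_high = 0.01, sig_low = 0.05,
                            clade_priority = c("gnathostome", "osteichthyan",
                                               "sarcopterygian", "tetrapod"),
                            sim = NULL, seed = 1L) {
  stopifnot(inherits(thresholds, "conservation_thresholds"),
            inherits(repeat_params, "repeat_search_params"))
  if (!(sig_high > 0 && sig_high < sig_low && sig_low < 1))
    stop("config error: significance tiers must satisfy 0 < high < low < 1")
  if (!setequal(clade_priority, c("gnathostome", "osteichthyan",
                                  "sarcopterygian", "tetrapod")))
    stop("config error: clade_priority must be a permutation of the four groups")
  if (missing(reference) || !nzchar(reference))
    stop("config error: a reference species is required")
  if (missing(outgroup) || !nzchar(outgroup))
    stop("config error: an outgroup species is required")
  structure(list(reference = reference, ingroups = ingroups,
                 outgroup = outgroup, diagnostic_species = diagnostic_species,
                 thresholds = thresholds, repeat_params = repeat_params,
                 sig_high = sig_high, sig_low = sig_low,
                 clade_priority = clade_priority, sim = sim,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # version 2 serialization is stable across sessions of the same R series
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

write_stage_table <- function(x, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hoxcomp config=%s seed=%d", hash, seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative pipeline
#'
#' Executes the stages in dependency order: acquire clusters (simulate from
#' `config$sim`, or read FASTA/feature inputs), align every species against
#' the reference, call and classify CNEs, discover repeats and compute
#' densities and hotspots, run the relative-rate battery over the exon-derived
#' gene set with Hasse synthesis, and summarise. Every output table carries a
#' header with the config hash and seed; re-running with an identical config
#' is byte-identical.
#'
#' @param config an [analysis_config()].
#' @param inputs optional named list for file-based runs: `fasta` (multi-record
#'   FASTA of per-species cluster sequences), optional `features` +
#'   `features_dialect`, optional `genes_dir` (directory of per-gene aligned
#'   FASTAs), optional `tree` (Newick path). Ignored when `config$sim` is set.
#' @param out_dir output directory (created).
#' @return invisibly, a list of the in-memory stage results (`clusters`,
#'   `cnes`, `cne_table`, `repeats`, `densities`, `rrt`, `hasse`,
#'   `pairwise_summary`, `genome` when applicable).
#' @export
run_pipeline <- function(config, inputs = NULL, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  put <- function(x, name) write_stage_table(x, file.path(out_dir, name),
                                             hash, config$seed)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("# hoxcomp run config=%s seed=%d\n", hash, config$seed),
      file = log_path)

  # ---- stage 1: clusters ----
  exon_feats <- NULL
  if (!is.null(config$sim)) {
    truth <- simulate_clusters(config$sim)
    seqs <- vapply(truth$clusters, function(cl) cl$sequence, character(1))
    if (config$reference %in% names(truth$clusters)) {
      exon_feats <- truth$clusters[[config$reference]]$features
      exon_feats <- exon_feats[exon_feats$kind == "exon", , drop = FALSE]
    }
  } else {
    if (is.null(inputs$fasta)) stop("config error: no simulation and no FASTA input")
    seqs <- read_fasta(inputs$fasta)
    truth <- NULL
    if (!is.null(inputs$features)) {
      feats <- read_features(inputs$features,
                             dialect = inputs$features_dialect %||% "BED")
      exon_feats <- feats[feats$kind == "exon" &
                            feats$seq_id == config$reference, , drop = FALSE]
    }
  }
  species <- names(seqs)
  for (role in c(config$reference, config$outgroup))
    if (!role %in% species)
      stop("config error: species role '", role, "' missing from inputs")
  logf("stage clusters: %d species, reference %s", length(species),
       config$reference)
  write_fasta(seqs, file.path(out_dir, "clusters.fasta"))

  # ---- stage 2+3: alignments and CNEs ----
  ref_seq <- seqs[[config$reference]]
  mask <- if (!is.null(exon_feats) && nrow(exon_feats) > 0)
    gi(config$reference, exon_feats$start, exon_feats$end) else NULL
  others <- setdiff(species, config$reference)
  cnes <- list()
  for (sp in others) {
    aln <- if (nchar(ref_seq) == nchar(seqs[[sp]]))
      align_positional(ref_seq, seqs[[sp]], config$reference, sp)
    else global_align(ref_seq, seqs[[sp]], ref_species = config$reference,
                      other_species = sp)
    cnes[[sp]] <- call_cnes(aln, config$thresholds, coding_mask = mask)
    logf("stage cne: %s vs %s -> %d elements", config$reference, sp,
         nrow(cnes[[sp]]))
  }
  diag_sp <- unlist(config$diagnostic_species)
  ref_cnes <- classified <- NULL
  # reference CNE set: elements conserved with any non-diagnostic comparator,
  # classified by overlap with the diagnostic species' conserved intervals
  comparators <- setdiff(others, diag_sp)
  if (length(comparators) > 0) {
    pooled <- do.call(rbind, cnes[comparators])
    if (!is.null(pooled) && nrow(pooled) > 0) {
      pooled <- pooled[order(pooled$start), , drop = FALSE]
      keep <- rep(TRUE, nrow(pooled))
      last_end <- -1L
      for (i in seq_len(nrow(pooled))) {   # collapse duplicates across comparators
        if (pooled$start[i] < last_end) keep[i] <- FALSE
        else last_end <- pooled$end[i]
      }
      ref_cnes <- pooled[keep, , drop = FALSE]
    }
  }
  if (!is.null(ref_cnes) && nrow(ref_cnes) > 0) {
    classified <- classify_cne_groups(ref_cnes, config$diagnostic_species,
                                      per_species_hits = cnes)
    write_bed(data.frame(seq_id = classified$seq_id, start = classified$start,
                         end = classified$end, strand = ".",
                         name = classified$group,
                         score = round(classified$identity, 1)),
              file.path(out_dir, "cnes.bed"))
  }
  cne_table <- cne_summary_table(stats::setNames(
    list(if (is.null(classified)) data.frame(group = character()) else classified),
    "run"))
  put(cne_table, "cne_summary.tsv")

  # ---- stage 4: repeats ----
  repeats <- list()
  densities <- NULL
  for (sp in species) {
    rp <- find_repeat_pairs(seqs[[sp]], config$repeat_params)
    repeats[[sp]] <- rp
    arm_hits <- if (nrow(rp) == 0) empty_gi() else
      gi(sp, c(rp$arm1_start, rp$arm2_start), c(rp$arm1_end, rp$arm2_end))
    densities <- rbind(densities, data.frame(
      species = sp, n_pairs = nrow(rp),
      n_long_inverted = nrow(long_inverted_repeats(rp, config$repeat_params)),
      density = repeat_density(arm_hits, nchar(seqs[[sp]])),
      stringsAsFactors = FALSE))
    put(rp, paste0("repeats_", sp, ".tsv"))
    logf("stage repeats: %s -> %d pairs", sp, nrow(rp))
  }
  put(densities, "repeat_density.tsv")

  # ---- stage 5: relative rate tests over the exon-derived gene set ----
  rrt <- hasse <- pw <- genome <- NULL
  gene_alns <- NULL
  if (!is.null(config$sim) && !is.null(config$sim$exon_spec)) {
    ex <- config$sim$exon_spec
    gene_alns <- lapply(seq_len(nrow(ex)), function(i) {
      vapply(seqs, function(s)
        substr(s, ex$position[i] + 1, ex$position[i] + ex$length[i]),
        character(1))
    })
    names(gene_alns) <- paste0("exon", seq_len(nrow(ex)))
  } else if (!is.null(inputs$genes_dir)) {
    files <- list.files(inputs$genes_dir, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    gene_alns <- lapply(files, read_alignment)
    names(gene_alns) <- sub("\\.fa(sta)?$", "", basename(files))
  }
  if (!is.null(gene_alns) && length(config$ingroups) >= 2) {
    rrt <- rrt_battery(gene_alns, config$ingroups, config$outgroup)
    put(rrt, "rrt_results.tsv")
    hasse <- lapply(split(rrt, rrt$gene), build_hasse)
    for (g in names(hasse))
      writeLines(as_dot(hasse[[g]]), file.path(out_dir, paste0("hasse_", g, ".dot")))
    pw <- summarize_pairwise(rrt)
    put(pw, "rrt_pairwise_summary.tsv")
    if (length(config$ingroups) == 3) {
      genome <- genome_matrix(rrt, config$ingroups)
      put(genome$counts, "rrt_genome_counts.tsv")
      put(genome$summary, "rrt_genome_summary.tsv")
    }
    logf("stage rrt: %d tests over %d genes", nrow(rrt), length(gene_alns))
  }

  # ---- stage 6: tree summary ----
  folds <- NULL
  if (!is.null(inputs$tree)) {
    tr <- parse_newick(inputs$tree)
    lens <- data.frame(species = tr$tips,
                       terminal_branch_length = unname(tr$terminal_branch_length),
                       stringsAsFactors = FALSE)
    put(lens, "branch_lengths.tsv")
  }

  invisible(list(clusters = seqs, truth = truth, cnes = cnes,
                 classified = classified, cne_table = cne_table,
                 repeats = repeats, densities = densities, rrt = rrt,
                 hasse = hasse, pairwise_summary = pw, genome = genome))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
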