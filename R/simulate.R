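#' Simulation configuration for synthetic Hox-like clusters
#'
#' Describes a multi-species simulation: a fixed species tree with branch
#' lengths in expected substitutions/site, per-lineage rate multipliers
#' (applied to terminal branches), and planted elements — low-divergence CNEs
#' with clade-specific retention, strongly conserved exons, and
#' direct/inverted/interspersed repeats at known coordinates. Planted
#' elements must not overlap one another.
#'
#' @param tree Newick text with branch lengths (substitutions/site), or an
#'   `ape` `phylo` object.
#' @param seq_length cluster length in bp.
#' @param rate_multipliers named positive numeric vector, species -> rate
#'   multiplier on that species' terminal branch (default 1 for all tips).
#' @param cne_spec data frame with columns `position`, `length`,
#'   `scaling` (branch-length scaling in `(0,1]`; smaller = more conserved)
#'   and optionally `retained_in` (comma-separated species names; `NA` or
#'   missing column = retained in all species). Species not retaining a CNE
#'   have it replaced by freshly randomised sequence.
#' @param exon_spec data frame with columns `position`, `length`; exon sites
#'   evolve at 0.1 of the background rate.
#' @param repeat_spec data frame with columns `kind`
#'   (`direct`/`inverted`/`interspersed`), `arm_length`, `spacer_length`,
#'   `position`, `mutation_rate` and optionally `species` (comma-separated;
#'   `NA` = planted in every species). Repeats are written into each species'
#'   finished sequence independently, after tree simulation.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(tree, seq_length, rate_multipliers = NULL,
                              cne_spec = NULL, exon_spec = NULL,
                              repeat_spec = NULL, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("config error: tree must be Newick text or a phylo object")
  if (is.null(tree$edge.length)) stop("config error: tree must carry branch lengths")
  seq_length <- as.integer(seq_length)
  stopifnot(seq_length > 0)
  tips <- tree$tip.label
  if (is.null(rate_multipliers)) rate_multipliers <- stats::setNames(rep(1, length(tips)), tips)
  if (!all(names(rate_multipliers) %in% tips))
    stop("config error: rate_multipliers name a non-tip species")
  if (any(rate_multipliers <= 0)) stop("config error: rate multipliers must be positive")

  norm_spec <- function(x, cols) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0) return(NULL)
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    missing <- setdiff(cols, names(x))
    if (length(missing)) stop("config error: spec lacks columns ", paste(missing, collapse = ", "))
    x
  }
  cne_spec <- norm_spec(cne_spec, c("position", "length", "scaling"))
  exon_spec <- norm_spec(exon_spec, c("position", "length"))
  repeat_spec <- norm_spec(repeat_spec, c("kind", "arm_length", "spacer_length", "position"))
  if (!is.null(cne_spec)) {
    if (any(cne_spec$scaling <= 0 | cne_spec$scaling > 1))
      stop("config error: conservation scaling must be in (0, 1]")
    if (is.null(cne_spec$retained_in)) cne_spec$retained_in <- NA_character_
  }
  if (!is.null(repeat_spec)) {
    if (!all(repeat_spec$kind %in% c("direct", "inverted", "interspersed")))
      stop("config error: repeat kind must be direct, inverted or interspersed")
    if (is.null(repeat_spec$mutation_rate)) repeat_spec$mutation_rate <- 0
    if (is.null(repeat_spec$species)) repeat_spec$species <- NA_character_
    if (any(repeat_spec$arm_length < 1)) stop("config error: arm_length must be >= 1")
  }

  # footprints of all planted elements; they must fit and must not overlap
  fp <- rbind(
    if (!is.null(cne_spec)) cbind(cne_spec$position, cne_spec$position + cne_spec$length),
    if (!is.null(exon_spec)) cbind(exon_spec$position, exon_spec$position + exon_spec$length),
    if (!is.null(repeat_spec)) {
      len <- ifelse(repeat_spec$kind == "interspersed", repeat_spec$arm_length,
                    2L * repeat_spec$arm_length + repeat_spec$spacer_length)
      cbind(repeat_spec$position, repeat_spec$position + len)
    }
  )
  if (!is.null(fp) && nrow(fp) > 0) {
    if (any(fp[, 1] < 0) || any(fp[, 2] > seq_length))
      stop("config error: planted element outside [0, seq_length)")
    o <- order(fp[, 1])
    if (nrow(fp) > 1 && any(fp[o, 1][-1] < fp[o, 2][-nrow(fp)]))
      stop("config error: planted elements overlap")
  }

  structure(list(tree = tree, seq_length = seq_length,
                 rate_multipliers = rate_multipliers,
                 cne_spec = cne_spec, exon_spec = exon_spec,
                 repeat_spec = repeat_spec, seed = as.integer(seed)),
            class = "simulation_config")
}

# one Jukes-Cantor step along a branch: d is the per-site expected
# substitutions/site vector; returns new sequence and realized change count
jc_evolve <- function(seq_int, d) {
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- stats::runif(length(seq_int)) < p
  n_hit <- sum(hit)
  if (n_hit > 0) {
    off <- sample.int(3L, n_hit, replace = TRUE)
    seq_int[hit] <- ((seq_int[hit] - 1L + off) %% 4L) + 1L
  }
  list(seq = seq_int, nsub = n_hit)
}

#' Expected proportion of differing sites under Jukes-Cantor
#'
#' Closed form `(3/4)(1 - exp(-4 d / 3))` for the expected fraction of sites
#' differing between the two ends of a path of `d` expected
#' substitutions/site.
#'
#' @param d expected substitutions/site along the path.
#' @return expected proportion of differing sites.
#' @export
jc_expected_divergence <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Simulate multi-species clusters with known ground truth
#'
#' Draws a root sequence uniformly over `{A,C,G,T}` and evolves it down the
#' configured tree under the Jukes-Cantor model. Per-branch expected
#' substitutions/site are branch length times the lineage's rate multiplier
#' (terminal branches only); sites inside a planted CNE are additionally
#' scaled by its `conservation_scaling`, sites inside exons by 0.1. CNEs not
#' retained in a species are overwritten with fresh random sequence in that
#' species; repeats are written in post hoc, per species, with arms mutated
#' at their `mutation_rate`. Deterministic under a fixed config seed.
#'
#' @param config a [simulation_config()].
#' @return an object of class `ground_truth`: a list with `clusters` (named
#'   list of [annotated_cluster()]), `cne_truth` and `repeat_truth` data
#'   frames of planted coordinates per species, `substitutions` (realized
#'   substitution counts per branch), and the `config`.
#' @export
simulate_clusters <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_clusters_impl(config))
}

simulate_clusters_impl <- function(config) {
  tree <- config$tree
  L <- config$seq_length
  tips <- tree$tip.label
  n_tip <- length(tips)
  root <- n_tip + 1L

  # per-site branch-length scaling from planted conserved elements
  sc <- rep(1, L)
  if (!is.null(config$exon_spec)) {
    for (i in seq_len(nrow(config$exon_spec))) {
      e <- config$exon_spec[i, ]
      sc[(e$position + 1):(e$position + e$length)] <- 0.1
    }
  }
  if (!is.null(config$cne_spec)) {
    for (i in seq_len(nrow(config$cne_spec))) {
      cn <- config$cne_spec[i, ]
      sc[(cn$position + 1):(cn$position + cn$length)] <- cn$scaling
    }
  }

  mult <- stats::setNames(rep(1, max(tree$edge)), NULL)
  mult[match(names(config$rate_multipliers), tips)] <- config$rate_multipliers

  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  # preorder traversal: ape edge matrix reordered so parents precede children
  ord <- stats::reorder(tree, "cladewise")
  subs <- data.frame(parent = ord$edge[, 1], child = ord$edge[, 2],
                     label = NA_character_, n_substitutions = NA_integer_)
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chd <- ord$edge[k, 2]
    m <- if (chd <= n_tip) mult[chd] else 1
    d <- ord$edge.length[k] * m * sc
    st <- jc_evolve(seqs[[par]], d)
    seqs[[chd]] <- st$seq
    subs$label[k] <- if (chd <= n_tip) tips[chd] else paste0("node", chd)
    subs$n_substitutions[k] <- st$nsub
  }

  clusters <- list()
  cne_truth <- NULL
  repeat_truth <- NULL
  for (sp_i in seq_len(n_tip)) {
    sp <- tips[sp_i]
    s <- seqs[[sp_i]]
    feats <- empty_gi(); feats$kind <- character()

    if (!is.null(config$cne_spec)) {
      for (i in seq_len(nrow(config$cne_spec))) {
        cn <- config$cne_spec[i, ]
        retained <- is.na(cn$retained_in) ||
          sp %in% trimws(strsplit(cn$retained_in, ",")[[1]])
        if (!retained) {
          s[(cn$position + 1):(cn$position + cn$length)] <-
            sample.int(4L, cn$length, replace = TRUE)
        } else {
          cne_truth <- rbind(cne_truth, data.frame(
            species = sp, start = cn$position, end = cn$position + cn$length,
            scaling = cn$scaling, stringsAsFactors = FALSE))
        }
      }
    }

    if (!is.null(config$exon_spec)) {
      for (i in seq_len(nrow(config$exon_spec))) {
        e <- config$exon_spec[i, ]
        feats <- rbind(feats, data.frame(seq_id = sp, start = e$position,
                                         end = e$position + e$length,
                                         strand = "+", kind = "exon",
                                         stringsAsFactors = FALSE))
      }
    }

    if (!is.null(config$repeat_spec)) {
      for (i in seq_len(nrow(config$repeat_spec))) {
        rp <- config$repeat_spec[i, ]
        applies <- is.na(rp$species) || sp %in% trimws(strsplit(rp$species, ",")[[1]])
        if (!applies) next
        pl <- plant_repeat_impl(int_to_seq(s), rp$kind, rp$arm_length,
                                rp$spacer_length, rp$position, rp$mutation_rate)
        s <- seq_to_int(pl$sequence)
        if (!is.null(pl$pair)) {
          repeat_truth <- rbind(repeat_truth, cbind(species = sp, pl$pair))
          feats <- rbind(feats,
                         data.frame(seq_id = sp,
                                    start = c(pl$pair$arm1_start, pl$pair$arm2_start),
                                    end = c(pl$pair$arm1_end, pl$pair$arm2_end),
                                    strand = "+", kind = "repeat",
                                    stringsAsFactors = FALSE))
        } else {
          feats <- rbind(feats, data.frame(seq_id = sp, start = rp$position,
                                           end = rp$position + rp$arm_length,
                                           strand = "+", kind = "repeat",
                                           stringsAsFactors = FALSE))
        }
      }
    }

    clusters[[sp]] <- annotated_cluster(sp, "other", int_to_seq(s), feats)
  }

  structure(list(clusters = clusters, cne_truth = cne_truth,
                 repeat_truth = repeat_truth, substitutions = subs,
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic cluster set:", length(x$clusters), "species x",
      x$config$seq_length, "bp\n")
  cat("  planted CNEs:", if (is.null(x$cne_truth)) 0 else nrow(x$cne_truth),
      " repeats:", if (is.null(x$repeat_truth)) 0 else nrow(x$repeat_truth), "\n")
  invisible(x)
}

# Make a freshly planted repeat pair locally maximal on its own diagonal,
# so the planted coordinates ARE the ground truth an ungapped finder should
# report: flanking/spacer bases whose diagonal partner would extend the arm
# match are resampled to mismatch. Only non-arm positions are touched.
# Positions are 1-based here; b1/e1 and b2/e2 are the arm bounds (closed).
guard_repeat_flanks <- function(s, kind, b1, e1, b2, e2, spacer_length) {
  n <- length(s)
  pick_not <- function(forbidden) {
    # uniform over the three bases different from `forbidden`
    v <- sample.int(3L, length(forbidden), replace = TRUE)
    ((forbidden - 1L + v) %% 4L) + 1L
  }
  if (kind == "direct") {
    d <- b2 - b1
    for (j in seq_len(spacer_length)) {
      y <- e1 + j + d              # beyond arm2; pairs with spacer base e1+j
      if (y <= n) s[y] <- pick_not(s[e1 + j])
      x <- b1 - j                  # before arm1; pairs with s[x + d]
      if (x >= 1) s[x] <- pick_not(s[x + d])
    }
  } else {
    C <- b1 + e2                   # anti-diagonal constant
    # inner: spacer columns pair among themselves
    xs <- seq_len(max(0L, (C - 1L) %/% 2L - e1))
    for (j in xs) {
      x <- e1 + j
      s[x] <- pick_not(5L - s[C - x])
    }
    # outer: far enough that the identity X-drop gives up first
    G <- max(150L, e1 - b1 + 2L)
    for (j in seq_len(G)) {
      x <- b1 - j
      y <- C - x                   # beyond arm2 end
      if (x < 1 || y > n) break
      s[y] <- pick_not(5L - s[x])
    }
  }
  s
}

# core repeat planting: overwrites sequence in place; 0-based position
plant_repeat_impl <- function(sequence, kind, arm_length, spacer_length,
                              position, mutation_rate = 0) {
  n <- nchar(sequence)
  arm_length <- as.integer(arm_length)
  spacer_length <- as.integer(spacer_length)
  position <- as.integer(position)
  if (arm_length < 1) stop("config error: arm_length must be >= 1")
  if (spacer_length < 0) stop("config error: spacer_length must be >= 0")
  footprint <- if (kind == "interspersed") arm_length
               else 2L * arm_length + spacer_length
  if (position < 0 || position + footprint > n)
    stop("config error: repeat insertion out of bounds")

  mutate <- function(v) {
    if (mutation_rate <= 0) return(v)
    hit <- stats::runif(length(v)) < mutation_rate
    n_hit <- sum(hit)
    if (n_hit > 0) {
      off <- sample.int(3L, n_hit, replace = TRUE)
      v[hit] <- ((v[hit] - 1L + off) %% 4L) + 1L
    }
    v
  }

  s <- seq_to_int(sequence)
  arm <- sample.int(4L, arm_length, replace = TRUE)
  if (kind == "interspersed") {
    s[(position + 1):(position + arm_length)] <- mutate(arm)
    return(list(sequence = int_to_seq(s), pair = NULL))
  }
  arm1 <- mutate(arm)
  arm2 <- if (kind == "inverted") rev(int_complement(mutate(arm))) else mutate(arm)
  if (spacer_length > 0)
    s[(position + arm_length + 1):(position + arm_length + spacer_length)] <-
      sample.int(4L, spacer_length, replace = TRUE)
  s[(position + 1):(position + arm_length)] <- arm1
  a2 <- position + arm_length + spacer_length
  s[(a2 + 1):(a2 + arm_length)] <- arm2
  s <- guard_repeat_flanks(s, kind, position + 1L, position + arm_length,
                           a2 + 1L, a2 + arm_length, spacer_length)
  oriented2 <- if (kind == "inverted") rev(int_complement(arm2)) else arm2
  pair <- data.frame(
    arm1_start = position, arm1_end = position + arm_length,
    arm2_start = a2, arm2_end = a2 + arm_length,
    orientation = kind, arm_identity = 100 * mean(arm1 == oriented2),
    arm_length = arm_length, spacer = spacer_length,
    stringsAsFactors = FALSE
  )
  list(sequence = int_to_seq(s), pair = pair)
}

#' Plant an inverted repeat into a sequence
#'
#' Writes `arm`, a random spacer, and the reverse complement of `arm` into
#' the sequence starting at `position` (in place; the sequence keeps its
#' length) and returns the exact planted coordinates. The second arm equals
#' the reverse complement of the first before any mutation.
#'
#' @param sequence nucleotide string.
#' @param arm_length arm length in bp (>= 1).
#' @param spacer_length spacer between the arms in bp (>= 0).
#' @param position 0-based insertion offset; the footprint
#'   `2 * arm_length + spacer_length` must fit within the sequence.
#' @param seed integer seed.
#' @param mutation_rate per-base substitution probability applied to each arm
#'   copy independently (default 0 = perfect arms).
#' @return a list with `sequence` (modified string) and `pair` (a one-row
#'   repeat-pair data frame: arm intervals, orientation, identity, spacer).
#' @export
plant_inverted_repeat <- function(sequence, arm_length, spacer_length,
                                  position, seed = 1L, mutation_rate = 0) {
  with_seed(seed, plant_repeat_impl(sequence, "inverted", arm_length,
                                    spacer_length, position, mutation_rate))
}

#' Plant a direct repeat into a sequence
#'
#' As [plant_inverted_repeat()] but the second arm is a same-orientation copy
#' of the first.
#'
#' @inheritParams plant_inverted_repeat
#' @return a list with `sequence` and `pair` as in [plant_inverted_repeat()].
#' @export
plant_direct_repeat <- function(sequence, arm_length, spacer_length,
                                position, seed = 1L, mutation_rate = 0) {
  with_seed(seed, plant_repeat_impl(sequence, "direct", arm_length,
                                    spacer_length, position, mutation_rate))
}

#' Simulate aligned gene triplets under lineage-specific rates
#'
#' Convenience generator for relative-rate-test studies: for each gene an
#' ancestral sequence is drawn and evolved to two ingroups and an outgroup
#' under Jukes-Cantor, with the ingroup branch lengths scaled by per-lineage
#' rate multipliers. Because the model has no indels the raw sequences are
#' already aligned.
#'
#' @param n_genes number of genes.
#' @param n_sites sites per gene.
#' @param rate_a,rate_b rate multipliers for the two ingroup branches.
#' @param d_ingroup base ingroup branch length (expected substitutions/site;
#'   default 0.1).
#' @param d_outgroup outgroup branch length from the ingroup ancestor
#'   (default 0.3).
#' @param seed integer seed.
#' @return a list of length `n_genes`; each element is a
#'   [triplet_alignment()] with rows `A`, `B`, `O`.
#' @export
simulate_gene_triplets <- function(n_genes, n_sites, rate_a = 1, rate_b = 1,
                                   d_ingroup = 0.1, d_outgroup = 0.3,
                                   seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      anc <- sample.int(4L, n_sites, replace = TRUE)
      a <- jc_evolve(anc, rep(d_ingroup * rate_a, n_sites))$seq
      b <- jc_evolve(anc, rep(d_ingroup * rate_b, n_sites))$seq
      o <- jc_evolve(anc, rep(d_outgroup, n_sites))$seq
      triplet_alignment(paste0("gene", g), int_to_seq(a), int_to_seq(b),
                        int_to_seq(o), alphabet = "nucleotide")
    })
  })
}
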