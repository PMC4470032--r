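#' Aligned triplet for a relative rate test
#'
#' Two ingroup sequences and one outgroup sequence from the same gene
#' alignment, as equal-length residue strings.
#'
#' @param gene gene label.
#' @param ingroup_a,ingroup_b,outgroup equal-length aligned strings.
#' @param alphabet `"nucleotide"` or `"protein"`; controls which symbols are
#'   treated as ambiguous by [strip_ambiguous_columns()].
#' @param species_a,species_b,species_out optional species labels.
#' @return an object of class `triplet_alignment`.
#' @export
triplet_alignment <- function(gene, ingroup_a, ingroup_b, outgroup,
                              alphabet = c("nucleotide", "protein"),
                              species_a = "A", species_b = "B",
                              species_out = "outgroup") {
  alphabet <- match.arg(alphabet)
  lens <- c(nchar(ingroup_a), nchar(ingroup_b), nchar(outgroup))
  if (length(unique(lens)) != 1L)
    stop("usage error: triplet rows must have equal length")
  structure(list(gene = gene,
                 ingroup_a = toupper(ingroup_a),
                 ingroup_b = toupper(ingroup_b),
                 outgroup = toupper(outgroup),
                 alphabet = alphabet,
                 species_a = species_a, species_b = species_b,
                 species_out = species_out),
            class = "triplet_alignment")
}

ambiguous_symbols <- function(alphabet) {
  gaps <- c("-", ".", "?")
  if (alphabet == "nucleotide") c(gaps, "N") else c(gaps, "X", "B", "Z", "J", "*")
}

#' Remove alignment columns with gaps or ambiguous residues
#'
#' Complete deletion: every column containing a gap character or an
#' ambiguity symbol (`N` for nucleotide; `X`, `B`, `Z`, `J` for protein) in
#' any of the three rows is removed before testing.
#'
#' @param triplet a [triplet_alignment()].
#' @return the stripped `triplet_alignment` (possibly zero columns).
#' @export
strip_ambiguous_columns <- function(triplet) {
  stopifnot(inherits(triplet, "triplet_alignment"))
  rows <- lapply(triplet[c("ingroup_a", "ingroup_b", "outgroup")],
                 function(x) strsplit(x, "", fixed = TRUE)[[1]])
  bad_sym <- ambiguous_symbols(triplet$alphabet)
  keep <- !(rows[[1]] %in% bad_sym | rows[[2]] %in% bad_sym | rows[[3]] %in% bad_sym)
  out <- triplet
  out$ingroup_a <- paste(rows[[1]][keep], collapse = "")
  out$ingroup_b <- paste(rows[[2]][keep], collapse = "")
  out$outgroup <- paste(rows[[3]][keep], collapse = "")
  out
}

#' Tajima's relative rate test
#'
#' Counts the sites where exactly one ingroup carries a unique residue:
#' `m_a` is the number of columns where ingroup A differs from both ingroup B
#' and the outgroup while B equals the outgroup, and `m_b` symmetrically.
#' Under rate constancy the two counts have equal expectation, and
#' `(m_a - m_b)^2 / (m_a + m_b)` is asymptotically chi-square with one degree
#' of freedom. No continuity correction is applied. When `m_a + m_b = 0` the
#' test is uninformative and `p = 1`.
#'
#' The triplet should already be stripped of gap/ambiguous columns
#' ([strip_ambiguous_columns()]); this is applied here defensively if any
#' ambiguous symbols remain.
#'
#' @param triplet a [triplet_alignment()].
#' @return an object of class `tajima_rrt`: gene, species labels,
#'   `n_sites_used`, `m_a`, `m_b`, `chi2`, `p` and a `significance` tier
#'   (`"high"` for p <= 0.01, `"significant"` for 0.01 < p <= 0.05,
#'   `"ns"` otherwise).
#' @examples
#' tr <- triplet_alignment("g", "ACGTACGTTT", "ACGAACGTTT", "ACGAACGTTT")
#' tajima_rrt(tr)
#' @export
tajima_rrt <- function(triplet) {
  stopifnot(inherits(triplet, "triplet_alignment"))
  bad <- ambiguous_symbols(triplet$alphabet)
  if (any(strsplit(paste0(triplet$ingroup_a, triplet$ingroup_b, triplet$outgroup),
                   "", fixed = TRUE)[[1]] %in% bad))
    triplet <- strip_ambiguous_columns(triplet)
  a <- strsplit(triplet$ingroup_a, "", fixed = TRUE)[[1]]
  b <- strsplit(triplet$ingroup_b, "", fixed = TRUE)[[1]]
  o <- strsplit(triplet$outgroup, "", fixed = TRUE)[[1]]
  m_a <- sum(b == o & a != b)
  m_b <- sum(a == o & b != a)
  chi2 <- if (m_a + m_b > 0) (m_a - m_b)^2 / (m_a + m_b) else 0
  p <- if (m_a + m_b > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  structure(list(gene = triplet$gene,
                 species_a = triplet$species_a, species_b = triplet$species_b,
                 outgroup = triplet$species_out,
                 n_sites_used = length(a), m_a = m_a, m_b = m_b,
                 chi2 = chi2, p = p,
                 significance = significance_tier(p),
                 degenerate = length(a) == 0L),
            class = "tajima_rrt")
}

significance_tier <- function(p) {
  ifelse(p <= 0.01, "high", ifelse(p <= 0.05, "significant", "ns"))
}

#' @export
print.tajima_rrt <- function(x, ...) {
  cat("\n\tTajima relative rate test\n\n")
  cat("gene:", x$gene, "  ingroups:", x$species_a, "vs", x$species_b,
      "  outgroup:", x$outgroup, "\n")
  cat("sites used:", x$n_sites_used,
      "  unique substitutions:", x$species_a, "=", x$m_a, ",",
      x$species_b, "=", x$m_b, "\n")
  cat(sprintf("chi-squared = %.4f, df = 1, p-value = %.4g [%s]\n",
              x$chi2, x$p, x$significance))
  if (x$m_a != x$m_b && x$significance != "ns")
    cat("slower lineage:", if (x$m_a < x$m_b) x$species_a else x$species_b, "\n")
  invisible(x)
}

as_rrt_row <- function(x) {
  data.frame(gene = x$gene, species_a = x$species_a, species_b = x$species_b,
             outgroup = x$outgroup, n_sites_used = x$n_sites_used,
             m_a = x$m_a, m_b = x$m_b, chi2 = x$chi2, p = x$p,
             significance = x$significance, stringsAsFactors = FALSE)
}

#' Run relative rate tests over a gene set and species panel
#'
#' For every gene and every unordered pair of ingroup species present in
#' that gene's alignment, builds the triplet with the outgroup, strips
#' gap/ambiguous columns, and runs [tajima_rrt()]. Genes lacking the
#' outgroup, or with fewer than two ingroups, are skipped with a message
#' (mirrors swapping species panels for genes missing from some lineages).
#'
#' @param alignments named list, gene -> named character vector of
#'   equal-length aligned sequences (names are species).
#' @param ingroups character vector of ingroup species.
#' @param outgroup single outgroup species.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return a data frame, one row per (gene, species pair), ordered by gene
#'   then pair: `gene`, `species_a`, `species_b`, `outgroup`,
#'   `n_sites_used`, `m_a`, `m_b`, `chi2`, `p`, `significance`.
#' @export
rrt_battery <- function(alignments, ingroups, outgroup,
                        alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(outgroup) == 1L, length(ingroups) >= 2L)
  rows <- list()
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    if (!outgroup %in% names(aln)) {
      message("skipping gene '", gene, "': outgroup ", outgroup, " absent")
      next
    }
    present <- sort(intersect(ingroups, names(aln)))
    if (length(present) < 2L) {
      message("skipping gene '", gene, "': fewer than two ingroups present")
      next
    }
    prs <- utils::combn(present, 2L)
    for (j in seq_len(ncol(prs))) {
      tr <- triplet_alignment(gene, aln[[prs[1, j]]], aln[[prs[2, j]]],
                              aln[[outgroup]], alphabet,
                              species_a = prs[1, j], species_b = prs[2, j],
                              species_out = outgroup)
      rows[[length(rows) + 1L]] <- as_rrt_row(tajima_rrt(strip_ambiguous_columns(tr)))
    }
  }
  if (length(rows) == 0)
    return(as_rrt_row(tajima_rrt(triplet_alignment("x", "A", "A", "A")))[0, ])
  out <- do.call(rbind, rows)
  out[order(out$gene, out$species_a, out$species_b), , drop = FALSE]
}

# boolean reachability closure (Warshall); m is a logical adjacency matrix
transitive_closure_bool <- function(m) {
  n <- nrow(m)
  for (k in seq_len(n)) m <- m | (m[, k] %o% m[k, ] > 0)
  m
}

# transitive reduction of a DAG given as a logical adjacency matrix:
# keep edge (u,v) iff there is no path u -> v through an intermediate node
transitive_reduction_bool <- function(m) {
  cl <- transitive_closure_bool(m)
  red <- m
  n <- nrow(m)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (!m[u, v]) next
    via <- any(m[u, ] & cl[, v] & seq_len(n) != u & seq_len(n) != v)
    if (via) red[u, v] <- FALSE
  }
  red
}

has_cycle <- function(m) {
  cl <- transitive_closure_bool(m)
  any(diag(cl))
}

#' Build a Hasse diagram of relative evolutionary rates
#'
#' Synthesises the pairwise relative rate tests for one gene into a partial
#' order: a directed edge runs from the faster to the slower lineage for
#' every test with `p <= 0.05` (the lineage with fewer unique substitutions
#' is the slower one), tiered `high` at `p <= 0.01` and `significant` in
#' `(0.01, 0.05]`. The reduced edge set is the transitive reduction;
#' non-significant pairs stay incomparable. Should the significant edges ever
#' form a cycle (possible only through three or more pairwise tests), the
#' weakest edges (largest p) are dropped with a warning until acyclic.
#'
#' @param results a data frame of [rrt_battery()] rows for a single gene, or
#'   a list of `tajima_rrt` objects.
#' @return an object of class `hasse_diagram`: `nodes`, `edges` (columns
#'   `slower`, `faster`, `significance`, `p`) and `reduced_edges`.
#' @export
build_hasse <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as_rrt_row))
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  if (length(unique(results$gene)) != 1L)
    stop("usage error: build_hasse takes results for a single gene")
  nodes <- sort(unique(c(results$species_a, results$species_b)))
  sig <- results[results$p <= 0.05 & (results$m_a != results$m_b), , drop = FALSE]
  edges <- data.frame(slower = character(), faster = character(),
                      significance = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) > 0) {
    slower <- ifelse(sig$m_a < sig$m_b, sig$species_a, sig$species_b)
    faster <- ifelse(sig$m_a < sig$m_b, sig$species_b, sig$species_a)
    edges <- data.frame(slower = slower, faster = faster,
                        significance = significance_tier(sig$p), p = sig$p,
                        stringsAsFactors = FALSE)
  }
  # adjacency faster -> slower
  n <- length(nodes)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) m[edges$faster[i], edges$slower[i]] <- TRUE
  while (has_cycle(m)) {
    warning("contradictory significant rate ordering; dropping weakest edge")
    worst <- which.max(edges$p)
    m[edges$faster[worst], edges$slower[worst]] <- FALSE
    edges <- edges[-worst, , drop = FALSE]
  }
  red <- transitive_reduction_bool(m)
  keep <- vapply(seq_len(nrow(edges)),
                 function(i) red[edges$faster[i], edges$slower[i]], logical(1))
  structure(list(gene = results$gene[1], nodes = nodes, edges = edges,
                 reduced_edges = edges[keep, , drop = FALSE]),
            class = "hasse_diagram")
}

#' @export
print.hasse_diagram <- function(x, ...) {
  cat("Hasse diagram of relative rates, gene:", x$gene, "\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$reduced_edges) == 0) {
    cat("  no significant orderings\n")
  } else {
    for (i in seq_len(nrow(x$reduced_edges))) {
      e <- x$reduced_edges[i, ]
      cat(sprintf("  %s %s %s (p = %.3g)\n", e$slower,
                  if (e$significance == "high") "<<" else "<", e$faster, e$p))
    }
  }
  invisible(x)
}

#' Render a Hasse diagram as Graphviz DOT text
#'
#' Solid edges mark highly significant orderings (p <= 0.01), dashed edges
#' significant ones (0.01 < p <= 0.05); arrows point from faster to slower.
#'
#' @param x a `hasse_diagram`.
#' @return a character scalar of DOT source.
#' @export
as_dot <- function(x) {
  stopifnot(inherits(x, "hasse_diagram"))
  lines <- c(sprintf("digraph \"%s\" {", x$gene),
             paste0("  \"", x$nodes, "\";"))
  if (nrow(x$reduced_edges) > 0) {
    style <- ifelse(x$reduced_edges$significance == "high", "solid", "dashed")
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [style=%s];",
                              x$reduced_edges$faster, x$reduced_edges$slower,
                              style))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Summarise pairwise relative rate tests across genes
#'
#' Per cluster (or overall) and species pair: how many genes are
#' significantly slower in each direction at each tier, and the fraction of
#' genes in which each side is the slower one at `p <= 0.05`.
#'
#' @param results an [rrt_battery()] data frame; an optional `cluster` column
#'   groups genes (otherwise all genes form one group).
#' @param clusters optional named vector gene -> cluster label.
#' @return a data frame with one row per (cluster, species pair):
#'   `n_genes`, counts `a_slower_high`, `a_slower_sig`, `b_slower_high`,
#'   `b_slower_sig`, and fractions `frac_a_slower`, `frac_b_slower`.
#' @export
summarize_pairwise <- function(results, clusters = NULL) {
  stopifnot(is.data.frame(results))
  if (!is.null(clusters)) results$cluster <- unname(clusters[results$gene])
  if (is.null(results$cluster)) results$cluster <- "all"
  key <- interaction(results$cluster, results$species_a, results$species_b,
                     drop = TRUE)
  out <- lapply(split(results, key), function(d) {
    a_slower <- d$p <= 0.05 & d$m_a < d$m_b
    b_slower <- d$p <= 0.05 & d$m_b < d$m_a
    data.frame(cluster = d$cluster[1], species_a = d$species_a[1],
               species_b = d$species_b[1], n_genes = nrow(d),
               a_slower_high = sum(a_slower & d$p <= 0.01),
               a_slower_sig = sum(a_slower & d$p > 0.01),
               b_slower_high = sum(b_slower & d$p <= 0.01),
               b_slower_sig = sum(b_slower & d$p > 0.01),
               frac_a_slower = mean(a_slower),
               frac_b_slower = mean(b_slower),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cluster, out$species_a, out$species_b), , drop = FALSE]
}

#' Genome-wide significance matrix for three ingroup species
#'
#' For a three-species ingroup design, tallies for every species how many
#' genes place it significantly slower or faster than each of the other two,
#' at both significance tiers, plus summary percentages: the share of genes
#' in which the species is slower than at least one other ingroup
#' (`pct_slower_either`) and slower than both (`pct_slower_both`).
#'
#' @param results an [rrt_battery()] data frame covering all three unordered
#'   pairs of `ingroups`.
#' @param ingroups exactly three ingroup species.
#' @return a list with `counts` (data frame: `species`, `versus`,
#'   `slower_high`, `slower_sig`, `faster_high`, `faster_sig`) and `summary`
#'   (data frame: `species`, `n_genes`, `pct_slower_either`,
#'   `pct_slower_both`, `pct_faster_either`, `pct_faster_both`).
#' @export
genome_matrix <- function(results, ingroups) {
  if (length(ingroups) != 3L)
    stop("usage error: genome_matrix requires exactly 3 ingroup species")
  stopifnot(is.data.frame(results))
  results <- results[results$species_a %in% ingroups &
                       results$species_b %in% ingroups, , drop = FALSE]
  genes <- unique(results$gene)
  slower_of <- function(d) ifelse(d$m_a < d$m_b, d$species_a, d$species_b)
  faster_of <- function(d) ifelse(d$m_a < d$m_b, d$species_b, d$species_a)

  counts <- NULL
  for (sp in ingroups) for (ot in setdiff(ingroups, sp)) {
    d <- results[(results$species_a == sp & results$species_b == ot) |
                   (results$species_a == ot & results$species_b == sp), ,
                 drop = FALSE]
    sig <- d$p <= 0.05 & d$m_a != d$m_b
    sl <- slower_of(d)
    counts <- rbind(counts, data.frame(
      species = sp, versus = ot,
      slower_high = sum(sig & d$p <= 0.01 & sl == sp),
      slower_sig = sum(sig & d$p > 0.01 & sl == sp),
      faster_high = sum(sig & d$p <= 0.01 & sl == ot),
      faster_sig = sum(sig & d$p > 0.01 & sl == ot),
      stringsAsFactors = FALSE))
  }

  summary <- NULL
  for (sp in ingroups) {
    d <- results[results$species_a == sp | results$species_b == sp, , drop = FALSE]
    sig <- d$p <= 0.05 & d$m_a != d$m_b
    sl_gene <- split(sig & slower_of(d) == sp, d$gene)
    fa_gene <- split(sig & faster_of(d) == sp, d$gene)
    slower_n <- vapply(sl_gene, sum, numeric(1))
    faster_n <- vapply(fa_gene, sum, numeric(1))
    summary <- rbind(summary, data.frame(
      species = sp, n_genes = length(genes),
      pct_slower_either = 100 * sum(slower_n >= 1) / length(genes),
      pct_slower_both = 100 * sum(slower_n == 2) / length(genes),
      pct_faster_either = 100 * sum(faster_n >= 1) / length(genes),
      pct_faster_both = 100 * sum(faster_n == 2) / length(genes),
      stringsAsFactors = FALSE))
  }
  list(counts = counts, summary = summary)
}
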