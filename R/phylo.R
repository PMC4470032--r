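#' Parse a Newick species tree
#'
#' Extracts the tip set and the terminal (tip-side) branch lengths from
#' Newick text or a file; the internal topology is retained for display.
#' Trees without branch lengths parse, but any query through
#' [branch_fold()] on a length-less tip is an error.
#'
#' @param text Newick text, a path to a Newick file, or a `phylo` object.
#' @return an object of class `species_tree`: `phylo`, `tips`,
#'   `terminal_branch_length` (named numeric, `NA` when absent).
#' @examples
#' parse_newick("(frog:0.34,caecilian:0.13);")
#' @export
parse_newick <- function(text) {
  tr <- if (inherits(text, "phylo")) {
    text
  } else if (length(text) == 1L && file.exists(text)) {
    tryCatch(suppressWarnings(ape::read.tree(text)), error = function(e)
      stop("Newick format error: ", conditionMessage(e), call. = FALSE))
  } else {
    tryCatch(suppressWarnings(ape::read.tree(text = text)), error = function(e)
      stop("Newick format error: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick format error: could not parse tree")
  tips <- tr$tip.label
  term <- stats::setNames(rep(NA_real_, length(tips)), tips)
  if (!is.null(tr$edge.length)) {
    tip_edges <- match(seq_along(tips), tr$edge[, 2])
    term[] <- tr$edge.length[tip_edges]
  }
  if (any(!is.na(term) & term < 0))
    stop("Newick format error: negative branch length")
  structure(list(phylo = tr, tips = tips, terminal_branch_length = term),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree with", length(x$tips), "tips\n")
  lens <- x$terminal_branch_length
  for (tp in x$tips)
    cat(sprintf("  %s: %s\n", tp,
                if (is.na(lens[tp])) "(no length)" else format(lens[tp])))
  invisible(x)
}

#' Terminal branch-length fold difference between two lineages
#'
#' Ratio of the two species' terminal branch lengths (substitutions/site),
#' rounded half-up — the per-lineage rate comparison behind statements such
#' as one lineage's branch being 2.6-fold longer than another's
#' (0.34 vs 0.13). Root-to-tip sums are available via `from_root = TRUE`.
#'
#' @param tree a [parse_newick()] tree.
#' @param numerator,denominator tip species names.
#' @param decimals decimal places for half-up rounding (default 1).
#' @param from_root use root-to-tip path lengths instead of terminal
#'   branches.
#' @return the rounded fold difference.
#' @examples
#' branch_fold(parse_newick("(frog:0.34,caecilian:0.13);"), "frog", "caecilian")
#' @export
branch_fold <- function(tree, numerator, denominator, decimals = 1,
                        from_root = FALSE) {
  stopifnot(inherits(tree, "species_tree"))
  for (sp in c(numerator, denominator))
    if (!sp %in% tree$tips) stop("usage error: '", sp, "' is not a tip")
  if (from_root) {
    if (is.null(tree$phylo$edge.length))
      stop("Newick format error: tree has no branch lengths")
    depths <- ape::node.depth.edgelength(tree$phylo)
    num <- depths[match(numerator, tree$tips)]
    den <- depths[match(denominator, tree$tips)]
  } else {
    num <- tree$terminal_branch_length[numerator]
    den <- tree$terminal_branch_length[denominator]
  }
  if (is.na(num) || is.na(den))
    stop("Newick format error: queried tip has no branch length")
  if (den == 0) stop("usage error: zero denominator branch length")
  unname(round_half_up(num / den, decimals))
}
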