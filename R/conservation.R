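#' Conservation thresholds for CNE calling
#'
#' The defaults are the classical VISTA-style cutoff used for vertebrate Hox
#' comparisons: at least 65 percent identity over windows of at least 50
#' reference bases.
#'
#' @param min_identity minimum percent identity (0, 100].
#' @param min_length minimum element length in reference bases (>= 1); also
#'   the scan window size in alignment columns.
#' @return an object of class `conservation_thresholds`.
#' @export
conservation_thresholds <- function(min_identity = 65, min_length = 50) {
  if (!(min_identity > 0 && min_identity <= 100))
    stop("config error: min_identity must be in (0, 100]")
  if (min_length < 1) stop("config error: min_length must be >= 1")
  structure(list(min_identity = min_identity, min_length = as.integer(min_length)),
            class = "conservation_thresholds")
}

# per-column match indicator: both rows carry the same unambiguous base;
# gap or N columns count as mismatches
column_matches <- function(aln) {
  rc <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  oc <- strsplit(aln$other_aln, "", fixed = TRUE)[[1]]
  rc %in% c("A", "C", "G", "T") & rc == oc
}

#' Windowed percent identity along an alignment
#'
#' For every window start, the percentage of columns in which both rows
#' carry the same non-gap, non-N base. Gap and N columns count as
#' mismatches.
#'
#' @param aln a [pairwise_alignment()].
#' @param window window size in alignment columns.
#' @return numeric vector of length `ncol - window + 1` of percent
#'   identities per window start.
#' @export
windowed_identity <- function(aln, window) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  window <- as.integer(window)
  if (window < 1) stop("usage error: window must be >= 1")
  m <- column_matches(aln)
  L <- length(m)
  if (window > L) stop("usage error: window exceeds alignment length")
  cs <- cumsum(c(0L, m))
  100 * (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
}

#' Call conserved noncoding elements from a pairwise alignment
#'
#' Seed-merge-trim procedure: every window of `min_length` columns with
#' identity at or above `min_identity` percent seeds a call; overlapping
#' passing windows are merged; merged intervals are trimmed so they start
#' and end on matching columns; an interval is kept when it still spans at
#' least `min_length` reference bases and its overall column identity is at
#' least `min_identity`. Intervals overlapping the coding mask are cut down
#' to their noncoding remainder (re-trimmed and re-checked) and dropped when
#' too short. Output intervals are sorted, non-overlapping, in reference
#' coordinates.
#'
#' @param aln a [pairwise_alignment()].
#' @param thresholds a [conservation_thresholds()].
#' @param coding_mask optional interval data frame in reference coordinates
#'   (exons/coding sequence to exclude).
#' @param gene_spans optional interval data frame of gene extents in
#'   reference coordinates; CNEs inside a gene span but outside the coding
#'   mask are flagged `in_intron`.
#' @return a data frame of CNE records: `seq_id`, `start`, `end` (reference,
#'   0-based half-open), `identity` (percent over the alignment columns),
#'   `aln_span` (columns), `group` (initially `"unassigned"`), `in_intron`.
#' @export
call_cnes <- function(aln, thresholds = conservation_thresholds(),
                      coding_mask = NULL, gene_spans = NULL) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(thresholds, "conservation_thresholds"))
  m <- column_matches(aln)
  L <- length(m)
  w <- thresholds$min_length
  min_frac <- thresholds$min_identity / 100
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      identity = numeric(), aln_span = integer(),
                      group = character(), in_intron = logical(),
                      stringsAsFactors = FALSE)
  if (L < w) return(empty)

  cs <- cumsum(c(0L, m))
  win_id <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  pass <- which(win_id >= min_frac)
  if (length(pass) == 0) return(empty)

  # union of covered columns via a difference array
  d <- integer(L + 1L)
  d[pass] <- d[pass] + 1L
  d[pass + w] <- d[pass + w] - 1L
  covered <- cumsum(d[seq_len(L)]) > 0L

  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  refmap <- aln$ref_coord_map
  recs <- list()
  for (i in seq_len(nrow(runs))) {
    span <- trim_to_matches(runs[i, 1], runs[i, 2], m)
    if (is.null(span)) next
    rec <- span_record(span[1], span[2], m, refmap, cs, aln$ref_species)
    if (is.null(rec)) next
    if (rec$end - rec$start >= w && rec$identity >= thresholds$min_identity)
      recs[[length(recs) + 1L]] <- rec
  }
  if (length(recs) == 0) return(empty)
  out <- do.call(rbind, recs)

  if (!is.null(coding_mask) && nrow(coding_mask) > 0) {
    out <- mask_coding(out, coding_mask, m, refmap, cs, thresholds, aln$ref_species)
    if (nrow(out) == 0) return(empty)
  }
  out$group <- "unassigned"
  out$in_intron <- flag_intronic(out, gene_spans, coding_mask)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shrink a column interval so it starts and ends on match columns
trim_to_matches <- function(b, e, m) {
  idx <- which(m[b:e])
  if (length(idx) == 0) return(NULL)
  c(b + idx[1] - 1L, b + idx[length(idx)] - 1L)
}

# build one CNE record from a trimmed column span
span_record <- function(b, e, m, refmap, cs, seq_id) {
  ident <- 100 * (cs[e + 1L] - cs[b]) / (e - b + 1L)
  refpos <- refmap[b:e]
  refpos <- refpos[!is.na(refpos)]
  if (length(refpos) == 0) return(NULL)
  data.frame(seq_id = seq_id, start = refpos[1], end = refpos[length(refpos)] + 1L,
             identity = ident, aln_span = e - b + 1L,
             stringsAsFactors = FALSE)
}

# cut calls down to their noncoding remainder, re-trim and re-filter
mask_coding <- function(out, coding_mask, m, refmap, cs, thresholds, seq_id) {
  keep <- list()
  # columns indexed by reference position for mapping remainders back
  col_of_ref <- rep(NA_integer_, max(refmap, na.rm = TRUE) + 1L)
  nz <- which(!is.na(refmap))
  col_of_ref[refmap[nz] + 1L] <- nz
  for (i in seq_len(nrow(out))) {
    pieces <- subtract_intervals(gi(seq_id, out$start[i], out$end[i]), coding_mask)
    for (j in seq_len(nrow(pieces))) {
      cols <- col_of_ref[(pieces$start[j] + 1L):pieces$end[j]]
      cols <- cols[!is.na(cols)]
      if (length(cols) == 0) next
      span <- trim_to_matches(min(cols), max(cols), m)
      if (is.null(span)) next
      rec <- span_record(span[1], span[2], m, refmap, cs, seq_id)
      if (is.null(rec)) next
      if (rec$end - rec$start >= thresholds$min_length &&
          rec$identity >= thresholds$min_identity)
        keep[[length(keep) + 1L]] <- rec
    }
  }
  if (length(keep) == 0) return(out[0, , drop = FALSE])
  do.call(rbind, keep)
}

flag_intronic <- function(out, gene_spans, coding_mask) {
  if (is.null(gene_spans) || nrow(gene_spans) == 0)
    return(rep(FALSE, nrow(out)))
  in_gene <- vapply(seq_len(nrow(out)), function(i) {
    any(out$start[i] < gene_spans$end & out$end[i] > gene_spans$start)
  }, logical(1))
  in_exon <- if (is.null(coding_mask) || nrow(coding_mask) == 0) {
    rep(FALSE, nrow(out))
  } else vapply(seq_len(nrow(out)), function(i) {
    any(out$start[i] < coding_mask$end & out$end[i] > coding_mask$start)
  }, logical(1))
  in_gene & !in_exon
}

#' Match CNEs across species through their alignment
#'
#' Projects the other species' CNE intervals onto the reference through the
#' alignment coordinate maps and records every overlap of at least one base.
#' One reference CNE may correspond to several CNEs of the other species
#' (long elements break into shorter ones) and vice versa.
#'
#' @param ref_cnes CNE data frame in reference coordinates ([call_cnes()]).
#' @param other_cnes CNE data frame in the other species' own coordinates.
#' @param aln the [pairwise_alignment()] linking the two coordinate systems.
#' @return a list, one element per reference CNE, of integer vectors of
#'   matching `other_cnes` row indices (possibly empty).
#' @export
match_cnes <- function(ref_cnes, other_cnes, aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  omap <- aln$other_coord_map
  rmap <- aln$ref_coord_map
  proj <- lapply(seq_len(nrow(other_cnes)), function(j) {
    cols <- which(!is.na(omap) & omap >= other_cnes$start[j] &
                    omap < other_cnes$end[j])
    refpos <- rmap[cols]
    refpos <- refpos[!is.na(refpos)]
    if (length(refpos) == 0) return(c(NA_integer_, NA_integer_))
    c(min(refpos), max(refpos) + 1L)
  })
  lapply(seq_len(nrow(ref_cnes)), function(i) {
    hits <- vapply(proj, function(p) {
      !is.na(p[1]) && ref_cnes$start[i] < p[2] && ref_cnes$end[i] > p[1]
    }, logical(1))
    which(hits)
  })
}

#' Classify CNEs into phylogenetic depth groups
#'
#' Assigns each reference CNE the deepest clade, in the fixed priority order
#' gnathostome > osteichthyan > sarcopterygian > tetrapod, whose diagnostic
#' species' conserved intervals overlap it by at least one base. A CNE
#' already claimed by one group is not counted again by a shallower one;
#' CNEs shared with none of the diagnostic species fall through to the
#' tetrapod group.
#'
#' @param ref_cnes CNE data frame in reference coordinates.
#' @param presence named list mapping clade labels (among `"gnathostome"`,
#'   `"osteichthyan"`, `"sarcopterygian"`) to character vectors of diagnostic
#'   species (e.g. elephant shark for gnathostome, spotted gar for
#'   osteichthyan, coelacanth for sarcopterygian).
#' @param per_species_hits named list mapping species to interval data
#'   frames (reference coordinates) where that species is conserved —
#'   typically that species' own CNE calls against the same reference.
#' @return `ref_cnes` with the `group` column filled in.
#' @export
classify_cne_groups <- function(ref_cnes,
                                presence = list(gnathostome = "elephant_shark",
                                                osteichthyan = "spotted_gar",
                                                sarcopterygian = "coelacanth"),
                                per_species_hits = list()) {
  priority <- c("gnathostome", "osteichthyan", "sarcopterygian")
  if (!all(names(presence) %in% priority))
    stop("config error: unknown clade label: ",
         paste(setdiff(names(presence), priority), collapse = ", "))
  group <- rep("tetrapod", nrow(ref_cnes))
  assigned <- rep(FALSE, nrow(ref_cnes))
  for (clade in priority) {
    spp <- presence[[clade]]
    if (is.null(spp)) next
    hits <- do.call(rbind, lapply(spp, function(s) per_species_hits[[s]]))
    if (is.null(hits) || nrow(hits) == 0) next
    ov <- vapply(seq_len(nrow(ref_cnes)), function(i) {
      any(ref_cnes$start[i] < hits$end & ref_cnes$end[i] > hits$start)
    }, logical(1))
    newly <- ov & !assigned
    group[newly] <- clade
    assigned <- assigned | newly
  }
  ref_cnes$group <- group
  ref_cnes
}

#' Tabulate CNE counts by cluster and phylogenetic group
#'
#' @param classified named list, cluster name -> classified CNE data frame
#'   (with `group` filled in).
#' @return a data frame with one row per cluster plus a total row; columns
#'   are the four groups and their sum.
#' @export
cne_summary_table <- function(classified) {
  groups <- c("gnathostome", "osteichthyan", "sarcopterygian", "tetrapod")
  rows <- lapply(names(classified), function(cl) {
    g <- classified[[cl]]$group
    cnt <- vapply(groups, function(x) sum(g == x), numeric(1))
    data.frame(cluster = cl, t(cnt), total = sum(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = character(), stringsAsFactors = FALSE)
    for (g in groups) out[[g]] <- numeric()
    out$total <- numeric()
    return(out)
  }
  names(out) <- c("cluster", groups, "total")
  total <- data.frame(cluster = "total", t(colSums(out[groups])),
                      total = sum(out$total), stringsAsFactors = FALSE)
  names(total) <- names(out)
  rbind(out, total)
}
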