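#' Pairwise alignment container
#'
#' Two equal-length gapped strings plus column-to-sequence coordinate maps.
#' `ref_coord_map[i]` is the 0-based reference position written in alignment
#' column `i`, or `NA` where the reference row carries a gap (likewise
#' `other_coord_map` for the second row). Removing the gaps from `ref_aln`
#' must reproduce the reference sequence.
#'
#' @param ref_aln,other_aln equal-length gapped strings (gap character `-`).
#' @param ref_species,other_species species labels.
#' @param score optional alignment score.
#' @return an object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(ref_aln, other_aln, ref_species = "ref",
                               other_species = "other", score = NA_real_) {
  ref_aln <- toupper(ref_aln)
  other_aln <- toupper(other_aln)
  if (nchar(ref_aln) != nchar(other_aln))
    stop("usage error: aligned rows must have equal length")
  rc <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  oc <- strsplit(other_aln, "", fixed = TRUE)[[1]]
  ref_map <- ifelse(rc == "-", NA_integer_, cumsum(rc != "-") - 1L)
  other_map <- ifelse(oc == "-", NA_integer_, cumsum(oc != "-") - 1L)
  structure(list(ref_species = ref_species, other_species = other_species,
                 ref_aln = ref_aln, other_aln = other_aln,
                 ref_coord_map = as.integer(ref_map),
                 other_coord_map = as.integer(other_map),
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment:", x$ref_species, "vs", x$other_species, "\n")
  cat("  columns:", nchar(x$ref_aln),
      " ref bases:", sum(!is.na(x$ref_coord_map)),
      " other bases:", sum(!is.na(x$other_coord_map)), "\n")
  if (!is.na(x$score)) cat("  score:", x$score, "\n")
  invisible(x)
}

#' Global pairwise alignment with affine gap costs
#'
#' Optimal Needleman-Wunsch alignment over `{A,C,G,T,N}` where a gap of
#' length `k` costs `gap_open + (k - 1) * gap_extend`; `N` scores as a
#' mismatch against everything. The dynamic programming (via
#' `Biostrings::pairwiseAlignment`) is quadratic, so inputs are capped at
#' 50 kb each. The traceback is deterministic.
#'
#' @param ref,other nucleotide strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (`mismatch`, `gap_open`, `gap_extend` are penalties, given as negative
#'   scores).
#' @param ref_species,other_species labels carried into the result.
#' @return a [pairwise_alignment()].
#' @examples
#' global_align("ACGT", "ACT")
#' @export
global_align <- function(ref, other, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1,
                         ref_species = "ref", other_species = "other") {
  if (!nzchar(ref) || !nzchar(other)) stop("usage error: empty sequence")
  if (nchar(ref) > 50000 || nchar(other) > 50000)
    stop("usage error: sequences above the 50 kb quadratic-DP bound")
  stopifnot(gap_open <= 0, gap_extend <= 0, mismatch <= match)
  alpha <- c("A", "C", "G", "T", "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(sm) <- match
  sm["N", ] <- mismatch
  sm[, "N"] <- mismatch
  # Biostrings charges gapOpening + gapExtension * k for a length-k gap;
  # the affine form used here charges gap_open for the first position
  pa <- Biostrings::pairwiseAlignment(
    pattern = toupper(ref), subject = toupper(other), type = "global",
    substitutionMatrix = sm,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend
  )
  pairwise_alignment(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)),
                     ref_species, other_species,
                     score = Biostrings::score(pa))
}

#' Treat two equal-length ungapped sequences as already aligned
#'
#' Positional alignment for sequences that are directly comparable
#' coordinate-for-coordinate (e.g. simulated clusters without indels).
#'
#' @param ref,other equal-length nucleotide strings.
#' @inheritParams global_align
#' @return a [pairwise_alignment()].
#' @export
align_positional <- function(ref, other, ref_species = "ref",
                             other_species = "other") {
  if (nchar(ref) != nchar(other))
    stop("usage error: positional alignment needs equal-length sequences")
  pairwise_alignment(ref, other, ref_species, other_species)
}
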