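#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}`
#' (IUPAC ambiguity codes, gaps, etc.) is replaced by `N` with a warning,
#' so that downstream scans see a uniform five-letter alphabet.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0) stop("FASTA format error: no records in '", path, "'")
  seqs <- toupper(as.character(ss))
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  n_rep <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_rep > 0)
    warning(n_rep, " non-ACGTN character(s) replaced by N")
  stats::setNames(unname(cleaned), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences (gapped sequences allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but the gap character `-` is preserved and all records
#' must have equal length.
#'
#' @param path path to an aligned FASTA file.
#' @return a named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0) stop("FASTA format error: no records in '", path, "'")
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment format error: records differ in length")
  stats::setNames(unname(seqs), sub("\\s.*$", "", names(ss)))
}

#' Read feature intervals from BED or GFF3
#'
#' BED intervals (already 0-based half-open) pass through unchanged; GFF3's
#' 1-based closed coordinates are converted to the package's 0-based half-open
#' convention at this boundary. The feature kind is taken from the BED name
#' column (4th) or the GFF3 type column; common synonyms are normalised
#' (`miRNA` to `microRNA`, `repeat_region` to `repeat`, `gap` to
#' `assembly_gap`).
#'
#' @param path path to the annotation file.
#' @param dialect `"BED"` or `"GFF3"`.
#' @return a data frame of intervals (see [gi()]) with an extra `kind` column.
#' @export
read_features <- function(path, dialect = c("BED", "GFF3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "BED") "bed" else "gff3"),
    error = function(e) stop(dialect, " format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # GRanges is 1-based closed for both dialects; internal convention is
  # 0-based half-open, so start shifts by one here for BED and GFF3 alike
  # (rtracklayer already shifted BED starts on import).
  kind <- if (dialect == "BED") {
    if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  } else as.character(gr$type)
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = rep_len(kind, length(gr)),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) stop(dialect, " format error: no feature lines")
  if (any(out$start > out$end) || any(out$start < 0))
    stop(dialect, " format error: invalid coordinates after conversion")
  out$strand[!out$strand %in% c("+", "-", ".")] <- "."
  synonyms <- c(miRNA = "microRNA", repeat_region = "repeat", gap = "assembly_gap")
  hit <- out$kind %in% names(synonyms)
  out$kind[hit] <- synonyms[out$kind[hit]]
  out
}

#' Write intervals as BED
#'
#' @param x an interval data frame (see [gi()]); optional `kind`/`name` column
#'   becomes the BED name field, optional `score` column the score field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if (!is.null(x$name)) x$name else if (!is.null(x$kind)) x$kind else "."
  score <- if (!is.null(x$score)) x$score else 0
  tab <- data.frame(x$seq_id, x$start, x$end, name, score, x$strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an annotated cluster
#'
#' Bundles one species' cluster sequence with its typed feature intervals
#' (exons, genes, microRNAs, pseudogenes, assembly gaps, repeats).
#'
#' @param species species label.
#' @param cluster_name one of `"HoxA"`, `"HoxB"`, `"HoxC"`, `"HoxD"`, `"other"`.
#' @param sequence nucleotide string over `{A,C,G,T,N}`.
#' @param features interval data frame with a `kind` column; every interval
#'   must lie within the sequence and assembly gaps must not overlap
#'   one another.
#' @return an object of class `annotated_cluster`.
#' @export
annotated_cluster <- function(species, cluster_name = "other", sequence,
                              features = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  cluster_name <- match.arg(cluster_name, c("HoxA", "HoxB", "HoxC", "HoxD", "other"))
  if (grepl("[^ACGTN]", sequence))
    stop("sequence must be over {A,C,G,T,N}; see read_fasta() for cleaning")
  if (is.null(features)) {
    features <- empty_gi()
    features$kind <- character()
  }
  validate_intervals(features)
  n <- nchar(sequence)
  if (nrow(features) > 0 && (any(features$start < 0) || any(features$end > n)))
    stop("feature interval outside [0, sequence length]")
  gaps <- features[features$kind %in% "assembly_gap", , drop = FALSE]
  if (nrow(gaps) > 1) {
    o <- order(gaps$start)
    if (any(gaps$start[o][-1] < gaps$end[o][-nrow(gaps)]))
      stop("assembly_gap intervals must be pairwise non-overlapping")
  }
  structure(list(species = species, cluster_name = cluster_name,
                 sequence = sequence, features = features),
            class = "annotated_cluster")
}

#' @export
print.annotated_cluster <- function(x, ...) {
  cat("Annotated cluster:", x$cluster_name, "(", x$species, ")\n")
  cat("  sequence:", nchar(x$sequence), "bp =", cluster_length_kb(x), "kb\n")
  if (nrow(x$features))
    cat("  features:", paste(sprintf("%s (%d)", names(table(x$features$kind)),
                                     table(x$features$kind)), collapse = ", "), "\n")
  invisible(x)
}

#' Cluster length in kilobases
#'
#' Reported to one decimal with half-up rounding, the convention used for
#' cluster sizes (e.g. a 126,900 bp cluster is 126.9 kb).
#'
#' @param cluster an [annotated_cluster()] or a nucleotide string.
#' @return length in kb, one decimal.
#' @export
cluster_length_kb <- function(cluster) {
  seq <- if (inherits(cluster, "annotated_cluster")) cluster$sequence else cluster
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  round_half_up(nchar(seq) / 1000, 1)
}
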