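#' Genomic intervals
#'
#' Intervals are plain data frames with columns `seq_id`, `start`, `end`,
#' `strand` using 0-based half-open coordinates (`start` inclusive, `end`
#' exclusive), the convention used throughout the package. GFF3's 1-based
#' closed coordinates are converted at the parsing boundary by
#' [read_features()].
#'
#' @param seq_id character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open; `0 <= start <= end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return a data frame with columns `seq_id`, `start`, `end`, `strand`.
#' @examples
#' gi("chr", 0, 100)
#' @export
gi <- function(seq_id, start, end, strand = ".") {
  n <- max(length(seq_id), length(start), length(end))
  out <- data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("seq_id", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$start > x$end)) stop("interval start must be <= end")
  if (!all(x$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  invisible(x)
}

empty_gi <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# 0-based half-open data frame -> IRanges (1-based closed) and back
gi_to_ir <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

ir_to_gi <- function(ir, seq_id, strand = ".") {
  if (length(ir) == 0) return(empty_gi())
  gi(seq_id, IRanges::start(ir) - 1L, IRanges::end(ir), strand)
}

#' Subtract masking intervals from a region
#'
#' Returns the maximal sub-intervals of `region` not covered by any interval
#' in `mask`, sorted by position. Used to restrict analyses to regions
#' homologous to the sequence actually obtained, excluding e.g. assembly gaps.
#'
#' @param region a single-row interval data frame (see [gi()]).
#' @param mask an interval data frame on the same `seq_id` (may be empty).
#' @return an interval data frame, possibly empty.
#' @examples
#' subtract_intervals(gi("c", 0, 100), gi("c", 40, 60))
#' @export
subtract_intervals <- function(region, mask) {
  validate_intervals(region)
  stopifnot(nrow(region) == 1L)
  if (is.null(mask) || nrow(mask) == 0) return(region)
  validate_intervals(mask)
  if (any(mask$seq_id != region$seq_id))
    stop("usage error: region and mask must share one seq_id")
  kept <- IRanges::setdiff(gi_to_ir(region), gi_to_ir(mask))
  ir_to_gi(kept, region$seq_id[1])
}

# total length of the union of intervals (single seq_id assumed)
union_length <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(0L)
  x <- x[x$end > x$start, , drop = FALSE]
  if (nrow(x) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(gi_to_ir(x))))
}

# clip intervals to a window [start, end) on the same seq_id
clip_intervals <- function(x, start, end) {
  if (is.null(x) || nrow(x) == 0) return(empty_gi())
  s <- pmax(x$start, start)
  e <- pmin(x$end, end)
  keep <- s < e
  out <- x[keep, , drop = FALSE]
  out$start <- s[keep]
  out$end <- e[keep]
  out
}

# length of intersection of hit union with each of several regions
intersect_length <- function(hits, region) {
  clipped <- clip_intervals(hits, region$start, region$end)
  union_length(clipped)
}
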