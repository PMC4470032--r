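# shared internal helpers

#' Round half away from zero
#'
#' Base `round()` rounds half to even; cluster sizes and fold ratios are
#' reported with conventional half-up rounding, so that is provided here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of a nucleotide string
#'
#' @param x a single character string over `{A,C,G,T,N}` (case preserved as
#'   upper case in the output).
#' @return the reverse complement string.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# integer encoding A=1 C=2 G=3 T=4, N/other = NA
seq_to_int <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  v
}

int_to_seq <- function(v) {
  out <- c("A", "C", "G", "T")[v]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# complement in integer encoding (A<->T, C<->G); NA stays NA
int_complement <- function(v) 5L - v
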