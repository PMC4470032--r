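#' Search parameters for direct/inverted repeat discovery
#'
#' Defaults mirror a self-self similarity search: 70 percent minimum arm
#' identity, 50 bp minimum arm length, and the ">100 bp arm" convention for
#' calling an inverted repeat "long". Explicit identity/length thresholds
#' replace database-size-dependent e-value cutoffs so results are
#' deterministic.
#'
#' @param min_arm_identity minimum percent identity between the two arms.
#' @param min_arm_length minimum arm length in bp.
#' @param long_arm_threshold arms strictly longer than this are "long".
#' @param seed_length exact-match seed size in bp (must not exceed
#'   `min_arm_length`).
#' @param max_spacer maximum gap between the arms in bp.
#' @return an object of class `repeat_search_params`.
#' @export
repeat_search_params <- function(min_arm_identity = 70, min_arm_length = 50,
                                 long_arm_threshold = 100, seed_length = 12,
                                 max_spacer = 10000) {
  if (seed_length > min_arm_length)
    stop("config error: seed_length must not exceed min_arm_length")
  if (!(min_arm_identity > 0 && min_arm_identity <= 100))
    stop("config error: min_arm_identity must be in (0, 100]")
  structure(list(min_arm_identity = min_arm_identity,
                 min_arm_length = as.integer(min_arm_length),
                 long_arm_threshold = as.integer(long_arm_threshold),
                 seed_length = as.integer(seed_length),
                 max_spacer = as.integer(max_spacer)),
            class = "repeat_search_params")
}

empty_repeat_pairs <- function() {
  data.frame(arm1_start = integer(), arm1_end = integer(),
             arm2_start = integer(), arm2_end = integer(),
             orientation = character(), arm_identity = numeric(),
             arm_length = integer(), spacer = integer(),
             stringsAsFactors = FALSE)
}

# Extend a seed [b0, e0] (1-based, all matches) along a precomputed match
# vector mv restricted to [lo, hi]. The X-drop walk explores while the
# running identity of the grown span stays above min_frac - 0.05; the arm is
# then trimmed to the maximal-scoring ungapped span (match +1, mismatch -1,
# first maximum kept), the usual HSP formalisation of "the maximal-identity
# span". Returns c(b, e, n_matches).
extend_seed <- function(mv, lo, hi, b0, e0, min_frac, max_len = Inf) {
  drop_frac <- min_frac - 0.05
  # right
  best_e <- e0
  best_m <- e0 - b0 + 1L
  best_s <- best_m                       # seed score = its length
  mcount <- best_m
  x <- e0
  while (x < hi) {
    x <- x + 1L
    mcount <- mcount + mv[x]
    len <- x - b0 + 1L
    sc <- 2L * mcount - len
    if (sc > best_s) { best_e <- x; best_m <- mcount; best_s <- sc }
    if (mcount / len < drop_frac) break
  }
  # left, against the chosen right end
  lo <- max(lo, best_e - max_len + 1L)
  best_b <- b0
  mcount <- best_m
  best_s <- 2L * best_m - (best_e - b0 + 1L)
  x <- b0
  while (x > lo) {
    x <- x - 1L
    mcount <- mcount + mv[x]
    len <- best_e - x + 1L
    sc <- 2L * mcount - len
    if (sc > best_s) { best_b <- x; best_m <- mcount; best_s <- sc }
    if (mcount / len < drop_frac) break
  }
  c(best_b, best_e, best_m)
}

# distinct-base count per k-window; seeds with <= 2 distinct bases are
# skipped (suppresses homopolymer/dinucleotide artifacts)
seed_complexity_ok <- function(s, k) {
  n <- length(s)
  npos <- n - k + 1L
  if (npos < 1) return(logical(0))
  distinct <- integer(npos)
  for (b in 1:4) {
    cs <- cumsum(c(0L, s == b & !is.na(s)))
    distinct <- distinct + ((cs[(k + 1):(n + 1)] - cs[1:npos]) > 0L)
  }
  distinct >= 3L
}

# numeric k-mer ids (base 4); NA where the window contains N
kmer_ids <- function(code, k) {
  n <- length(code)
  npos <- n - k + 1L
  id <- numeric(npos)
  for (t in 0:(k - 1)) id <- id + code[(1 + t):(npos + t)] * 4^(k - 1 - t)
  id
}

#' Find direct and inverted repeat pairs by self comparison
#'
#' Exact `seed_length`-mer matches between the sequence and itself (direct)
#' and between the sequence and its reverse complement (inverted) are
#' extended in both directions without gaps; the X-drop walk stops when the
#' running identity of the growing span falls 5 points below
#' `min_arm_identity`, and each arm is trimmed to the longest span ending on
#' matching bases with identity at or above `min_arm_identity`. Pairs are
#' filtered by `min_arm_length`, `min_arm_identity` and `max_spacer`,
#' deduplicated (self and mirror hits removed), and overlapping pairs merged
#' keeping the longer arm. Seeds whose k-mer has two or fewer distinct bases
#' are skipped (low-complexity filter).
#'
#' @param sequence nucleotide string over `{A,C,G,T,N}`.
#' @param params a [repeat_search_params()].
#' @return a data frame of repeat pairs (0-based half-open arm intervals):
#'   `arm1_start`, `arm1_end`, `arm2_start`, `arm2_end`, `orientation`
#'   (`direct`/`inverted`), `arm_identity` (percent), `arm_length`, `spacer`
#'   (bp between arm1 end and arm2 start). Arms never overlap
#'   (`spacer >= 0`) and `arm1_start < arm2_start`.
#' @export
find_repeat_pairs <- function(sequence, params = repeat_search_params()) {
  stopifnot(inherits(params, "repeat_search_params"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L * params$min_arm_length) {
    warning("sequence shorter than two minimum arms; no repeats reported")
    return(empty_repeat_pairs())
  }
  s <- seq_to_int(sequence)
  k <- params$seed_length
  min_frac <- params$min_arm_identity / 100

  code <- s - 1L
  ids <- kmer_ids(code, k)
  ok <- seed_complexity_ok(s, k) & !is.na(ids)
  # reverse-complement k-mer ids: id of revcomp(s[j..j+k-1])
  ccode <- 4L - s              # complement, 0-based code
  rids <- numeric(n - k + 1L)
  for (t in 0:(k - 1)) rids <- rids + ccode[(1 + t):(n - k + 1L + t)] * 4^t

  cand <- list()
  push <- function(x) cand[[length(cand) + 1L]] <<- x

  # ---- direct: same-id position pairs, grouped by diagonal ----
  pos_ok <- which(ok)
  grp <- split(pos_ok, ids[pos_ok])
  seeds_d <- NULL
  for (g in grp) {
    if (length(g) < 2) next
    pr <- utils::combn(g, 2L)
    seeds_d <- rbind(seeds_d, cbind(pr[1, ], pr[2, ]))
  }
  if (!is.null(seeds_d)) {
    d_all <- seeds_d[, 2] - seeds_d[, 1]
    keep <- d_all >= k & d_all <= params$max_spacer + n  # spacer bounded later
    seeds_d <- seeds_d[keep, , drop = FALSE]
    for (d in unique(seeds_d[, 2] - seeds_d[, 1])) {
      rows <- seeds_d[seeds_d[, 2] - seeds_d[, 1] == d, 1]
      mv <- s[1:(n - d)] == s[(1 + d):n]
      mv[is.na(mv)] <- FALSE
      done <- matrix(numeric(0), ncol = 2)
      for (i in sort(rows)) {
        b0 <- i; e0 <- i + k - 1L
        if (nrow(done) > 0 && any(done[, 1] <= b0 & done[, 2] >= e0)) next
        hi <- min(n - d, b0 + d - 1L)     # cap keeps arms from overlapping
        if (e0 > hi) next
        sp <- extend_seed(mv, 1L, hi, b0, e0, min_frac, max_len = d)
        done <- rbind(done, sp[1:2])
        L <- sp[2] - sp[1] + 1L
        spacer <- d - L
        identity <- 100 * sp[3] / L
        if (L >= params$min_arm_length && identity >= params$min_arm_identity &&
            spacer >= 0 && spacer <= params$max_spacer)
          push(data.frame(arm1_start = sp[1] - 1L, arm1_end = sp[2],
                          arm2_start = sp[1] + d - 1L, arm2_end = sp[2] + d,
                          orientation = "direct", arm_identity = identity,
                          arm_length = L, spacer = spacer,
                          stringsAsFactors = FALSE))
      }
    }
  }

  # ---- inverted: forward k-mer equals reverse complement of a later one ----
  rok <- seed_complexity_ok(s, k) & !is.na(rids)
  common <- intersect(unique(ids[pos_ok]), unique(rids[which(rok)]))
  seeds_i <- NULL
  for (v in common) {
    fi <- pos_ok[ids[pos_ok] == v]
    rj <- which(rok)[rids[which(rok)] == v]
    pr <- expand.grid(i = fi, j = rj)
    pr <- pr[pr$j >= pr$i + k, , drop = FALSE]  # arm2 strictly right of arm1
    if (nrow(pr)) seeds_i <- rbind(seeds_i, as.matrix(pr))
  }
  if (!is.null(seeds_i) && nrow(seeds_i) > 0) {
    C_all <- seeds_i[, 1] + seeds_i[, 2] + k - 1L
    for (C in unique(C_all)) {
      rows <- sort(seeds_i[C_all == C, 1])
      lo <- max(1L, C - n)
      hi <- (C - 1L) %/% 2L                 # spacer >= 0 cap
      xs <- lo:hi
      mv_part <- s[xs] == (5L - s[C - xs])
      mv_part[is.na(mv_part)] <- FALSE
      mv <- logical(hi)
      mv[xs] <- mv_part
      done <- matrix(numeric(0), ncol = 2)
      for (i in rows) {
        b0 <- i; e0 <- i + k - 1L
        if (e0 > hi) next
        if (nrow(done) > 0 && any(done[, 1] <= b0 & done[, 2] >= e0)) next
        sp <- extend_seed(mv, lo, hi, b0, e0, min_frac)
        done <- rbind(done, sp[1:2])
        L <- sp[2] - sp[1] + 1L
        spacer <- C - 2L * sp[2] - 1L
        identity <- 100 * sp[3] / L
        if (L >= params$min_arm_length && identity >= params$min_arm_identity &&
            spacer >= 0 && spacer <= params$max_spacer)
          push(data.frame(arm1_start = sp[1] - 1L, arm1_end = sp[2],
                          arm2_start = C - sp[2] - 1L, arm2_end = C - sp[1],
                          orientation = "inverted", arm_identity = identity,
                          arm_length = L, spacer = spacer,
                          stringsAsFactors = FALSE))
      }
    }
  }

  if (length(cand) == 0) return(empty_repeat_pairs())
  out <- unique(do.call(rbind, cand))
  merge_overlapping_pairs(out)
}

# keep the longer arm among same-orientation pairs whose arm1 AND arm2
# intervals both overlap
merge_overlapping_pairs <- function(out) {
  o <- order(-out$arm_length, -out$arm_identity, out$arm1_start, out$arm2_start)
  out <- out[o, , drop = FALSE]
  kept <- out[0, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    clash <- FALSE
    if (nrow(kept) > 0) {
      same <- kept$orientation == x$orientation
      ov1 <- kept$arm1_start < x$arm1_end & kept$arm1_end > x$arm1_start
      ov2 <- kept$arm2_start < x$arm2_end & kept$arm2_end > x$arm2_start
      clash <- any(same & ov1 & ov2)
    }
    if (!clash) kept <- rbind(kept, x)
  }
  kept <- kept[order(kept$arm1_start, kept$arm2_start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Long inverted repeats
#'
#' The inverted subset of [find_repeat_pairs()] output with arms strictly
#' longer than `long_arm_threshold`, sorted by decreasing arm length.
#'
#' @param pairs output of [find_repeat_pairs()].
#' @param params a [repeat_search_params()].
#' @return the filtered, sorted repeat-pair data frame.
#' @export
long_inverted_repeats <- function(pairs, params = repeat_search_params()) {
  out <- pairs[pairs$orientation == "inverted" &
                 pairs$arm_length > params$long_arm_threshold, , drop = FALSE]
  out <- out[order(-out$arm_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repeat density over a region
#'
#' 100 times the length of the union of the repeat intervals (clipped to the
#' region) divided by the region length; overlapping hits are counted once.
#'
#' @param repeat_hits interval data frame of repeat hits.
#' @param region_length region length in bp (> 0).
#' @return percent density.
#' @export
repeat_density <- function(repeat_hits, region_length) {
  if (region_length <= 0) stop("usage error: region_length must be > 0")
  clipped <- clip_intervals(repeat_hits, 0L, as.integer(region_length))
  100 * union_length(clipped) / region_length
}

#' Repeat density restricted to retained sub-regions
#'
#' Density over `subtract_intervals(region, exclusions)`: hits are clipped to
#' the retained sub-regions and the denominator is their total length. Used
#' to compare repeat content only over regions homologous to sequence that
#' was actually obtained, excluding gaps.
#'
#' @param hits interval data frame of repeat hits.
#' @param region single-row interval data frame.
#' @param exclusions interval data frame of regions to exclude (within
#'   `region`).
#' @return percent density over the retained length.
#' @export
restricted_density <- function(hits, region, exclusions = NULL) {
  retained <- subtract_intervals(region, exclusions)
  denom <- sum(retained$end - retained$start)
  if (denom <= 0) stop("usage error: no retained region length")
  covered <- sum(vapply(seq_len(nrow(retained)), function(i)
    intersect_length(hits, retained[i, ]), numeric(1)))
  100 * covered / denom
}

#' Per-region repeat counts and densities
#'
#' Tallies, for each named (non-overlapping) region, the number of hits
#' overlapping it, the clipped union length in bp, and the density, plus an
#' overall total row — the "hotspot" view of repeat distribution across
#' intergenic regions.
#'
#' @param hits interval data frame of repeat hits.
#' @param regions data frame with columns `name`, `start`, `end` (or a named
#'   list of single-row interval data frames).
#' @return a data frame: `name`, `length`, `n_hits`, `bp`, `density`.
#' @export
hotspot_table <- function(hits, regions) {
  if (is.list(regions) && !is.data.frame(regions)) {
    regions <- do.call(rbind, lapply(names(regions), function(nm) {
      data.frame(name = nm, start = regions[[nm]]$start,
                 end = regions[[nm]]$end, stringsAsFactors = FALSE)
    }))
  }
  o <- order(regions$start)
  if (nrow(regions) > 1 && any(regions$start[o][-1] < regions$end[o][-nrow(regions)]))
    stop("usage error: regions must be non-overlapping")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    clipped <- if (is.null(hits) || nrow(hits) == 0) empty_gi()
               else clip_intervals(hits, rg$start, rg$end)
    bp <- union_length(clipped)
    data.frame(name = rg$name, length = rg$end - rg$start,
               n_hits = nrow(clipped), bp = bp,
               density = 100 * bp / (rg$end - rg$start),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(name = "total", length = sum(out$length),
                      n_hits = sum(out$n_hits), bp = sum(out$bp),
                      density = 100 * sum(out$bp) / sum(out$length),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}
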