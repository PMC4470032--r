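# Independent oracle implementations used to cross-check the package's
# vectorised code paths. Everything here is written as plain loops over the
# normative definitions, with no shared code with R/.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# ---- interval subtraction: per-base brute force ----
oracle_subtract <- function(region, mask) {
  covered <- rep(FALSE, region$end - region$start)
  for (i in seq_len(nrow(mask))) {
    lo <- max(mask$start[i], region$start)
    hi <- min(mask$end[i], region$end)
    if (lo < hi) covered[(lo - region$start + 1):(hi - region$start)] <- TRUE
  }
  free <- which(!covered)
  if (length(free) == 0) return(NULL)
  brk <- c(0, which(diff(free) > 1), length(free))
  out <- NULL
  for (j in seq_len(length(brk) - 1)) {
    run <- free[(brk[j] + 1):brk[j + 1]]
    out <- rbind(out, data.frame(start = region$start + run[1] - 1,
                                 end = region$start + run[length(run)]))
  }
  out
}

# ---- affine-gap global alignment score by exhaustive enumeration ----
# gap of length k costs open + (k-1) * extend; tiny inputs only
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -2, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, score + if (av[i] == bv[j]) match else mismatch, "m")
    if (i <= length(av))
      rec(i + 1, j, score + if (state == "a") gap_extend else gap_open, "a")
    if (j <= length(bv))
      rec(i, j + 1, score + if (state == "b") gap_extend else gap_open, "b")
  }
  rec(1, 1, 0, "m")
  best
}

# ---- Tajima RRT counts: per-column classifier ----
oracle_rrt_counts <- function(a, b, o) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]; ov <- strsplit(o, "")[[1]]
  m_a <- 0; m_b <- 0
  for (i in seq_along(av)) {
    if (av[i] != bv[i] && bv[i] == ov[i]) m_a <- m_a + 1
    if (bv[i] != av[i] && av[i] == ov[i]) m_b <- m_b + 1
  }
  c(m_a = m_a, m_b = m_b)
}

# ---- CNE calling: naive re-derivation of the seed-merge-trim definition ----
oracle_call_cnes <- function(aln, min_identity = 65, min_length = 50,
                             coding_mask = NULL) {
  rc <- strsplit(aln$ref_aln, "")[[1]]
  oc <- strsplit(aln$other_aln, "")[[1]]
  L <- length(rc)
  m <- logical(L)
  for (i in seq_len(L))
    m[i] <- rc[i] %in% c("A", "C", "G", "T") && rc[i] == oc[i]
  w <- min_length
  if (L < w) return(NULL)
  covered <- logical(L)
  for (i in 1:(L - w + 1))
    if (mean(m[i:(i + w - 1)]) >= min_identity / 100)
      covered[i:(i + w - 1)] <- TRUE
  refmap <- integer(L); pos <- -1L
  for (i in seq_len(L)) {
    if (rc[i] != "-") pos <- pos + 1L
    refmap[i] <- if (rc[i] == "-") NA_integer_ else pos
  }
  mask_base <- NULL
  if (!is.null(coding_mask) && nrow(coding_mask) > 0)
    for (i in seq_len(nrow(coding_mask)))
      mask_base <- c(mask_base, seq(coding_mask$start[i], coding_mask$end[i] - 1))

  emit <- function(b, e) {
    while (b <= e && !m[b]) b <- b + 1
    while (e >= b && !m[e]) e <- e - 1
    if (b > e) return(NULL)
    ident <- 100 * sum(m[b:e]) / (e - b + 1)
    refs <- refmap[b:e]; refs <- refs[!is.na(refs)]
    if (length(refs) == 0) return(NULL)
    list(b = b, e = e, start = refs[1], end = refs[length(refs)] + 1,
         identity = ident)
  }

  out <- NULL
  i <- 1
  while (i <= L) {
    if (covered[i]) {
      j <- i
      while (j < L && covered[j + 1]) j <- j + 1
      rec <- emit(i, j)
      if (!is.null(rec) && rec$end - rec$start >= min_length &&
          rec$identity >= min_identity) {
        pieces <- list(c(rec$start, rec$end))
        if (!is.null(mask_base)) {
          keep <- setdiff(seq(rec$start, rec$end - 1), mask_base)
          pieces <- list()
          if (length(keep) > 0) {
            brk <- c(0, which(diff(keep) > 1), length(keep))
            for (q in seq_len(length(brk) - 1)) {
              run <- keep[(brk[q] + 1):brk[q + 1]]
              pieces[[q]] <- c(run[1], run[length(run)] + 1)
            }
          }
        }
        for (p in pieces) {
          cols <- which(!is.na(refmap) & refmap >= p[1] & refmap < p[2])
          if (length(cols) == 0) next
          r2 <- emit(min(cols), max(cols))
          if (!is.null(r2) && r2$end - r2$start >= min_length &&
              r2$identity >= min_identity)
            out <- rbind(out, data.frame(start = r2$start, end = r2$end,
                                         identity = r2$identity,
                                         aln_span = r2$e - r2$b + 1))
        }
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!is.null(out)) out <- out[order(out$start), , drop = FALSE]
  out
}

# ---- repeat finding: exhaustive per-diagonal scan, plain loops ----
oracle_find_repeats <- function(sequence, params) {
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ch <- strsplit(toupper(sequence), "")[[1]]
  s <- unname(base[ch])
  n <- length(s)
  k <- params$seed_length
  min_frac <- params$min_arm_identity / 100
  drop_frac <- min_frac - 0.05

  complexity_ok <- function(b) {
    win <- s[b:(b + k - 1)]
    !anyNA(win) && length(unique(win)) >= 3
  }

  walk <- function(mv, lo, hi, b0, e0, max_len) {
    best_e <- e0; best_m <- e0 - b0 + 1; best_s <- best_m; mc <- best_m
    x <- e0
    while (x < hi) {
      x <- x + 1
      mc <- mc + mv[x]
      sc <- 2 * mc - (x - b0 + 1)
      if (sc > best_s) { best_e <- x; best_m <- mc; best_s <- sc }
      if (mc / (x - b0 + 1) < drop_frac) break
    }
    lo <- max(lo, best_e - max_len + 1)
    best_b <- b0; mc <- best_m; best_s <- 2 * best_m - (best_e - b0 + 1)
    x <- b0
    while (x > lo) {
      x <- x - 1
      mc <- mc + mv[x]
      sc <- 2 * mc - (best_e - x + 1)
      if (sc > best_s) { best_b <- x; best_m <- mc; best_s <- sc }
      if (mc / (best_e - x + 1) < drop_frac) break
    }
    c(best_b, best_e, best_m)
  }

  cand <- NULL
  add <- function(a1s, a1e, a2s, a2e, orient, ident, L, spacer) {
    cand <<- rbind(cand, data.frame(
      arm1_start = a1s, arm1_end = a1e, arm2_start = a2s, arm2_end = a2e,
      orientation = orient, arm_identity = ident, arm_length = L,
      spacer = spacer, stringsAsFactors = FALSE))
  }

  # direct diagonals
  for (d in k:(n - 1)) {
    len <- n - d
    if (len < k) next
    mv <- logical(len)
    for (x in 1:len) mv[x] <- !is.na(s[x]) && !is.na(s[x + d]) && s[x] == s[x + d]
    done <- NULL
    for (i in 1:(len - k + 1)) {
      if (!all(mv[i:(i + k - 1)])) next
      if (!complexity_ok(i)) next
      if (!is.null(done) && any(done[, 1] <= i & done[, 2] >= i + k - 1)) next
      hi <- min(len, i + d - 1)
      if (i + k - 1 > hi) next
      sp <- walk(mv, 1, hi, i, i + k - 1, d)
      done <- rbind(done, sp[1:2])
      L <- sp[2] - sp[1] + 1
      spacer <- d - L
      ident <- 100 * sp[3] / L
      if (L >= params$min_arm_length && ident >= params$min_arm_identity &&
          spacer >= 0 && spacer <= params$max_spacer)
        add(sp[1] - 1, sp[2], sp[1] + d - 1, sp[2] + d, "direct", ident, L, spacer)
    }
  }

  # inverted anti-diagonals
  for (C in 3:(2 * n - 1)) {
    lo <- max(1, C - n)
    hi <- (C - 1) %/% 2
    if (hi - lo + 1 < k) next
    mv <- logical(hi)
    for (x in lo:hi) mv[x] <- !is.na(s[x]) && !is.na(s[C - x]) &&
      s[x] == 5 - s[C - x]
    done <- NULL
    for (i in lo:(hi - k + 1)) {
      if (!all(mv[i:(i + k - 1)])) next
      if (!complexity_ok(i)) next
      if (i + k - 1 > hi) next
      if (!is.null(done) && any(done[, 1] <= i & done[, 2] >= i + k - 1)) next
      sp <- walk(mv, lo, hi, i, i + k - 1, Inf)
      done <- rbind(done, sp[1:2])
      L <- sp[2] - sp[1] + 1
      spacer <- C - 2 * sp[2] - 1
      ident <- 100 * sp[3] / L
      if (L >= params$min_arm_length && ident >= params$min_arm_identity &&
          spacer >= 0 && spacer <= params$max_spacer)
        add(sp[1] - 1, sp[2], C - sp[2] - 1, C - sp[1], "inverted", ident, L, spacer)
    }
  }

  if (is.null(cand)) return(NULL)
  cand <- unique(cand)
  # merge: keep longer arm among both-overlapping same-orientation pairs
  o <- order(-cand$arm_length, -cand$arm_identity, cand$arm1_start, cand$arm2_start)
  cand <- cand[o, , drop = FALSE]
  kept <- NULL
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, ]
    clash <- FALSE
    if (!is.null(kept)) {
      for (j in seq_len(nrow(kept))) {
        if (kept$orientation[j] == x$orientation &&
            kept$arm1_start[j] < x$arm1_end && kept$arm1_end[j] > x$arm1_start &&
            kept$arm2_start[j] < x$arm2_end && kept$arm2_end[j] > x$arm2_start) {
          clash <- TRUE; break
        }
      }
    }
    if (!clash) kept <- rbind(kept, x)
  }
  kept <- kept[order(kept$arm1_start, kept$arm2_start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# ---- reachability by depth-first search ----
oracle_reachability <- function(adj) {
  n <- nrow(adj)
  reach <- matrix(FALSE, n, n)
  for (src in seq_len(n)) {
    stack <- which(adj[src, ])
    seen <- logical(n)
    while (length(stack) > 0) {
      v <- stack[1]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ]))
    }
    reach[src, ] <- seen
  }
  reach
}
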