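test_that("ambiguous-column stripping removes exactly the flagged columns", {
  tr <- triplet_alignment("g", "ACGT", "ACGT", "ACGT")
  expect_identical(strip_ambiguous_columns(tr)$ingroup_a, "ACGT")

  tr2 <- triplet_alignment("g", "----", "ACGT", "ACGT")
  st2 <- strip_ambiguous_columns(tr2)
  expect_identical(st2$ingroup_a, "")

  # an N in the outgroup alone removes that column
  tr3 <- triplet_alignment("g", "ACGT", "ACGT", "ACNT")
  st3 <- strip_ambiguous_columns(tr3)
  expect_identical(st3$outgroup, "ACT")
  expect_identical(st3$ingroup_a, "ACT")

  # protein mode flags X/B/Z/J but keeps N (asparagine)
  tr4 <- triplet_alignment("g", "MNXB", "MNKL", "MNKL", alphabet = "protein")
  st4 <- strip_ambiguous_columns(tr4)
  expect_identical(st4$ingroup_a, "MN")
})

test_that("the test statistic follows the unique-substitution counts", {
  # balanced counts: no signal
  tr <- triplet_alignment("g", "TTAAAA", "AATTAA", "AAAAAA")
  res <- tajima_rrt(tr)
  expect_equal(res$m_a, res$m_b)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # m_a = 3, m_b = 1 -> chi2 = 1, p = P(chisq_1 > 1)
  a <- "CCCA"; b <- "AAAC"; o <- "AAAA"
  res2 <- tajima_rrt(triplet_alignment("g", a, b, o))
  expect_equal(res2$m_a, 3)
  expect_equal(res2$m_b, 1)
  expect_equal(res2$chi2, 1.0)
  expect_equal(res2$p, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(res2$p, 4), 0.3173)

  # no informative sites at all
  res3 <- tajima_rrt(triplet_alignment("g", "AAAA", "AAAA", "AAAA"))
  expect_equal(res3$chi2, 0)
  expect_equal(res3$p, 1)
  expect_equal(res3$significance, "ns")
})

test_that("counts match the per-site oracle on 200 random triplets", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(20:120, 1)
    a <- rand_seq(n); b <- rand_seq(n); o <- rand_seq(n)
    res <- tajima_rrt(triplet_alignment("g", a, b, o))
    exp <- oracle_rrt_counts(a, b, o)
    expect_equal(res$m_a, unname(exp["m_a"]))
    expect_equal(res$m_b, unname(exp["m_b"]))
  }
})

test_that("the test is exchangeable and ignores shared-ingroup columns", {
  set.seed(102)
  for (rep in 1:20) {
    a <- rand_seq(60); b <- rand_seq(60); o <- rand_seq(60)
    r1 <- tajima_rrt(triplet_alignment("g", a, b, o))
    r2 <- tajima_rrt(triplet_alignment("g", b, a, o))
    expect_equal(r1$chi2, r2$chi2)
    expect_equal(r1$p, r2$p)
    expect_equal(r1$m_a, r2$m_b)
  }
  # columns where A == B but the outgroup differs carry no signal
  base <- tajima_rrt(triplet_alignment("g", "CCCA", "AAAC", "AAAA"))
  padded <- tajima_rrt(triplet_alignment("g", "CCCAGGGG", "AAACGGGG", "AAAATTTT"))
  expect_equal(padded$m_a, base$m_a)
  expect_equal(padded$m_b, base$m_b)
})

test_that("the battery enumerates genes and pairs deterministically", {
  set.seed(103)
  mk_gene <- function(spp, n = 40)
    vapply(spp, function(s) rand_seq(n), character(1))
  spp <- c("caecilian", "frog", "human", "turtle", "coelacanth")
  alns <- lapply(1:10, function(i) mk_gene(spp))
  names(alns) <- paste0("gene", sprintf("%02d", 1:10))

  res2 <- rrt_battery(alns, c("caecilian", "frog"), "coelacanth")
  expect_equal(nrow(res2), 10)

  res4 <- rrt_battery(alns, c("caecilian", "frog", "human", "turtle"),
                      "coelacanth")
  expect_equal(nrow(res4), 60)  # C(4,2) = 6 pairs per gene
  expect_equal(res4$gene, sort(res4$gene))

  # a gene lacking the outgroup is skipped with a notice
  alns$gene03 <- alns$gene03[setdiff(spp, "coelacanth")]
  expect_message(res <- rrt_battery(alns, c("caecilian", "frog"), "coelacanth"),
                 "outgroup")
  expect_equal(nrow(res), 9)
})

test_that("Hasse construction places slower lineages below faster ones", {
  row <- function(a, b, m_a, m_b, p)
    data.frame(gene = "g", species_a = a, species_b = b, outgroup = "o",
               n_sites_used = 100, m_a = m_a, m_b = m_b,
               chi2 = 0, p = p, significance = "x", stringsAsFactors = FALSE)

  # single significant result: A slower -> edge B -> A
  h1 <- build_hasse(row("A", "B", 2, 20, 0.001))
  expect_equal(nrow(h1$reduced_edges), 1)
  expect_equal(h1$reduced_edges$slower, "A")
  expect_equal(h1$reduced_edges$faster, "B")
  expect_equal(h1$reduced_edges$significance, "high")

  # chain A < B < C with the redundant A < C edge removed by reduction
  res <- rbind(row("A", "B", 2, 20, 0.001), row("B", "C", 2, 20, 0.001),
               row("A", "C", 2, 30, 0.0005))
  h2 <- build_hasse(res)
  expect_equal(nrow(h2$edges), 3)
  got <- h2$reduced_edges[order(h2$reduced_edges$slower), c("slower", "faster")]
  rownames(got) <- NULL
  expect_equal(got, data.frame(slower = c("A", "B"), faster = c("B", "C"),
                               stringsAsFactors = FALSE))

  # nothing significant: an edgeless order
  h3 <- build_hasse(row("A", "B", 5, 6, 0.6))
  expect_equal(nrow(h3$edges), 0)
  expect_equal(h3$nodes, c("A", "B"))

  # DOT output uses solid for high, dashed for significant
  expect_match(as_dot(h1), "style=solid")
  h4 <- build_hasse(row("A", "B", 5, 16, 0.03))
  expect_match(as_dot(h4), "style=dashed")
})

test_that("transitive reduction preserves reachability on all 4-node DAGs", {
  # exhaustive: every labeled DAG on 4 nodes via upper-triangular edge sets
  # under all vertex orderings
  perms <- list(); idx <- 1
  perm_rec <- function(v, acc) {
    if (length(v) == 0) { perms[[idx]] <<- acc; idx <<- idx + 1; return() }
    for (i in seq_along(v)) perm_rec(v[-i], c(acc, v[i]))
  }
  perm_rec(1:4, integer(0))
  pairs <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  seen <- new.env()
  n_checked <- 0
  for (mask in 0:(2^nrow(pairs) - 1)) {
    bits <- bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0
    for (pm in perms) {
      adj <- matrix(FALSE, 4, 4)
      for (e in which(bits))
        adj[pm[pairs[e, 1]], pm[pairs[e, 2]]] <- TRUE
      key <- paste0("k", paste(which(adj), collapse = ","))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      n_checked <- n_checked + 1
      red <- hoxcomp:::transitive_reduction_bool(adj)
      expect_true(all(red <= adj))
      expect_identical(oracle_reachability(red), oracle_reachability(adj))
      # minimality: removing any kept edge loses reachability
      for (e in which(red)) {
        r2 <- red; r2[e] <- FALSE
        expect_false(identical(oracle_reachability(r2),
                               oracle_reachability(adj)))
      }
    }
  }
  expect_equal(n_checked, 543)  # number of labeled DAGs on 4 nodes
})

test_that("pairwise and genome summaries count directions and tiers", {
  row <- function(gene, a, b, m_a, m_b, p)
    data.frame(gene = gene, species_a = a, species_b = b, outgroup = "o",
               n_sites_used = 100, m_a = m_a, m_b = m_b, chi2 = 0, p = p,
               significance = "x", stringsAsFactors = FALSE)
  # all non-significant: zero counts
  res_ns <- rbind(row("g1", "A", "B", 5, 6, 0.8), row("g2", "A", "B", 6, 5, 0.7))
  s <- summarize_pairwise(res_ns)
  expect_true(all(s[c("a_slower_high", "a_slower_sig",
                      "b_slower_high", "b_slower_sig")] == 0))

  # one significant result increments exactly one directional cell
  res1 <- rbind(res_ns, row("g3", "A", "B", 1, 19, 0.004))
  s1 <- summarize_pairwise(res1)
  expect_equal(s1$a_slower_high, 1)
  expect_equal(s1$b_slower_high + s1$b_slower_sig + s1$a_slower_sig, 0)
  expect_equal(s1$frac_a_slower, 1 / 3)

  expect_error(genome_matrix(res1, c("A", "B")), "usage error")

  res3 <- rbind(
    row("g1", "A", "B", 1, 19, 0.004), row("g1", "A", "C", 2, 18, 0.03),
    row("g1", "B", "C", 9, 9, 1),
    row("g2", "A", "B", 9, 9, 1), row("g2", "A", "C", 9, 9, 1),
    row("g2", "B", "C", 9, 9, 1))
  gm <- genome_matrix(res3, c("A", "B", "C"))
  a_rows <- gm$counts[gm$counts$species == "A", ]
  expect_equal(sum(a_rows$slower_high), 1)
  expect_equal(sum(a_rows$slower_sig), 1)
  smry <- gm$summary
  expect_equal(smry$pct_slower_either[smry$species == "A"], 50)  # 1 of 2 genes
  expect_equal(smry$pct_slower_both[smry$species == "A"], 50)
  expect_equal(smry$pct_slower_either[smry$species == "B"], 0)
})
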