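# small shim so tests can reach the internal match-column logic
column_matches_for_test <- function(aln) hoxcomp:::column_matches(aln)

test_that("global alignment reproduces enumerated optimal scores", {
  a <- global_align(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(a$score, 100)
  expect_false(grepl("-", a$ref_aln))
  expect_true(all(column_matches_for_test(a)))

  # exhaustive-enumeration oracle on tiny inputs
  expect_equal(global_align("ACGT", "ACT")$score,
               oracle_global_score("ACGT", "ACT"))
  expect_equal(global_align("ACGT", "ACT")$score, 1)
  set.seed(21)
  for (rep in 1:10) {
    x <- rand_seq(sample(3:7, 1)); y <- rand_seq(sample(3:7, 1))
    expect_equal(global_align(x, y)$score, oracle_global_score(x, y),
                 info = paste(x, y))
  }

  # single mismatch column
  a2 <- global_align("A", "T")
  expect_equal(a2$ref_aln, "A")
  expect_equal(a2$other_aln, "T")
  expect_error(global_align("", "ACGT"), "usage error")
})

test_that("windowed identity counts matches, gaps and N as specified", {
  aln <- pairwise_alignment(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_true(all(windowed_identity(aln, 50) == 100))

  # exactly 10 mismatch columns inside the first 50-column window
  ref <- strrep("ACGT", 25)
  other <- paste0(chartr("ACGT", "CGTA", substr(ref, 1, 10)), substr(ref, 11, 100))
  aln2 <- pairwise_alignment(ref, other)
  expect_equal(windowed_identity(aln2, 50)[1], 80)

  # an all-gap other row scores zero everywhere
  aln3 <- pairwise_alignment(strrep("ACGT", 25), strrep("-", 100))
  expect_true(all(windowed_identity(aln3, 50) == 0))
  expect_error(windowed_identity(aln, 0), "usage error")
  expect_error(windowed_identity(aln, 200), "usage error")
})

make_planted_alignment <- function(n = 3000, plant_at = 1200, plant_len = 200,
                                   seed = 1) {
  # background ~25% identity, planted segment >=90% identity
  set.seed(seed)
  ref <- rand_seq(n)
  oth <- rand_seq(n)
  rv <- strsplit(ref, "")[[1]]
  ov <- strsplit(oth, "")[[1]]
  idx <- plant_at:(plant_at + plant_len - 1)
  keep <- runif(plant_len) < 0.92
  ov[idx][keep] <- rv[idx][keep]
  list(aln = pairwise_alignment(ref, paste(ov, collapse = "")),
       start = plant_at - 1, end = plant_at + plant_len - 1)
}

test_that("call_cnes recovers planted elements and rejects weak similarity", {
  pl <- make_planted_alignment(seed = 31)
  cn <- call_cnes(pl$aln)
  expect_equal(nrow(cn), 1)
  ov <- min(cn$end[1], pl$end) - max(cn$start[1], pl$start)
  expect_gte(ov / (pl$end - pl$start), 0.8)
  expect_gte(ov / (cn$end[1] - cn$start[1]), 0.8)

  # an alignment at a uniform 50% identity (strict alternation) yields nothing
  set.seed(8)
  rv <- strsplit(rand_seq(2000), "")[[1]]
  ov2 <- rv
  odd <- seq(1, 2000, by = 2)
  ov2[odd] <- chartr("ACGT", "CGTA", rv[odd])
  weak <- pairwise_alignment(paste(rv, collapse = ""), paste(ov2, collapse = ""))
  expect_equal(nrow(call_cnes(weak)), 0)

  # a passing region fully inside the coding mask is dropped
  mask <- gi("ref", pl$start - 60, pl$end + 60)
  expect_equal(nrow(call_cnes(pl$aln, coding_mask = mask)), 0)
})

test_that("every emitted CNE meets the thresholds and calls do not overlap", {
  for (sd in c(41, 42, 43)) {
    pl <- make_planted_alignment(n = 6000, plant_at = 500, plant_len = 400,
                                 seed = sd)
    cn <- call_cnes(pl$aln)
    expect_true(all(cn$identity >= 65))
    expect_true(all(cn$end - cn$start >= 50))
    if (nrow(cn) > 1) {
      expect_true(all(diff(cn$start) > 0))
      expect_true(all(cn$start[-1] >= cn$end[-nrow(cn)]))
    }
  }
})

test_that("call_cnes equals the naive oracle, with and without masking and gaps", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(500:1900, 1)
    plant_at <- sample(100:(n - 320), 1)
    pl <- make_planted_alignment(n = n, plant_at = plant_at,
                                 plant_len = sample(c(120, 200, 300), 1),
                                 seed = 500 + rep)
    # random gap columns sprinkled into both rows away from each other
    rv <- strsplit(pl$aln$ref_aln, "")[[1]]
    ov <- strsplit(pl$aln$other_aln, "")[[1]]
    gap_i <- sample(n, 10)
    ov[gap_i[1:5]] <- "-"
    rv[gap_i[6:10]] <- "-"
    aln <- pairwise_alignment(paste(rv, collapse = ""), paste(ov, collapse = ""))
    mask <- if (rep %% 3 == 0)
      gi("ref", plant_at + 20, plant_at + 90) else NULL

    got <- call_cnes(aln, coding_mask = mask)
    exp <- oracle_call_cnes(aln, coding_mask = mask)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$identity, exp$identity, tolerance = 1e-12)
      expect_equal(got$aln_span, exp$aln_span)
    }
  }
})

test_that("match_cnes projects coordinates and allows one-to-many links", {
  ref <- rand_seq(1000)
  aln <- pairwise_alignment(ref, ref)
  ref_cnes <- data.frame(start = c(100, 500), end = c(300, 600))
  other_cnes <- data.frame(start = c(120, 220, 800), end = c(180, 290, 900))
  m <- match_cnes(ref_cnes, other_cnes, aln)
  expect_equal(m[[1]], c(1L, 2L))   # one ref CNE spans two other CNEs
  expect_equal(length(m[[2]]), 0)

  # identical sets give a perfect 1:1 matching
  m2 <- match_cnes(ref_cnes, ref_cnes, aln)
  expect_equal(m2, list(1L, 2L))

  # disjoint sets match nothing
  m3 <- match_cnes(ref_cnes, data.frame(start = 700, end = 750), aln)
  expect_equal(lengths(m3), c(0L, 0L))
})

test_that("CNE groups follow the fixed clade priority with fall-through", {
  cnes <- data.frame(seq_id = "ref", start = c(0, 100, 200, 300),
                     end = c(50, 150, 250, 350), identity = 80,
                     aln_span = 50, group = "unassigned", in_intron = FALSE)
  hits <- list(
    elephant_shark = data.frame(start = 0, end = 40),
    spotted_gar = data.frame(start = 110, end = 140),
    coelacanth = data.frame(start = c(10, 210), end = c(30, 240))
  )
  out <- classify_cne_groups(cnes, per_species_hits = hits)
  # shark + coelacanth overlap -> gnathostome wins by priority
  expect_equal(out$group, c("gnathostome", "osteichthyan", "sarcopterygian",
                            "tetrapod"))
  # each CNE gets exactly one group
  expect_true(all(table(seq_len(nrow(out))) == 1))
  expect_error(classify_cne_groups(cnes, presence = list(archosaur = "chicken")),
               "config error")
})

test_that("the summary table adds up by cluster and in total", {
  empty <- cne_summary_table(list(HoxA = data.frame(group = character())))
  expect_true(all(empty[empty$cluster == "HoxA", -1] == 0))

  cls <- list(
    HoxA = data.frame(group = c(rep("gnathostome", 3), rep("tetrapod", 2))),
    HoxD = data.frame(group = c("sarcopterygian", "tetrapod"))
  )
  tab <- cne_summary_table(cls)
  expect_equal(tab$total[tab$cluster == "HoxA"], 5)
  expect_equal(tab$total[tab$cluster == "total"], 7)
  expect_equal(tab$gnathostome[tab$cluster == "total"], 3)
  groups <- c("gnathostome", "osteichthyan", "sarcopterygian", "tetrapod")
  expect_equal(rowSums(tab[groups]), tab$total)
})
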