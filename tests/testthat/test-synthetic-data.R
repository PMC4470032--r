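test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config("((a:0.1,b:0.2):0.05,c:0.3);", 5000,
                           cne_spec = data.frame(position = 1000, length = 150,
                                                 scaling = 0.1),
                           exon_spec = data.frame(position = 3000, length = 200),
                           seed = 77)
  g1 <- simulate_clusters(cfg)
  g2 <- simulate_clusters(cfg)
  expect_identical(g1, g2)
  g3 <- simulate_clusters(simulation_config("((a:0.1,b:0.2):0.05,c:0.3);", 5000,
                                            seed = 78))
  expect_false(identical(g1$clusters$a$sequence, g3$clusters$a$sequence))
})

test_that("zero branch lengths give identical species sequences", {
  cfg <- simulation_config("(a:0,b:0);", 3000, seed = 3)
  gt <- simulate_clusters(cfg)
  expect_identical(gt$clusters$a$sequence, gt$clusters$b$sequence)
  expect_true(all(gt$substitutions$n_substitutions == 0))
})

test_that("realized divergence follows the Jukes-Cantor closed form", {
  # one branch of 0.2 subs/site over 10,000 neutral sites, 50 replicates:
  # observed mean proportion of differing sites within 3 standard errors of
  # (3/4)(1 - exp(-4*0.2/3))
  expected <- jc_expected_divergence(0.2)
  props <- vapply(1:50, function(r) {
    gt <- simulate_clusters(simulation_config("(a:0.2,b:0);", 10000, seed = r))
    a <- strsplit(gt$clusters$a$sequence, "")[[1]]
    b <- strsplit(gt$clusters$b$sequence, "")[[1]]
    mean(a != b)
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / 10000) / sqrt(50)
  expect_lt(abs(mean(props) - expected), 3 * se)
})

test_that("conservation scaling orders within-element identity", {
  # lower scaling = more conserved: mean pairwise identity inside
  # low-scaling CNEs is at least that of high-scaling CNEs over replicates
  id_by_scaling <- function(s, seeds) {
    mean(vapply(seeds, function(sd) {
      cfg <- simulation_config("(a:0.5,b:0.5);", 3000,
                               cne_spec = data.frame(position = 500, length = 300,
                                                     scaling = s),
                               seed = sd)
      gt <- simulate_clusters(cfg)
      a <- strsplit(substr(gt$clusters$a$sequence, 501, 800), "")[[1]]
      b <- strsplit(substr(gt$clusters$b$sequence, 501, 800), "")[[1]]
      mean(a == b)
    }, numeric(1)))
  }
  seeds <- 1:100
  expect_gte(id_by_scaling(0.05, seeds), id_by_scaling(0.5, seeds))
  expect_gte(id_by_scaling(0.5, seeds), id_by_scaling(1, seeds))
})

test_that("CNE loss replaces the element only in non-retaining species", {
  cfg <- simulation_config("(a:0,b:0);", 4000,
                           cne_spec = data.frame(position = 1000, length = 200,
                                                 scaling = 0.1,
                                                 retained_in = "a"),
                           seed = 12)
  gt <- simulate_clusters(cfg)
  a <- gt$clusters$a$sequence
  b <- gt$clusters$b$sequence
  expect_identical(substr(a, 1, 1000), substr(b, 1, 1000))
  expect_identical(substr(a, 1201, 4000), substr(b, 1201, 4000))
  expect_false(identical(substr(a, 1001, 1200), substr(b, 1001, 1200)))
  # ground truth lists the element only for the retaining species
  expect_identical(gt$cne_truth$species, "a")
})

test_that("plant_inverted_repeat writes exact coordinates and structure", {
  seq1k <- rand_seq(1000)
  pl <- plant_inverted_repeat(seq1k, 120, 10, 0, seed = 4)
  expect_equal(pl$pair$arm1_start, 0)
  expect_equal(pl$pair$arm1_end, 120)
  expect_equal(pl$pair$arm2_start, 130)
  expect_equal(pl$pair$arm2_end, 250)
  expect_equal(pl$pair$orientation, "inverted")
  expect_equal(nchar(pl$sequence), 1000)

  # second arm is the reverse complement of the first before mutation
  arm1 <- substr(pl$sequence, 1, 120)
  arm2 <- substr(pl$sequence, 131, 250)
  expect_identical(arm2, revcomp(arm1))
  expect_equal(pl$pair$arm_identity, 100)

  # footprint of a 125 bp arm with an 8 bp spacer
  pl2 <- plant_inverted_repeat(rand_seq(1000), 125, 8, 100, seed = 5)
  expect_equal(pl2$pair$arm2_end - pl2$pair$arm1_start, 258)

  expect_error(plant_inverted_repeat(seq1k, 0, 10, 0), "config error")
  expect_error(plant_inverted_repeat(seq1k, 480, 100, 0), "config error")
})

test_that("overlapping planted elements are rejected at config time", {
  expect_error(
    simulation_config("(a:0.1,b:0.1);", 2000,
                      cne_spec = data.frame(position = c(100, 150),
                                            length = c(100, 100),
                                            scaling = 0.1)),
    "overlap")
  expect_error(
    simulation_config("(a:0.1,b:0.1);", 2000,
                      cne_spec = data.frame(position = 1950, length = 100,
                                            scaling = 0.1)),
    "outside")
})

test_that("planted repeats are recorded per species with realized identity", {
  cfg <- simulation_config("(a:0.1,b:0.1);", 5000,
    repeat_spec = data.frame(kind = c("inverted", "direct"),
                             arm_length = c(120, 80), spacer_length = c(10, 30),
                             position = c(1000, 3000),
                             mutation_rate = c(0, 0.05),
                             species = c(NA, "a")),
    seed = 9)
  gt <- simulate_clusters(cfg)
  rt <- gt$repeat_truth
  expect_equal(sum(rt$orientation == "inverted"), 2)  # both species
  expect_equal(sum(rt$orientation == "direct"), 1)    # species a only
  expect_true(all(rt$arm_identity[rt$orientation == "inverted"] == 100))
  expect_true(all(rt$arm_identity[rt$orientation == "direct"] < 100))
})
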