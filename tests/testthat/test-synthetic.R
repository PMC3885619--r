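test_that("simulated trees are deterministic, rooted and labelled", {
  tr <- simulate_tree(4, seed = 1)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 3L)
  expect_true(ape::is.rooted(tr))

  tr2 <- simulate_tree(4, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  big <- simulate_tree(50, seed = 2)
  expect_gt(sum(big$edge.length), 0)
  expect_false(anyDuplicated(big$tip.label) > 0)
  expect_equal(max(ape::node.depth.edgelength(big)), 1, tolerance = 1e-12)

  expect_error(simulate_tree(2, seed = 1), class = "coevo_input_error")
})

test_that("the simulated bundle is internally consistent and deterministic", {
  sim <- small_sim(5, n_org = 10, len = 60)
  expect_s3_class(sim$famA, "aligned_family")
  # paralog expansion: org01 holds 2 A- and 2 B-members -> 4 pairing rows
  expect_equal(sum(sim$pairing$organism_id == "org01"), 4L)
  expect_equal(nrow(sim$pairing), 9L + 4L)
  # clades are the two root subtrees and cover every organism
  expect_setequal(sim$clades$organism_id, sim$tree$tip.label)
  expect_equal(sort(unique(sim$clades$clade)), c("clade1", "clade2"))
  # truth lists the configured coupled pairs
  expect_equal(nrow(sim$truth$coupled_pairs), 5L)
  expect_equal(nrow(sim$truth$branch_rates), nrow(sim$tree$edge))

  sim2 <- small_sim(5, n_org = 10, len = 60)
  expect_identical(sim$famA$mat, sim2$famA$mat)
  expect_identical(sim$marker$mat, sim2$marker$mat)
})

test_that("fixture bundles round-trip through the package readers", {
  sim <- small_sim(6, n_org = 8, len = 50)
  dir1 <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim, dir1)
  famA <- read_alignment(paths[["famA"]], organism_map = tibble::tibble(
    seq_id = sim$famA$seq_ids, organism_id = sim$famA$organisms))
  expect_identical(famA$mat, sim$famA$mat)
  marker <- read_alignment(paths[["marker"]], alphabet = "DNA")
  expect_identical(marker$mat, sim$marker$mat)
  tr <- read_species_tree(paths[["tree"]], organisms = sim$clades$organism_id)
  expect_setequal(tr$tip.label, sim$tree$tip.label)
  pairing <- read_pairing(paths[["pairing"]], famA = famA)
  expect_equal(nrow(pairing), nrow(sim$pairing))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$coupled_pairs), nrow(sim$truth$coupled_pairs))

  # same simulation object -> byte-identical bundle
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture_bundle(sim, dir2)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]),
                     label = nm)
  }
})

test_that("uncoupled, rate-uncorrelated families carry no mirror signal", {
  Rs <- vapply(1:25, function(s) {
    sim <- small_sim(600 + s, n_org = 12, len = 100,
                     n_coupled = 0, rate_correlation = 0,
                     duplicate_first_organism = FALSE)
    res <- tol_mirrortree(sim$famA, sim$famB, sim$pairing,
                          marker = sim$marker, n_perm = 99, seed = s)
    res$R
  }, numeric(1))
  expect_lt(abs(mean(Rs)), 0.1)
})

test_that("marker distances track tree distance (clock property)", {
  # true pairwise distances take one value per MRCA node, so most pairs
  # are exact ties; monotonicity in expectation is therefore tested on
  # the mean marker distance within each true-distance value
  rank_cors <- vapply(1:20, function(s) {
    tr <- simulate_tree(30, seed = 700 + s)
    cfg <- sim_config(n_organisms = 30, len_a = 30, len_b = 30,
                      n_coupled = 0, len_marker = 1500, rate_marker = 0.5,
                      duplicate_first_organism = FALSE)
    sim <- simulate_families(tr, cfg, seed = 750 + s)
    md <- p_distance(sim$marker)
    td <- ape::cophenetic.phylo(tr)[rownames(md), colnames(md)]
    x <- md[upper.tri(md)]
    y <- signif(td[upper.tri(td)], 10)
    gm <- tapply(x, y, mean)
    cor(gm, as.numeric(names(gm)), method = "spearman")
  }, numeric(1))
  expect_gt(mean(rank_cors), 0.9)
})

test_that("recovery of planted pairs never falls as compensation rises", {
  recovery_at <- function(prob) {
    hits <- 0L
    for (s in 1:8) {
      tr <- simulate_tree(20, seed = 800 + s)
      cfg <- sim_config(n_organisms = 20, len_a = 120, len_b = 120,
                        n_coupled = 5, compensation_prob = prob)
      sim <- simulate_families(tr, cfg, seed = 850 + s)
      scan <- suppressWarnings(caps_scan(sim$famA, sim$famB, sim$pairing,
                                         n_resample = 300, seed = 880 + s))
      key <- paste(sim$truth$coupled_pairs$site_a,
                   sim$truth$coupled_pairs$site_b)
      hits <- hits + sum(key %in% paste(scan$significant$site_a,
                                        scan$significant$site_b))
    }
    hits / (5 * 8)
  }
  r0 <- recovery_at(0)
  r5 <- recovery_at(0.5)
  r1 <- recovery_at(1)
  expect_lte(r0, r5 + 0.1)
  expect_lte(r5, r1 + 0.1)
  expect_gt(r1, r0)
})
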