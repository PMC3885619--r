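# A 4-sequence toy family whose theta values are hand-checkable: column 6
# carries the pattern A A S S, all other columns make the sequences
# pairwise distinct so every divergence is positive.
caps_toy <- function() {
  aligned_family(
    c("s1", "s2", "s3", "s4"), c("o1", "o2", "o3", "o4"),
    c("MKWDEAFHIKRN", "MRWEDAYHLKRN", "CKYDESFHVRRN", "CRYEDSYHMRRN"),
    family_name = "caps_toy"
  )
}

test_that("site profiles normalize substitution scores by divergence", {
  fam <- caps_toy()
  pairs <- t(combn(fam$seq_ids, 2L))
  prof <- site_profiles(fam, pairs, min_divergence = 0)
  expect_s3_class(prof, "site_profiles")
  expect_equal(nrow(prof$theta), 6L)

  # invariant columns (e.g. the final N) are excluded
  expect_false(12L %in% prof$sites)
  expect_true(6L %in% prof$sites)

  # hand tabulation for column 6 (A A S S) against BLOSUM62 scores,
  # divided by each pair's Poisson-corrected p-distance
  b62 <- get_subst_matrix("BLOSUM62")
  pd <- poisson_correct_matrix(p_distance(fam))
  col6 <- c(s1 = "A", s2 = "A", s3 = "S", s4 = "S")
  expected <- vapply(seq_len(nrow(pairs)), function(k) {
    b62[col6[[pairs[k, 1]]], col6[[pairs[k, 2]]]] /
      pd[pairs[k, 1], pairs[k, 2]]
  }, numeric(1))
  got <- prof$theta[, as.character(6L)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)

  # a two-sequence family gives a single-entry profile
  fam2 <- aligned_family(c("x", "y"), c("ox", "oy"),
                         c("MKWDEA", "MRWEDS"))
  prof2 <- site_profiles(fam2, cbind("x", "y"), min_divergence = 0)
  expect_equal(nrow(prof2$theta), 1L)

  # identical sequences cannot be divergence-normalized
  fam3 <- aligned_family(c("x", "y"), c("ox", "oy"), c("MKAA", "MKAA"))
  expect_warning(p3 <- site_profiles(fam3, cbind("x", "y")), "dropped")
  expect_equal(nrow(p3$theta), 0L)
})

test_that("intermolecular correlations hit the exact-copy extremes", {
  fam <- caps_toy()
  pairs <- t(combn(fam$seq_ids, 2L))
  prof <- site_profiles(fam, pairs, min_divergence = 0)
  cors <- intermolecular_correlations(prof, prof)
  self <- dplyr::filter(cors, site_a == site_b)
  expect_true(all(abs(self$rho - 1) < 1e-12))

  # a negated profile gives rho = -1
  neg <- prof
  neg$theta <- -prof$theta
  cors2 <- intermolecular_correlations(prof, neg)
  self2 <- dplyr::filter(cors2, site_a == site_b)
  expect_true(all(abs(self2$rho + 1) < 1e-12))

  # rho is symmetric under swapping the two profiles
  cors_ab <- intermolecular_correlations(prof, neg)
  cors_ba <- intermolecular_correlations(neg, prof)
  merged <- dplyr::inner_join(
    cors_ab, cors_ba, by = c(site_a = "site_b", site_b = "site_a"))
  expect_equal(merged$rho.x, merged$rho.y, tolerance = 1e-12)
})

test_that("significance filter calibrates near alpha on unrelated families", {
  sim <- suppressWarnings(small_sim(77, n_org = 15, len = 120,
                                    n_coupled = 0, rate_correlation = 0))
  scan <- suppressWarnings(caps_scan(sim$famA, sim$decoy,
                                     decoy_pairing(sim),
                                     n_resample = 1000, seed = 4))
  rate <- nrow(scan$significant) / nrow(scan$correlations)
  expect_lt(rate, 2 * 0.05)
  expect_gt(rate, 0.05 / 4)
  expect_error(
    significance_filter(scan$correlations, scan$profiles$A,
                        scan$profiles$B, n_resample = 50),
    class = "coevo_input_error"
  )
})

test_that("connectivity grouping forms deterministic connected components", {
  pairs <- tibble::tibble(
    site_a = c(1L, 1L, 3L), site_b = c(1L, 2L, 7L),
    rho = c(0.9, 0.8, 0.7)
  )
  g <- build_groups(pairs)
  expect_equal(nrow(g), 2L)
  expect_equal(g$group_id, c("G1", "G2"))
  expect_equal(g$sites_a[[1]], 1L)
  expect_equal(g$sites_b[[1]], c(1L, 2L))
  expect_equal(g$sites_a[[2]], 3L)
  expect_equal(g$mean_rho[1], 0.85)

  # cross-family chain joins through the shared B site
  chain <- tibble::tibble(site_a = c(1L, 2L), site_b = c(1L, 1L),
                          rho = c(0.9, 0.9))
  g2 <- build_groups(chain)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$sites_a[[1]], c(1L, 2L))
  expect_equal(g2$sites_b[[1]], 1L)

  # groups partition the significant pairs
  expect_equal(sum(g$n_pairs), nrow(pairs))
  expect_equal(nrow(build_groups(pairs[0, ])), 0L)
})

test_that("planted compensatory pairs surface among the top correlations", {
  hits <- 0L
  top_frac <- 0L
  n_seed <- 10L
  for (s in seq_len(n_seed)) {
    tr <- simulate_tree(30, seed = 4000 + s)
    cfg <- sim_config(n_organisms = 30, len_a = 200, len_b = 200,
                      n_coupled = 5, compensation_prob = 1)
    sim <- simulate_families(tr, cfg, seed = 4500 + s)
    scan <- suppressWarnings(caps_scan(sim$famA, sim$famB, sim$pairing,
                                       n_resample = 500, seed = 4900 + s))
    planted <- sim$truth$coupled_pairs
    key <- paste(planted$site_a, planted$site_b)
    sig_key <- paste(scan$significant$site_a, scan$significant$site_b)
    hits <- hits + sum(key %in% sig_key)
    cutoff <- stats::quantile(scan$correlations$rho, 0.95)
    in_top <- dplyr::semi_join(scan$correlations, planted,
                               by = c("site_a", "site_b"))$rho >= cutoff
    top_frac <- top_frac + sum(in_top)
  }
  # recovery of planted pairs in the significant set (regression bound)
  expect_gte(hits / (5 * n_seed), 0.6)
  # planted pairs sit in the top-|rho| 5% most of the time
  expect_gte(top_frac / (5 * n_seed), 0.6)
})

test_that("caps scan output contract and plot", {
  sim <- suppressWarnings(small_sim(88, n_org = 12, len = 80))
  scan <- suppressWarnings(caps_scan(sim$famA, sim$famB, sim$pairing,
                                     n_resample = 200, seed = 9))
  expect_s3_class(scan, "caps_result")
  g <- glance(scan)
  expect_equal(g$n_significant, nrow(scan$significant))
  expect_true(all(tidy(scan)$rho >= -1 & tidy(scan)$rho <= 1))
  expect_s3_class(autoplot(scan), "ggplot")
})
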