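test_that("p-distance counts mismatches over comparable columns", {
  fam <- aligned_family(c("a", "b"), c("oa", "ob"), c("AAAA", "AAAA"))
  expect_equal(unname(p_distance(fam)["a", "b"]), 0)

  fam2 <- aligned_family(c("a", "b"), c("oa", "ob"), c("AAAA", "AAAT"))
  expect_equal(unname(p_distance(fam2)["a", "b"]), 0.25)

  # pairwise deletion: the gapped column is skipped for this pair
  fam3 <- aligned_family(c("a", "b"), c("oa", "ob"), c("A-AA", "AGAT"))
  expect_equal(unname(p_distance(fam3)["a", "b"]), 1 / 3)

  # zero comparable columns flagged missing, never 0
  fam4 <- aligned_family(c("a", "b"), c("oa", "ob"), c("AA--", "--TT"))
  expect_true(is.na(p_distance(fam4)["a", "b"]))

  # complete deletion drops columns with any gap for every pair
  fam5 <- aligned_family(c("a", "b", "c"), c("oa", "ob", "oc"),
                         c("A-AA", "AGAT", "AGAT"))
  expect_equal(unname(p_distance(fam5, mode = "complete")["a", "b"]), 1 / 3)

  d <- p_distance(toy_family())
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(nrow(tidy(d)), 6L)
})

test_that("Poisson correction matches its closed form and is monotone", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.1), -log(0.9), tolerance = 1e-12)
  expect_equal(poisson_correct(0.5), -log(0.5), tolerance = 1e-12)
  expect_error(poisson_correct(1), class = "coevo_saturation_error")

  p <- seq(0, 0.95, by = 0.05)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("mean pairwise identity averages comparable-column identity", {
  fam <- aligned_family(c("a", "b"), c("oa", "ob"), c("AAAA", "AAAA"))
  expect_equal(mean_pairwise_identity(fam), 100)
  fam2 <- aligned_family(c("a", "b"), c("oa", "ob"), c("AAAA", "AAAT"))
  expect_equal(mean_pairwise_identity(fam2), 75)
})

test_that("Kimura-2P distance matches its closed form", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
  expect_equal(kimura2p(0, 0.05),
               -0.5 * log(0.95) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_error(kimura2p(0.4, 0.25), class = "coevo_saturation_error")

  # Jukes-Cantor regime: transitions are one of three change types, so
  # Q = 2P, where the K2P form collapses to -3/4 log(1 - 4/3 p)
  P <- seq(0.01, 0.2, by = 0.01)
  p <- 3 * P
  expect_equal(kimura2p(P, 2 * P), -0.75 * log(1 - 4 / 3 * p),
               tolerance = 1e-12)

  expect_equal(kimura2p_pair("ACGT", "ACGT"), 0)
  # one transition (G->A) in 4 sites: P = 0.25, Q = 0
  expect_equal(kimura2p_pair("ACGT", "ACAT"), kimura2p(0.25, 0),
               tolerance = 1e-12)
})

test_that("dN/dS counting separates synonymous and nonsynonymous change", {
  # identical pair: no differences at all
  r0 <- dnds_pair("ATGAAATTT", "ATGAAATTT")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_false(r0$omega_defined)

  # Phe TTT -> TTC: one synonymous transition; too short to de-saturate
  r1 <- dnds_pair("TTT", "TTC")
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$dN, 0)
  expect_gt(r1$pS, 0)
  expect_true(r1$dS_saturated)

  # Lys AAA -> Arg AGA: one nonsynonymous transition
  r2 <- dnds_pair("ATGAAA", "ATGAGA")
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  expect_equal(r2$dS, 0)
  expect_gt(r2$dN, 0)
  # hand site tabulation at kappa = 2: ATG contributes no synonymous
  # sites; AAA has 0.5 (third position, A<->G transition weighted 2 of 4,
  # with the T route excluded as a stop); AGA has 0.5 plus 1/3 at the
  # first position (AGA->CGA is Arg->Arg, the TGA route is a stop)
  expect_equal(r2$S, (0.5 + 0.5 + 1 / 3) / 2, tolerance = 1e-12)
  expect_equal(r2$N, 6 - (0.5 + 0.5 + 1 / 3) / 2, tolerance = 1e-12)

  # symmetry in the two sequences
  a <- "ATGAAATTTGGC"
  b <- "ATGAGATTCGGA"
  expect_equal(dnds_pair(a, b)[c("dN", "dS", "S", "N")],
               dnds_pair(b, a)[c("dN", "dS", "S", "N")])

  # difference counts are untouched by appending identical codons
  r3 <- dnds_pair(a, b)
  r4 <- dnds_pair(paste0(a, "GATGAC"), paste0(b, "GATGAC"))
  expect_equal(r4$Sd, r3$Sd)
  expect_equal(r4$Nd, r3$Nd)

  # two-codon-difference path averaging: gaps excluded pairwise
  r5 <- dnds_pair("ATG---AAA", "ATG---AGA")
  expect_equal(r5$Nd, 1)
})

test_that("family dN/dS summary averages defined pairs", {
  fam <- codon_family(
    c("a", "b", "c"), c("oa", "ob", "oc"),
    c("ATGAAAGATTTTCTGAGC", "ATGAGAGATTTCCTGAGC", "ATGAAAGACTTTTTGAGT")
  )
  rs <- dnds_family(fam)
  expect_s3_class(rs, "rate_summary")
  expect_equal(nrow(tidy(rs)), 3L)
  g <- glance(rs)
  expect_true(g$mean_dN >= 0)
  expect_equal(g$n_pairs, 3L)
})

test_that("two-sample Z comparison behaves at the extremes and under the null", {
  same <- z_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  sep <- z_compare(c(0, 0, 0, 0) + rnorm(4, sd = 1e-6),
                   c(1, 1, 1, 1) + rnorm(4, sd = 1e-6))
  expect_gt(abs(sep$z), 50)
  expect_lt(sep$p_value, 1e-10)

  # Monte-Carlo calibration at alpha = 0.05
  set.seed(42)
  rej <- mean(vapply(seq_len(1000), function(i) {
    z_compare(rnorm(100), rnorm(100))$p_value <= 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
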