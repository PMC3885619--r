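test_that("FASTA alignments parse with organism mapping and validation", {
  path <- write_toy_fasta(c(s1 = "MKAAWVLDER", s2 = "MKASWVLDER"))
  fam <- read_alignment(path)
  expect_s3_class(fam, "aligned_family")
  expect_equal(fam$n_cols, 10L)
  expect_equal(fam$seq_ids, c("s1", "s2"))

  # explicit organism map wins over header-derived ids
  map <- tibble::tibble(seq_id = c("s1", "s2"), organism_id = c("oA", "oB"))
  fam2 <- read_alignment(path, organism_map = map)
  expect_equal(fam2$organisms, c("oA", "oB"))

  # configurable header regex
  path3 <- write_toy_fasta(c(At_MAGO = "MKAA", Os_MAGO = "MKAS"))
  fam3 <- read_alignment(path3, organism_regex = "^([A-Za-z]+)_")
  expect_equal(fam3$organisms, c("At", "Os"))

  # ragged alignment refused
  bad <- write_toy_fasta(c(s1 = "MKAAWVLDER", s2 = "MKASWVLDE"))
  expect_error(read_alignment(bad), class = "coevo_alignment_error")

  # duplicate ids refused
  dup <- write_toy_fasta(c("MKAA", "MKAS"), ids = c("s1", "s1"))
  expect_error(read_alignment(dup), class = "coevo_input_error")
})

test_that("FASTA and newick round-trip byte-identically", {
  fam <- toy_family()
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(fam, out)
  fam2 <- read_alignment(out, organism_map = tibble::tibble(
    seq_id = fam$seq_ids, organism_id = fam$organisms))
  expect_identical(fam2$mat, fam$mat)
  out2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(fam2, out2)
  expect_identical(readLines(out), readLines(out2))

  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2):0.5,(c:1,d:1):1);", nwk)
  tr <- read_species_tree(nwk)
  expect_equal(ape::Ntip(tr), 4L)
  nwk2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, file = nwk2)
  expect_identical(ape::read.tree(nwk2)$tip.label, tr$tip.label)
  expect_equal(ape::read.tree(nwk2)$edge.length, tr$edge.length)
})

test_that("alignment columns map to ungapped reference coordinates", {
  fam <- aligned_family("r", "o", "M-AG")
  expect_equal(column_to_reference(fam, "r", 3L), 2L)
  expect_true(is.na(column_to_reference(fam, "r", 2L)))
  expect_equal(column_to_reference(fam, "r", c(1L, 4L)), c(1L, 3L))
  expect_error(column_to_reference(fam, "r", 5L), class = "coevo_input_error")

  # no-gap reference: identity mapping
  fam2 <- aligned_family("r", "o", "MKAG")
  expect_equal(column_to_reference(fam2, "r", 1:4), 1:4)

  # inverse composes to identity on non-gap columns
  cols <- which(!is.na(column_to_reference(fam, "r", 1:4)))
  res <- column_to_reference(fam, "r", cols)
  expect_equal(reference_to_column(fam, "r", res), cols)
})

test_that("pairing, region and clade tables validate cross-references", {
  famA <- toy_family()
  famB <- aligned_family(paste0("y", 1:4), paste0("o", 1:4),
                         rep("MKLW", 4), family_name = "B")
  pairing <- tibble::tibble(
    organism_id = c("o1", "o1", "o1", "o1", "o2"),
    member_a = c("s1", "s1", "s2", "s2", "s2"),
    member_b = c("y1", "y2", "y1", "y2", "y2")
  )
  # an organism with 2 A-members and 2 B-members contributes 4 rows
  ok <- read_pairing(pairing, famA = famA, famB = famB)
  expect_equal(sum(ok$organism_id == "o1"), 4L)
  bad <- dplyr::mutate(pairing, member_b = "nope")
  expect_error(read_pairing(bad, famA = famA, famB = famB),
               class = "coevo_crossref_error")

  regions <- tibble::tibble(region_name = "core", reference_seq_id = "s1",
                            start = 2L, end = 8L)
  expect_equal(nrow(read_regions(regions, families = list(famA))), 1L)
  too_long <- dplyr::mutate(regions, end = 99L)
  expect_error(read_regions(too_long, families = list(famA)),
               class = "coevo_input_error")
  expect_error(read_regions(dplyr::mutate(regions, start = 0L)),
               class = "coevo_input_error")

  clades <- tibble::tibble(organism_id = c("o1", "o2", "o1"),
                           clade = c("x", "y", "y"))
  expect_error(read_clades(clades), class = "coevo_input_error")
})

test_that("codon alignments enforce frame, whole-codon gaps and stops", {
  ok <- codon_family(c("a", "b"), c("oa", "ob"),
                     c("ATGAAATTT", "ATG---TTC"))
  expect_equal(ok$n_cols, 9L)
  expect_error(
    codon_family("a", "oa", "ATGA"),
    class = "coevo_codon_error"
  )
  expect_error(  # gap splits a codon
    codon_family("a", "oa", "AT-AAATTT"),
    class = "coevo_codon_error"
  )
  expect_error(  # internal stop
    codon_family("a", "oa", "ATGTAATTT"),
    class = "coevo_codon_error"
  )
})

test_that("interaction matrices keep bait/prey orientation and complete grid", {
  tab <- tibble::tibble(
    bait_id = c("MAGO_At", "MAGO_At", "Y14_At"),
    prey_id = c("Y14_At", "Y14_Os", "MAGO_At"),
    outcome = c("interacts", "none", "interacts")
  )
  out <- read_interactions(tab)
  # completed over declared baits x preys; missing cells are untested
  expect_equal(nrow(out), 2L * 3L)
  expect_equal(
    out$outcome[out$bait_id == "Y14_At" & out$prey_id == "Y14_Os"],
    "untested"
  )
  expect_error(
    read_interactions(dplyr::mutate(tab, outcome = "maybe")),
    class = "coevo_input_error"
  )
})
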