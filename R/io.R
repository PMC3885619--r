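#' Codon-aligned coding sequence family
#'
#' Validates a codon alignment: length a multiple of three, gaps occurring
#' in whole-codon units, and no internal stop codons in the ungapped frame.
#'
#' @inheritParams aligned_family
#' @return An object of class `codon_family` (also an `aligned_family` with
#'   DNA alphabet).
#' @export
codon_family <- function(seq_ids, organisms, residues, family_name = "cds") {
  fam <- aligned_family(seq_ids, organisms, residues,
                        family_name = family_name, alphabet = "DNA")
  if (fam$n_cols %% 3L != 0L) {
    abort("codon alignment length not a multiple of 3",
          class = "coevo_codon_error")
  }
  n_codons <- fam$n_cols %/% 3L
  for (i in seq_along(fam$seq_ids)) {
    s <- fam$mat[i, ]
    cod <- matrix(s, nrow = 3L)
    gap_counts <- colSums(matrix(is_gap(s), nrow = 3L))
    if (any(gap_counts %in% c(1L, 2L))) {
      abort(paste0("gaps not in whole-codon units in ", fam$seq_ids[i]),
            class = "coevo_codon_error")
    }
    codons <- apply(cod, 2L, paste, collapse = "")
    ungapped <- codons[gap_counts == 0L]
    internal <- head(ungapped, -1L)
    if (any(internal %in% STOP_CODONS)) {
      abort(paste0("internal stop codon in ", fam$seq_ids[i]),
            class = "coevo_codon_error")
    }
  }
  class(fam) <- c("codon_family", class(fam))
  fam
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a codon-aligned CDS FASTA
#'
#' @inheritParams read_alignment
#' @return A [codon_family].
#' @export
read_codon_alignment <- function(path, organism_map = NULL, family_name = NULL,
                                 organism_regex = NULL) {
  fam <- read_alignment(path, organism_map = organism_map,
                        family_name = family_name, alphabet = "DNA",
                        organism_regex = organism_regex)
  codon_family(fam$seq_ids, fam$organisms, fam$mat,
               family_name = fam$family_name)
}

#' Read a family pairing table
#'
#' The pairing table maps organisms to one member of each of the two
#' interacting families; organisms with paralogs contribute one row per
#' member combination (m paralogs in family A times n in family B gives
#' m*n rows). Columns: `organism_id`, `member_a`, `member_b`.
#'
#' @param path TSV path or data frame with the three columns.
#' @param famA,famB Optional [aligned_family] objects; when given, members
#'   are validated against them.
#' @return A tibble with columns `organism_id`, `member_a`, `member_b`.
#' @export
read_pairing <- function(path, famA = NULL, famB = NULL) {
  tab <- if (is.character(path)) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else {
    as_tibble(path)
  }
  need <- c("organism_id", "member_a", "member_b")
  if (!all(need %in% names(tab))) {
    abort("pairing table needs columns organism_id, member_a, member_b",
          class = "coevo_input_error")
  }
  tab <- tab[need]
  check_members <- function(members, fam, side) {
    if (is.null(fam)) return(invisible())
    bad <- setdiff(members, fam$seq_ids)
    if (length(bad) > 0L) {
      abort(paste0("pairing ", side, " members not in alignment: ",
                   paste(bad, collapse = ", ")),
            class = "coevo_crossref_error")
    }
  }
  check_members(tab$member_a, famA, "A")
  check_members(tab$member_b, famB, "B")
  tab
}

#' Read region annotations
#'
#' Regions are 1-based inclusive intervals on the ungapped reference
#' sequence, e.g. a domain such as the MAGO-core (residues 16-158 of a rice
#' reference) or a minimal interaction domain. Columns: `region_name`,
#' `reference_seq_id`, `start`, `end`.
#'
#' @param path TSV path or data frame.
#' @param families Optional named list of [aligned_family] objects used to
#'   validate that each reference exists and the interval fits its ungapped
#'   length.
#' @return A tibble of regions.
#' @export
read_regions <- function(path, families = NULL) {
  tab <- if (is.character(path)) {
    readr::read_tsv(path, col_types = readr::cols(
      region_name = "c", reference_seq_id = "c", start = "i", end = "i"
    ), progress = FALSE)
  } else {
    as_tibble(path)
  }
  need <- c("region_name", "reference_seq_id", "start", "end")
  if (!all(need %in% names(tab))) {
    abort("regions need columns region_name, reference_seq_id, start, end",
          class = "coevo_input_error")
  }
  if (any(tab$start < 1L) || any(tab$end < tab$start)) {
    abort("region bounds must satisfy 1 <= start <= end",
          class = "coevo_input_error")
  }
  if (!is.null(families)) {
    for (k in seq_len(nrow(tab))) {
      ref <- tab$reference_seq_id[k]
      fam <- Find(function(f) ref %in% f$seq_ids, families)
      if (is.null(fam)) {
        abort(paste0("region reference not found in any family: ", ref),
              class = "coevo_crossref_error")
      }
      ref_len <- sum(!is_gap(ref_row(fam, ref)))
      if (tab$end[k] > ref_len) {
        abort(paste0("region '", tab$region_name[k],
                     "' exceeds ungapped reference length ", ref_len),
              class = "coevo_input_error")
      }
    }
  }
  tab[need]
}

#' Read a clade partition
#'
#' Maps each organism to exactly one named clade (e.g. dicot, monocot,
#' worm, fly, mammal). Columns: `organism_id`, `clade`.
#'
#' @param path TSV path or data frame.
#' @return A tibble with columns `organism_id`, `clade`.
#' @export
read_clades <- function(path) {
  tab <- if (is.character(path)) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else {
    as_tibble(path)
  }
  if (!all(c("organism_id", "clade") %in% names(tab))) {
    abort("clade table needs columns organism_id and clade",
          class = "coevo_input_error")
  }
  if (anyDuplicated(tab$organism_id)) {
    abort("organism assigned to more than one clade",
          class = "coevo_input_error")
  }
  tab[c("organism_id", "clade")]
}

#' Read a species tree (newick)
#'
#' Thin wrapper over [ape::read.tree()] that validates unique tip labels
#' and optionally that a set of organisms is covered.
#'
#' @param path Newick file path.
#' @param organisms Optional character vector that must all be tips.
#' @return An [ape::phylo] tree.
#' @export
read_species_tree <- function(path, organisms = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("could not parse newick", class = "coevo_input_error")
  if (anyDuplicated(tr$tip.label)) {
    abort("duplicate tip labels in species tree", class = "coevo_input_error")
  }
  if (!is.null(organisms)) {
    miss <- setdiff(organisms, tr$tip.label)
    if (length(miss) > 0L) {
      abort(paste0("organisms missing from tree: ",
                   paste(miss, collapse = ", ")),
            class = "coevo_crossref_error")
    }
  }
  tr
}

#' Read a bait-by-prey interaction matrix
#'
#' A long TSV with columns `bait_id`, `prey_id`, `outcome` where outcome is
#' one of `interacts`, `none`, `untested`. Bait/prey orientation is kept:
#' no symmetry is assumed.
#'
#' @param path TSV path or data frame.
#' @return A tibble with the three columns, completed over all declared
#'   bait/prey combinations (missing combinations become `untested`).
#' @export
read_interactions <- function(path) {
  tab <- if (is.character(path)) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else {
    as_tibble(path)
  }
  need <- c("bait_id", "prey_id", "outcome")
  if (!all(need %in% names(tab))) {
    abort("interaction table needs columns bait_id, prey_id, outcome",
          class = "coevo_input_error")
  }
  ok <- c("interacts", "none", "untested")
  if (!all(tab$outcome %in% ok)) {
    abort(paste0("outcome must be one of: ", paste(ok, collapse = ", ")),
          class = "coevo_input_error")
  }
  full <- tidyr::expand_grid(bait_id = unique(tab$bait_id),
                             prey_id = unique(tab$prey_id))
  out <- left_join(full, tab[need], by = c("bait_id", "prey_id"))
  out$outcome[is.na(out$outcome)] <- "untested"
  out
}
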