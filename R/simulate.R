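#' Simulation configuration for co-evolving families
#'
#' Defaults emulate the empirical setting the analysis is built for: two
#' slowly evolving interacting protein families on one shared species tree
#' of 36 eukaryote-like organisms, the first family (MAGO-like) evolving
#' more slowly than the second (Y14-like), strongly correlated lineage
#' rates, a handful of compensatory (coupled) site pairs, a clock-like
#' neutral nucleotide marker (an 18S rRNA analog), one organism carrying
#' duplicates of both families (as the cereal paralogs do), and an
#' uncorrelated decoy family (LFY analog).
#'
#' @param n_organisms Number of tips on the species tree.
#' @param birth_rate Pure-birth rate for the tree shape.
#' @param tree_height Height the tree is rescaled to (1 time unit).
#' @param len_a,len_b Protein family alignment lengths (columns).
#' @param rate_a,rate_b Expected substitutions per site per unit branch
#'   length; the defaults land family A near 80% and family B near 50%
#'   mean pairwise identity on the default 36-organism height-1 tree,
#'   the identity contrast characteristic of the MAGO and Y14 families.
#' @param rate_correlation Correlation of the per-branch log rate
#'   multipliers of families A and B.
#' @param rate_log_sd Standard deviation of the log multipliers.
#' @param n_coupled Number of planted compensatory site pairs (used when
#'   `coupled_pairs` is NULL; pairs are spread evenly along the
#'   alignments).
#' @param coupled_pairs Optional tibble with `site_a`, `site_b`.
#' @param compensation_prob Probability that a substitution at a coupled
#'   family-A site triggers a same-branch substitution at its partner.
#' @param coupled_rate Substitution rate of the coupled family-A sites
#'   (the compensatory channel): co-evolving positions are by definition
#'   the changing ones, so they run faster than family A's conserved
#'   background.
#' @param compensation_mode `"favorable"` picks the partner residue with
#'   the best BLOSUM62 score against the new family-A residue (easy case
#'   for the detector); `"random"` picks uniformly (hard case).
#' @param duplicate_first_organism Duplicate both families in the first
#'   organism (paralog case)?
#' @param len_marker,rate_marker Neutral marker length and clock rate.
#' @param len_decoy,rate_decoy Decoy family length and base rate (lineage
#'   multipliers independent of A and B).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_organisms = 36, birth_rate = 1, tree_height = 1,
                       len_a = 150, len_b = 175,
                       rate_a = 0.13, rate_b = 0.48,
                       rate_correlation = 0.9, rate_log_sd = 0.6,
                       n_coupled = 5, coupled_pairs = NULL,
                       compensation_prob = 0.8, coupled_rate = 0.75,
                       compensation_mode = c("favorable", "random"),
                       duplicate_first_organism = TRUE,
                       len_marker = 1500, rate_marker = 0.5,
                       len_decoy = 175, rate_decoy = 0.48) {
  compensation_mode <- match.arg(compensation_mode)
  if (is.null(coupled_pairs) && n_coupled > 0) {
    coupled_pairs <- tibble(
      site_a = as.integer(round(seq(len_a * 0.1, len_a * 0.9,
                                    length.out = n_coupled))),
      site_b = as.integer(round(seq(len_b * 0.15, len_b * 0.85,
                                    length.out = n_coupled)))
    )
  }
  if (is.null(coupled_pairs)) {
    coupled_pairs <- tibble(site_a = integer(), site_b = integer())
  }
  if (nrow(coupled_pairs) > 0 &&
      (any(coupled_pairs$site_a < 1 | coupled_pairs$site_a > len_a) ||
       any(coupled_pairs$site_b < 1 | coupled_pairs$site_b > len_b))) {
    abort("coupled site out of range", class = "coevo_input_error")
  }
  stopifnot(compensation_prob >= 0, compensation_prob <= 1,
            rate_correlation >= -1, rate_correlation <= 1,
            len_a > 0, len_b > 0, len_marker > 0, len_decoy > 0)
  structure(
    list(n_organisms = n_organisms, birth_rate = birth_rate,
         tree_height = tree_height, len_a = len_a, len_b = len_b,
         rate_a = rate_a, rate_b = rate_b,
         rate_correlation = rate_correlation, rate_log_sd = rate_log_sd,
         coupled_pairs = coupled_pairs,
         compensation_prob = compensation_prob, coupled_rate = coupled_rate,
         compensation_mode = compensation_mode,
         duplicate_first_organism = duplicate_first_organism,
         len_marker = len_marker, rate_marker = rate_marker,
         len_decoy = len_decoy, rate_decoy = rate_decoy),
    class = "sim_config"
  )
}

#' Simulate a pure-birth species tree
#'
#' @param n Number of tips (>= 3).
#' @param birth_rate Birth rate.
#' @param seed Optional integer seed (deterministic topology and branch
#'   lengths under the same seed).
#' @param height Height to rescale the tree to.
#' @return An [ape::phylo] with tips labelled `org01`, `org02`, ...
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = NULL, height = 1) {
  if (n < 3) abort("need n >= 3 organisms", class = "coevo_input_error")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("org%02d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth * height
  tr
}

substitute_uniform <- function(cur, alphabet) {
  pool <- alphabet[alphabet != cur]
  pool[sample.int(length(pool), 1L)]
}

favorable_partner <- function(a_new, cur_b, b62) {
  scores <- b62[a_new, AA_LETTERS]
  scores <- scores[names(scores) != cur_b]
  best <- names(scores)[scores == max(scores)]
  best[sample.int(length(best), 1L)]
}

evolve_protein_branch <- function(seq, rate, mult, len_branch, alphabet,
                                  allowed = NULL) {
  if (is.null(allowed)) allowed <- seq_along(seq)
  n_ev <- rpois(1L, rate * mult * length(allowed) * len_branch)
  hits <- integer(0)
  if (n_ev > 0L) {
    sites <- allowed[sample.int(length(allowed), n_ev, replace = TRUE)]
    for (s in sites) seq[s] <- substitute_uniform(seq[s], alphabet)
    hits <- unique(sites)
  }
  list(seq = seq, hits = hits)
}

#' Simulate two co-evolving families, a neutral marker and a decoy
#'
#' Sequences evolve along the tree under a uniform-exchange substitution
#' process (every change to another symbol equally likely; substitution
#' counts Poisson in rate x branch length). Families A and B share
#' per-branch lognormal rate multipliers with the configured correlation;
#' the decoy draws independent multipliers; the marker is strictly
#' clock-like. When a substitution lands on a coupled family-A site, the
#' partnered family-B site substitutes on the same branch with the
#' configured compensation probability (partner residue favorable or
#' random). An optional duplication copies the sequence at the first
#' organism's ancestral node into a second paralog that evolves
#' independently along the terminal branch.
#'
#' @param tree Species tree from [simulate_tree()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `coevo_sim` with [aligned_family] members
#'   `famA`, `famB`, `decoy`, `marker`, the `tree`, a `pairing` tibble, a
#'   `clades` tibble (the two root subtrees) and `truth` (coupled pairs,
#'   per-branch multipliers, duplications, config).
#' @export
simulate_families <- function(tree, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  b62 <- get_subst_matrix("BLOSUM62")
  dna <- c("A", "C", "G", "T")

  stateA <- vector("list", n_node)
  stateB <- vector("list", n_node)
  stateD <- vector("list", n_node)
  stateM <- vector("list", n_node)
  stateA[[root]] <- sample(AA_LETTERS, cfg$len_a, replace = TRUE)
  stateB[[root]] <- sample(AA_LETTERS, cfg$len_b, replace = TRUE)
  stateD[[root]] <- sample(AA_LETTERS, cfg$len_decoy, replace = TRUE)
  stateM[[root]] <- sample(dna, cfg$len_marker, replace = TRUE)

  coupled_of <- integer(cfg$len_a)
  if (nrow(cfg$coupled_pairs) > 0) {
    coupled_of[cfg$coupled_pairs$site_a] <- cfg$coupled_pairs$site_b
  }
  # planted partner sites in family B change only through the compensatory
  # channel: an uncompensated background change at a compensated site is
  # taken to be deleterious
  b_background <- setdiff(seq_len(cfg$len_b), cfg$coupled_pairs$site_b)
  a_background <- setdiff(seq_len(cfg$len_a), cfg$coupled_pairs$site_a)
  a_coupled <- cfg$coupled_pairs$site_a
  sdv <- cfg$rate_log_sd
  rho <- cfg$rate_correlation
  mults <- matrix(NA_real_, nrow(edge), 3L,
                  dimnames = list(NULL, c("mult_a", "mult_b", "mult_decoy")))

  # joint evolution of the two interacting families along one branch:
  # correlated lineage rate multipliers, conserved background in each
  # family, and a faster coupled channel in A whose hits trigger
  # same-branch compensatory substitutions at the planted partner sites
  evolve_AB <- function(seqA, seqB, t) {
    za <- rnorm(1L)
    zb <- rho * za + sqrt(1 - rho^2) * rnorm(1L)
    ma <- exp(sdv * za - sdv^2 / 2)
    mb <- exp(sdv * zb - sdv^2 / 2)
    seqA <- evolve_protein_branch(seqA, cfg$rate_a, ma, t, AA_LETTERS,
                                  allowed = a_background)$seq
    rc <- if (length(a_coupled) > 0L) {
      evolve_protein_branch(seqA, cfg$coupled_rate, ma, t, AA_LETTERS,
                            allowed = a_coupled)
    } else {
      list(seq = seqA, hits = integer(0))
    }
    seqA <- rc$seq
    for (s in rc$hits) {
      p <- coupled_of[s]
      if (p > 0L && runif(1L) < cfg$compensation_prob) {
        seqB[p] <- if (cfg$compensation_mode == "favorable") {
          favorable_partner(seqA[s], seqB[p], b62)
        } else {
          substitute_uniform(seqB[p], AA_LETTERS)
        }
      }
    }
    seqB <- evolve_protein_branch(seqB, cfg$rate_b, mb, t, AA_LETTERS,
                                  allowed = b_background)$seq
    list(A = seqA, B = seqB, ma = ma, mb = mb)
  }

  evolve_edge <- function(k, seqA, seqB, seqD, seqM) {
    t <- elen[k]
    ab <- evolve_AB(seqA, seqB, t)
    zd <- rnorm(1L)
    md <- exp(sdv * zd - sdv^2 / 2)
    seqD <- evolve_protein_branch(seqD, cfg$rate_decoy, md, t, AA_LETTERS)$seq
    seqM <- evolve_protein_branch(seqM, cfg$rate_marker, 1, t, dna)$seq
    list(A = ab$A, B = ab$B, D = seqD, M = seqM,
         mults = c(ab$ma, ab$mb, md))
  }

  for (k in rev(seq_len(nrow(edge)))) {   # preorder
    parent <- edge[k, 1L]
    child <- edge[k, 2L]
    ev <- evolve_edge(k, stateA[[parent]], stateB[[parent]],
                      stateD[[parent]], stateM[[parent]])
    stateA[[child]] <- ev$A
    stateB[[child]] <- ev$B
    stateD[[child]] <- ev$D
    stateM[[child]] <- ev$M
    mults[k, ] <- ev$mults
  }

  orgs <- tree$tip.label
  seq_of <- function(state, tips = seq_len(n_tip)) {
    vapply(tips, function(i) paste(state[[i]], collapse = ""), character(1))
  }
  ids_a <- paste0(orgs, "_A1")
  ids_b <- paste0(orgs, "_B1")
  ids_d <- paste0(orgs, "_D1")
  recs_a <- tibble(seq_id = ids_a, organism_id = orgs,
                   residues = seq_of(stateA))
  recs_b <- tibble(seq_id = ids_b, organism_id = orgs,
                   residues = seq_of(stateB))

  duplications <- tibble(organism_id = character(), family = character())
  if (isTRUE(cfg$duplicate_first_organism)) {
    # second copies of both families branch at the first tip's ancestral
    # node and evolve jointly (same compensatory process) along the
    # terminal branch
    org1 <- orgs[1L]
    k1 <- which(edge[, 2L] == 1L)
    parent1 <- edge[k1, 1L]
    ab <- evolve_AB(stateA[[parent1]], stateB[[parent1]], elen[k1])
    recs_a <- bind_rows(recs_a, tibble(
      seq_id = paste0(org1, "_A2"), organism_id = org1,
      residues = paste(ab$A, collapse = "")))
    recs_b <- bind_rows(recs_b, tibble(
      seq_id = paste0(org1, "_B2"), organism_id = org1,
      residues = paste(ab$B, collapse = "")))
    duplications <- tibble(organism_id = org1, family = c("A", "B"))
  }

  famA <- aligned_family(recs_a$seq_id, recs_a$organism_id, recs_a$residues,
                         family_name = "famA")
  famB <- aligned_family(recs_b$seq_id, recs_b$organism_id, recs_b$residues,
                         family_name = "famB")
  decoy <- aligned_family(ids_d, orgs, seq_of(stateD), family_name = "decoy")
  marker <- aligned_family(orgs, orgs, seq_of(stateM),
                           family_name = "marker", alphabet = "DNA")

  pairing <- bind_rows(lapply(orgs, function(o) {
    ma <- famA$seq_ids[famA$organisms == o]
    mb <- famB$seq_ids[famB$organisms == o]
    tidyr::expand_grid(organism_id = o, member_a = ma, member_b = mb)
  }))

  # fixture clades: the two root subtrees when both hold >= 2 organisms
  # (the dicot/monocot-style contrast); otherwise the most balanced
  # bipartition of the tree, so both clades stay usable for contrasts
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  left_tips <- tree$tip.label[tips_under(tree, kids[1L], n_tip)]
  if (length(left_tips) < 2L || n_tip - length(left_tips) < 2L) {
    internal <- setdiff(unique(tree$edge[, 1L]), root)
    sizes <- vapply(internal, function(v) length(tips_under(tree, v, n_tip)),
                    integer(1))
    best <- internal[which.min(abs(sizes - n_tip / 2))]
    left_tips <- tree$tip.label[tips_under(tree, best, n_tip)]
  }
  clades <- tibble(
    organism_id = orgs,
    clade = ifelse(orgs %in% left_tips, "clade1", "clade2")
  )

  truth <- list(
    coupled_pairs = cfg$coupled_pairs,
    compensation_prob = cfg$compensation_prob,
    branch_rates = as_tibble(cbind(
      tibble(parent = edge[, 1L], child = edge[, 2L], length = elen),
      as.data.frame(mults))),
    duplications = duplications,
    config = cfg
  )
  structure(
    list(famA = famA, famB = famB, decoy = decoy, marker = marker,
         tree = tree, pairing = pairing, clades = clades, truth = truth),
    class = "coevo_sim"
  )
}

# tip indices descending from `node` (tips included)
tips_under <- function(tree, node, n_tip) {
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' @export
print.coevo_sim <- function(x, ...) {
  cat(sprintf(
    "<coevo_sim> %d organisms; famA %d cols, famB %d cols, %d coupled pairs\n",
    length(x$tree$tip.label), x$famA$n_cols, x$famB$n_cols,
    nrow(x$truth$coupled_pairs)))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits aligned FASTAs for the two families, the decoy and the marker,
#' the species tree as newick, the pairing and clade TSVs, and a truth
#' JSON (coupled pairs, duplications, compensation probability). All files
#' are plain text and re-readable with the package readers; two runs from
#' the same simulation object are byte-identical.
#'
#' @param sim A `coevo_sim`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    famA = file.path(outdir, "famA.fasta"),
    famB = file.path(outdir, "famB.fasta"),
    decoy = file.path(outdir, "decoy.fasta"),
    marker = file.path(outdir, "marker.fasta"),
    tree = file.path(outdir, "tree.nwk"),
    pairing = file.path(outdir, "pairing.tsv"),
    clades = file.path(outdir, "clades.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_alignment(sim$famA, paths[["famA"]])
  write_alignment(sim$famB, paths[["famB"]])
  write_alignment(sim$decoy, paths[["decoy"]])
  write_alignment(sim$marker, paths[["marker"]])
  ape::write.tree(sim$tree, file = paths[["tree"]])
  readr::write_tsv(sim$pairing, paths[["pairing"]], progress = FALSE)
  readr::write_tsv(sim$clades, paths[["clades"]], progress = FALSE)
  jsonlite::write_json(
    list(
      coupled_pairs = sim$truth$coupled_pairs,
      compensation_prob = sim$truth$compensation_prob,
      duplications = sim$truth$duplications
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Simulate neutral codon-aligned pairs
#'
#' Generates independently diverged coding-sequence pairs under a neutral
#' nucleotide process (transition:transversion rate ratio `kappa`) in
#' which every non-stop change is accepted — the omega = 1 reference case
#' used to calibrate the dN/dS estimator.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence.
#' @param divergence Expected substitutions per nucleotide site separating
#'   the two sequences of a pair.
#' @param kappa Transition/transversion rate ratio of the mutation
#'   process.
#' @param seed Optional integer seed.
#' @return A tibble with `pair`, `seq_a`, `seq_b`.
#' @export
simulate_neutral_codon_pairs <- function(n_pairs = 20, n_codons = 300,
                                         divergence = 0.3, kappa = 2,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dna <- c("A", "C", "G", "T")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  mutate_neutral <- function(seq, n_ev) {
    L <- length(seq)
    done <- 0L
    while (done < n_ev) {
      s <- sample.int(L, 1L)
      cur <- seq[s]
      new <- if (runif(1L) < kappa / (kappa + 2)) {
        ts_of[[cur]]
      } else {
        tv <- setdiff(dna, c(cur, ts_of[[cur]]))
        tv[sample.int(2L, 1L)]
      }
      ci <- (s - 1L) %/% 3L
      cod <- seq[(3L * ci + 1L):(3L * ci + 3L)]
      cod[(s - 1L) %% 3L + 1L] <- new
      if (paste(cod, collapse = "") %in% STOP_CODONS) next
      seq[s] <- new
      done <- done + 1L
    }
    seq
  }
  rows <- lapply(seq_len(n_pairs), function(p) {
    anc <- unlist(strsplit(sample(sense, n_codons, replace = TRUE), ""))
    L <- length(anc)
    a <- mutate_neutral(anc, rpois(1L, divergence / 2 * L))
    b <- mutate_neutral(anc, rpois(1L, divergence / 2 * L))
    tibble(pair = p, seq_a = paste(a, collapse = ""),
           seq_b = paste(b, collapse = ""))
  })
  bind_rows(rows)
}
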