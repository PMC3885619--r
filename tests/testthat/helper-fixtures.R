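# Small in-code fixtures shared across tests.

toy_family <- function() {
  aligned_family(
    seq_ids = c("s1", "s2", "s3", "s4"),
    organisms = c("o1", "o2", "o3", "o4"),
    residues = c("MKAAWVLDER", "MKASWVLDER", "MRASWVIDER", "MRTSWVIDEK"),
    family_name = "toy"
  )
}

write_toy_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

rand_dist_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

small_sim <- function(seed, n_org = 15, len = 100, ...) {
  tr <- simulate_tree(n_org, seed = seed)
  cfg <- sim_config(n_organisms = n_org, len_a = len, len_b = len, ...)
  simulate_families(tr, cfg, seed = seed + 10000L)
}

decoy_pairing <- function(sim) {
  dplyr::distinct(dplyr::mutate(sim$pairing,
                                member_b = paste0(organism_id, "_D1")))
}

# brute-force minimum-change oracle: try every internal labeling
brute_min_changes <- function(tree, tips) {
  n_tip <- length(tree$tip.label)
  st <- tips[tree$tip.label]
  n_int <- tree$Nnode
  best <- Inf
  for (code in 0:(2^n_int - 1)) {
    internal <- as.integer(intToBits(code))[seq_len(n_int)]
    full <- c(st, internal)
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# brute-force Mk2 marginals by enumerating internal assignments
brute_mk2 <- function(tree, tips, rate) {
  n_tip <- length(tree$tip.label)
  st <- tips[tree$tip.label]
  n_int <- tree$Nnode
  pm <- function(t) {
    e <- exp(-2 * rate * t)
    matrix(c(0.5 + 0.5 * e, 0.5 - 0.5 * e,
             0.5 - 0.5 * e, 0.5 + 0.5 * e), 2, 2)
  }
  tot <- 0
  marg1 <- numeric(n_int)
  for (code in 0:(2^n_int - 1)) {
    internal <- as.integer(intToBits(code))[seq_len(n_int)]
    full <- c(st, internal)
    lik <- 0.5
    for (k in seq_len(nrow(tree$edge))) {
      lik <- lik * pm(tree$edge.length[k])[
        full[tree$edge[k, 1]] + 1, full[tree$edge[k, 2]] + 1]
    }
    tot <- tot + lik
    marg1 <- marg1 + internal * lik
  }
  list(loglik = log(tot), p1 = marg1 / tot)
}

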