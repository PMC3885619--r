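#' @noRd
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

NUCS <- c("A", "C", "G", "T")

# Per-codon synonymous site count under modified Nei-Gojobori weighting:
# at each position the one transition gets weight kappa and each of the two
# transversions weight 1; a position contributes the weighted fraction of
# its viable (non-stop) changes that are synonymous. Changes to stop codons
# are excluded from numerator and denominator, matching the convention of
# codon-counting software that disallows nonsense changes. Each position
# still contributes one site, so a codon holds 3.
syn_sites_codon <- function(codon, code, kappa) {
  aa <- code[[codon]]
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    w_syn <- 0
    w_tot <- 0
    for (nt in setdiff(NUCS, chars[pos])) {
      alt <- chars
      alt[pos] <- nt
      alt_codon <- paste(alt, collapse = "")
      if (alt_codon %in% STOP_CODONS) next
      w <- if (is_transition(chars[pos], nt)) kappa else 1
      w_tot <- w_tot + w
      if (code[[alt_codon]] == aa) w_syn <- w_syn + w
    }
    if (w_tot > 0) s <- s + w_syn / w_tot
  }
  s
}

# Differences between two codons averaged with equal weight over the
# shortest substitution pathways (orderings of the differing positions).
# Pathways passing through a stop codon are dropped; if every pathway does,
# all are kept so the pair still contributes. Returns transitional /
# transversional synonymous and nonsynonymous difference counts.
codon_path_diffs <- function(ca, cb, code) {
  a <- strsplit(ca, "")[[1L]]
  b <- strsplit(cb, "")[[1L]]
  pos <- which(a != b)
  k <- length(pos)
  zero <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  if (k == 0L) return(zero)
  perms <- if (k == 1L) list(pos) else {
    idx <- permutations_of(k)
    lapply(idx, function(o) pos[o])
  }
  acc <- NULL
  acc_all <- zero
  n_valid <- 0L
  n_all <- 0L
  for (order_ in perms) {
    cur <- a
    counts <- zero
    valid <- TRUE
    for (p in order_) {
      nxt <- cur
      nxt[p] <- b[p]
      c_from <- paste(cur, collapse = "")
      c_to <- paste(nxt, collapse = "")
      if (c_to %in% STOP_CODONS || c_from %in% STOP_CODONS) valid <- FALSE
      ts <- is_transition(cur[p], b[p])
      syn <- !(c_to %in% STOP_CODONS) && !(c_from %in% STOP_CODONS) &&
        code[[c_from]] == code[[c_to]]
      key <- paste0(if (syn) "sd" else "nd", if (ts) "_ts" else "_tv")
      counts[key] <- counts[key] + 1
      cur <- nxt
    }
    n_all <- n_all + 1L
    acc_all <- acc_all + counts
    if (valid) {
      n_valid <- n_valid + 1L
      acc <- if (is.null(acc)) counts else acc + counts
    }
  }
  if (n_valid > 0L) acc / n_valid else acc_all / n_all
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- permutations_of(k - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, ifelse(r >= i, r + 1L, r))
  }
  out
}

#' dN and dS for one codon-aligned pair
#'
#' Modified Nei-Gojobori counting with a transition/transversion weighted
#' site definition (`kappa` = transition:transversion rate ratio;
#' `kappa = 1` recovers unweighted Nei-Gojobori sites), multiple pathways
#' between differing codons averaged with equal weight, and a Kimura-2P
#' style correction applied separately to the synonymous and nonsynonymous
#' difference proportions using their transitional/transversional split.
#'
#' @param a,b Gapped codon-aligned nucleotide strings (or character
#'   vectors) of equal length; codons with a gap or ambiguity in either
#'   sequence are skipped (pairwise deletion).
#' @param kappa Transition/transversion rate ratio used to weight site
#'   counts (default 2).
#' @return A one-row tibble with `dN`, `dS`, `omega`, the uncorrected
#'   proportions `pN` and `pS`, site totals `N` and `S`, difference counts
#'   `Nd` and `Sd`, and logical flags `dS_saturated`, `dN_saturated`,
#'   `omega_defined`.
#' @export
dnds_pair <- function(a, b, kappa = 2) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) {
    abort("sequences must be aligned to equal length", class = "coevo_input_error")
  }
  if (length(a) %% 3L != 0L) {
    abort("length not a multiple of 3", class = "coevo_codon_error")
  }
  code <- genetic_code()
  n_cod <- length(a) %/% 3L
  S <- 0; N <- 0
  diffs <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  used <- 0L
  for (ci in seq_len(n_cod)) {
    ix <- (3L * (ci - 1L) + 1L):(3L * ci)
    ca <- paste(a[ix], collapse = "")
    cb <- paste(b[ix], collapse = "")
    if (!all(c(a[ix], b[ix]) %in% NUCS)) next
    if (ca %in% STOP_CODONS || cb %in% STOP_CODONS) next
    used <- used + 1L
    S <- S + (syn_sites_codon(ca, code, kappa) +
                syn_sites_codon(cb, code, kappa)) / 2
    diffs <- diffs + codon_path_diffs(ca, cb, code)
  }
  if (used == 0L) abort("no comparable codons", class = "coevo_input_error")
  N <- 3 * used - S
  Sd <- diffs[["sd_ts"]] + diffs[["sd_tv"]]
  Nd <- diffs[["nd_ts"]] + diffs[["nd_tv"]]
  pS <- Sd / S
  pN <- Nd / N
  correct <- function(d_ts, d_tv, sites) {
    tryCatch(kimura2p(d_ts / sites, d_tv / sites),
             coevo_saturation_error = function(e) NA_real_)
  }
  dS <- if (S > 0) correct(diffs[["sd_ts"]], diffs[["sd_tv"]], S) else NA_real_
  dN <- if (N > 0) correct(diffs[["nd_ts"]], diffs[["nd_tv"]], N) else NA_real_
  omega_defined <- !is.na(dN) && !is.na(dS) && dS > 0
  tibble(
    dN = dN, dS = dS,
    omega = if (omega_defined) dN / dS else NA_real_,
    pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd,
    dN_saturated = is.na(dN), dS_saturated = is.na(dS),
    omega_defined = omega_defined
  )
}

#' Per-pair and family-level dN/dS summary
#'
#' Applies [dnds_pair()] to all unordered sequence pairs of a codon family
#' and summarises family means. Pairs with undefined omega (dS = 0 or
#' saturated) are excluded from the omega mean and counted.
#'
#' @param fam A [codon_family].
#' @inheritParams dnds_pair
#' @return An object of class `rate_summary`: a list with `pairs` (tibble of
#'   per-pair values with `id_a`, `id_b`) and `family` (one-row tibble of
#'   means and counts).
#' @export
dnds_family <- function(fam, kappa = 2) {
  n <- n_sequences(fam)
  if (n < 2L) abort("need >= 2 sequences", class = "coevo_input_error")
  pr <- combn(n, 2L)
  rows <- lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1L, k]; j <- pr[2L, k]
    res <- dnds_pair(fam$mat[i, ], fam$mat[j, ], kappa = kappa)
    mutate(res, id_a = fam$seq_ids[i], id_b = fam$seq_ids[j], .before = 1L)
  })
  pairs <- bind_rows(rows)
  fam_row <- tibble(
    family_name = fam$family_name,
    mean_dN = mean(pairs$dN, na.rm = TRUE),
    mean_dS = mean(pairs$dS, na.rm = TRUE),
    mean_omega = mean(pairs$omega[pairs$omega_defined]),
    n_pairs = nrow(pairs),
    n_omega_undefined = sum(!pairs$omega_defined)
  )
  structure(list(pairs = pairs, family = fam_row), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("<rate_summary>\n")
  print(x$family)
  invisible(x)
}

#' @export
tidy.rate_summary <- function(x, ...) x$pairs

#' @export
glance.rate_summary <- function(x, ...) x$family
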