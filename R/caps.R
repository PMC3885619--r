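#' Load a substitution scoring matrix by name
#'
#' @param name Matrix name available in Biostrings (default "BLOSUM62").
#' @return A numeric scoring matrix.
#' @export
get_subst_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    abort(paste0("unknown substitution matrix: ", name),
          class = "coevo_input_error")
  }
  get(name, envir = e)
}

#' Per-site normalized transition-score profiles
#'
#' For every usable alignment column, computes over a list of sequence
#' pairs k = (i, j) the normalized substitution score
#' theta_k = B(a_i, a_j) / t_ij, where B is the substitution-matrix score
#' of the residues the two sequences carry at the column and t_ij is the
#' Poisson-corrected p-distance between the sequences. Dividing by
#' divergence time discounts pairs that have had longer to accumulate
#' chance double substitutions. Columns constant across all sequences
#' carry no variance and are excluded, as are columns with more than
#' `max_gap_frac` gaps; entries where either sequence has a gap at the
#' column are NA. Pairs of non-identical sequences with t_ij = 0 cannot be
#' normalized and are dropped with a warning (as are fully identical
#' pairs).
#'
#' @param fam An [aligned_family] (protein).
#' @param pairs Two-column matrix or data frame of sequence ids (one row
#'   per sequence pair, order meaningful: row k here must correspond to
#'   row k of the partner family's profile).
#' @param subst_matrix Scoring matrix (default BLOSUM62) or its name.
#' @param max_gap_frac Columns with a larger gap fraction are excluded.
#' @param min_divergence Sequence pairs closer than this Poisson-corrected
#'   distance are dropped: the 1/t normalization diverges as t -> 0, and a
#'   single near-identical pair (e.g. young paralogs) would otherwise
#'   dominate every site's profile.
#' @return An object of class `site_profiles`: list with `theta` (pairs x
#'   sites matrix, NA = unusable), `sites` (alignment columns kept),
#'   `pair_ids` (tibble id_a/id_b), `dropped_pairs`, `family_name`.
#' @export
site_profiles <- function(fam, pairs, subst_matrix = "BLOSUM62",
                          max_gap_frac = 0.5, min_divergence = 0.05) {
  if (is.character(subst_matrix) && length(subst_matrix) == 1L) {
    subst_matrix <- get_subst_matrix(subst_matrix)
  }
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("id_a", "id_b")
  ia <- match(pairs$id_a, fam$seq_ids)
  ib <- match(pairs$id_b, fam$seq_ids)
  if (anyNA(ia) || anyNA(ib)) {
    abort("pair ids missing from alignment", class = "coevo_crossref_error")
  }
  pdist <- poisson_correct_matrix(p_distance(fam))
  t_ij <- pdist[cbind(ia, ib)]
  drop <- is.na(t_ij) | t_ij < min_divergence
  if (any(drop)) {
    warn(sprintf(
      "%d sequence pair(s) dropped (divergence below %g or saturated)",
      sum(drop), min_divergence))
  }
  keep_pairs <- which(!drop)
  mat <- fam$mat
  gapmask <- is_missing_char(mat, fam$alphabet)
  gap_frac <- colMeans(gapmask)
  constant <- vapply(seq_len(ncol(mat)), function(c) {
    res <- mat[!gapmask[, c], c]
    length(unique(res)) <= 1L
  }, logical(1))
  sites <- which(gap_frac <= max_gap_frac & !constant)
  theta <- matrix(NA_real_, nrow = length(keep_pairs), ncol = length(sites))
  for (s in seq_along(sites)) {
    col <- mat[, sites[s]]
    usable <- !gapmask[, sites[s]]
    a <- col[ia[keep_pairs]]
    b <- col[ib[keep_pairs]]
    ok <- usable[ia[keep_pairs]] & usable[ib[keep_pairs]] &
      a %in% rownames(subst_matrix) & b %in% colnames(subst_matrix)
    theta[ok, s] <- subst_matrix[cbind(a[ok], b[ok])] / t_ij[keep_pairs][ok]
  }
  colnames(theta) <- sites
  structure(
    list(theta = theta, sites = sites,
         pair_ids = tibble(id_a = pairs$id_a[keep_pairs],
                           id_b = pairs$id_b[keep_pairs]),
         kept_pair_rows = keep_pairs,
         dropped_pairs = which(drop),
         family_name = fam$family_name),
    class = "site_profiles"
  )
}

#' @export
print.site_profiles <- function(x, ...) {
  cat(sprintf("<site_profiles '%s'> %d sites x %d sequence pairs\n",
              x$family_name, length(x$sites), nrow(x$theta)))
  invisible(x)
}

#' Per-site variability of a profile
#'
#' Variance of the normalized transition scores of each site (the site's
#' Dc contribution).
#'
#' @param prof A `site_profiles`.
#' @return Named numeric vector over sites (names = alignment columns).
#' @export
site_variability <- function(prof) {
  v <- apply(prof$theta, 2L, var, na.rm = TRUE)
  setNames(v, colnames(prof$theta))
}

align_profiles <- function(profA, profB) {
  shared <- intersect(profA$kept_pair_rows, profB$kept_pair_rows)
  list(
    A = profA$theta[match(shared, profA$kept_pair_rows), , drop = FALSE],
    B = profB$theta[match(shared, profB$kept_pair_rows), , drop = FALSE]
  )
}

#' Intermolecular site-pair correlations
#'
#' Pearson correlation between the transition-score profiles of every
#' family-A site against every family-B site, over the sequence pairs
#' shared by both profiles (pairs correspond through the organism pairing:
#' row k of profile A and row k of profile B come from the same pairing
#' rows). Site pairs with fewer than `min_shared` jointly usable entries
#' are skipped.
#'
#' @param profA,profB `site_profiles` built over the same ordered pair
#'   list.
#' @param min_shared Minimum jointly usable sequence pairs (default 3).
#' @return A tibble with `site_a`, `site_b` (alignment columns), `rho`,
#'   `n_shared`.
#' @export
intermolecular_correlations <- function(profA, profB, min_shared = 3L) {
  al <- align_profiles(profA, profB)
  TA <- al$A; TB <- al$B
  if (nrow(TA) < min_shared) {
    abort("fewer shared sequence pairs than min_shared",
          class = "coevo_input_error")
  }
  suppressWarnings(
    rho <- cor(TA, TB, use = "pairwise.complete.obs")
  )
  n_shared <- crossprod((!is.na(TA)) * 1, (!is.na(TB)) * 1)
  grid <- tidyr::expand_grid(
    ai = seq_along(profA$sites), bi = seq_along(profB$sites)
  )
  out <- tibble(
    site_a = profA$sites[grid$ai],
    site_b = profB$sites[grid$bi],
    rho = rho[cbind(grid$ai, grid$bi)],
    n_shared = as.integer(n_shared[cbind(grid$ai, grid$bi)])
  )
  filter(out, .data$n_shared >= min_shared, !is.na(.data$rho))
}

#' Significance threshold for site-pair correlations by resampling
#'
#' Builds a null distribution of rho by repeatedly pairing the theta
#' vector of a randomly drawn family-A site with that of a randomly drawn
#' family-B site (one family's site labels shuffled; the sequence-pair
#' alignment stays intact). Because every site's profile shares the
#' divergence-time normalization, unrelated columns already correlate
#' substantially; the null captures that baseline, and a pair is called
#' significant when its rho exceeds the (1 - alpha) null quantile.
#'
#' @param cors Tibble from [intermolecular_correlations()].
#' @param profA,profB The profiles the correlations came from.
#' @param alpha Significance level (default 0.05).
#' @param n_resample Null draws (>= 100; default 1000).
#' @param seed Optional integer seed.
#' @return `cors` with a logical `significant` column; the null threshold
#'   and draws are attached as attributes `threshold` and `null_rho`.
#' @export
significance_filter <- function(cors, profA, profB, alpha = 0.05,
                                n_resample = 1000L, seed = NULL) {
  if (n_resample < 100L) {
    abort("n_resample must be >= 100", class = "coevo_input_error")
  }
  if (nrow(cors) == 0L) {
    abort("no correlated pairs supplied", class = "coevo_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  al <- align_profiles(profA, profB)
  TA <- al$A; TB <- al$B
  null_rho <- rep(NA_real_, n_resample)
  sa <- sample.int(ncol(TA), n_resample, replace = TRUE)
  sb <- sample.int(ncol(TB), n_resample, replace = TRUE)
  for (r in seq_len(n_resample)) {
    suppressWarnings(
      null_rho[r] <- cor(TA[, sa[r]], TB[, sb[r]],
                         use = "pairwise.complete.obs")
    )
  }
  null_rho <- null_rho[!is.na(null_rho)]
  threshold <- quantile(null_rho, 1 - alpha, names = FALSE, type = 8)
  out <- mutate(cors, significant = .data$rho > threshold)
  attr(out, "threshold") <- threshold
  attr(out, "null_rho") <- null_rho
  attr(out, "alpha") <- alpha
  out
}

#' Group significant site pairs by connectivity
#'
#' Connected components of the bipartite graph whose nodes are family-A
#' and family-B sites and whose edges are the significant pairs. Groups
#' are numbered G1..Gn ordered by their smallest family-A site (then
#' smallest family-B site) so output is diff-stable. When profiles are
#' supplied each group also reports mean_Dc, the mean per-site variance of
#' the member sites' transition scores.
#'
#' @param sig_pairs Tibble of significant pairs (`site_a`, `site_b`,
#'   `rho`).
#' @param profA,profB Optional `site_profiles` for mean_Dc.
#' @return A tibble with `group_id`, `sites_a` and `sites_b` (list
#'   columns of alignment columns), `n_pairs`, `mean_rho`, `mean_Dc`.
#' @export
build_groups <- function(sig_pairs, profA = NULL, profB = NULL) {
  if (nrow(sig_pairs) == 0L) {
    return(tibble(group_id = character(), sites_a = list(),
                  sites_b = list(), n_pairs = integer(),
                  mean_rho = numeric(), mean_Dc = numeric()))
  }
  va <- paste0("A:", sig_pairs$site_a)
  vb <- paste0("B:", sig_pairs$site_b)
  g <- igraph::graph_from_edgelist(cbind(va, vb), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  groups <- lapply(seq_len(comp$no), function(k) {
    verts <- names(memb)[memb == k]
    sa <- sort(as.integer(sub("^A:", "", verts[startsWith(verts, "A:")])))
    sb <- sort(as.integer(sub("^B:", "", verts[startsWith(verts, "B:")])))
    in_grp <- sig_pairs$site_a %in% sa & sig_pairs$site_b %in% sb
    dc <- NA_real_
    if (!is.null(profA) && !is.null(profB)) {
      va_var <- site_variability(profA)[as.character(sa)]
      vb_var <- site_variability(profB)[as.character(sb)]
      dc <- mean(c(va_var, vb_var), na.rm = TRUE)
    }
    tibble(sites_a = list(sa), sites_b = list(sb),
           n_pairs = sum(in_grp),
           mean_rho = mean(sig_pairs$rho[in_grp]),
           mean_Dc = dc,
           min_a = if (length(sa)) min(sa) else Inf,
           min_b = if (length(sb)) min(sb) else Inf)
  })
  out <- bind_rows(groups)
  out <- arrange(out, .data$min_a, .data$min_b)
  out <- mutate(out, group_id = paste0("G", dplyr::row_number()), .before = 1L)
  select(out, -"min_a", -"min_b")
}

#' Full correlated-mutation scan between two families
#'
#' Builds the matched sequence-pair list from all unordered pairs of
#' pairing rows, computes transition-score profiles for both families,
#' correlates every inter-family site pair, thresholds significance by
#' resampling, and groups significant pairs by connectivity.
#'
#' @param famA,famB [aligned_family] protein alignments.
#' @param pairing Pairing tibble ([read_pairing()]).
#' @inheritParams site_profiles
#' @inheritParams significance_filter
#' @return An object of class `caps_result`: list with `correlations`
#'   (all scored pairs with `significant`), `groups`, `profiles` (list of
#'   the two `site_profiles`), `threshold`, `alpha`.
#' @export
caps_scan <- function(famA, famB, pairing, subst_matrix = "BLOSUM62",
                      alpha = 0.05, n_resample = 1000L, seed = NULL,
                      max_gap_frac = 0.5, min_divergence = 0.05) {
  if (is.character(subst_matrix) && length(subst_matrix) == 1L) {
    subst_matrix <- get_subst_matrix(subst_matrix)
  }
  rows <- combn(nrow(pairing), 2L)
  pairs_a <- tibble(id_a = pairing$member_a[rows[1L, ]],
                    id_b = pairing$member_a[rows[2L, ]])
  pairs_b <- tibble(id_a = pairing$member_b[rows[1L, ]],
                    id_b = pairing$member_b[rows[2L, ]])
  profA <- site_profiles(famA, pairs_a, subst_matrix = subst_matrix,
                         max_gap_frac = max_gap_frac,
                         min_divergence = min_divergence)
  profB <- site_profiles(famB, pairs_b, subst_matrix = subst_matrix,
                         max_gap_frac = max_gap_frac,
                         min_divergence = min_divergence)
  cors <- intermolecular_correlations(profA, profB)
  cors <- significance_filter(cors, profA, profB, alpha = alpha,
                              n_resample = n_resample, seed = seed)
  sig <- filter(cors, .data$significant)
  groups <- build_groups(sig, profA, profB)
  structure(
    list(correlations = cors, significant = sig, groups = groups,
         profiles = list(A = profA, B = profB),
         threshold = attr(cors, "threshold"), alpha = alpha),
    class = "caps_result"
  )
}

#' @export
print.caps_result <- function(x, ...) {
  cat(sprintf(
    "<caps_result> %d site pairs scored, %d significant (rho > %.3f), %d groups\n",
    nrow(x$correlations), nrow(x$significant), x$threshold, nrow(x$groups)))
  invisible(x)
}

#' @export
tidy.caps_result <- function(x, ...) as_tibble(x$correlations)

#' @export
glance.caps_result <- function(x, ...) {
  tibble(
    n_pairs_scored = nrow(x$correlations),
    n_significant = nrow(x$significant),
    n_groups = nrow(x$groups),
    n_residues_a = length(unique(x$significant$site_a)),
    n_residues_b = length(unique(x$significant$site_b)),
    threshold = x$threshold,
    alpha = x$alpha
  )
}

#' Plot the site-pair correlation landscape
#'
#' @param object A `caps_result`.
#' @param ... Unused.
#' @return A ggplot tile map of rho over family-A x family-B sites with
#'   significant pairs outlined.
#' @export
autoplot.caps_result <- function(object, ...) {
  df <- object$correlations
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_a, y = .data$site_b)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$rho)) +
    ggplot2::geom_point(data = filter(df, .data$significant),
                        shape = 0, size = 1, colour = "black") +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "family A site", y = "family B site",
                  fill = expression(rho))
}
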