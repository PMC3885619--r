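#' Pairwise p-distance of an alignment
#'
#' Fraction of differing residues over the columns comparable in both
#' sequences (non-gap, non-missing). Under pairwise deletion each pair uses
#' its own comparable columns; under complete deletion only columns with no
#' gap/missing symbol in any sequence are used for every pair. Pairs with
#' zero comparable columns get `NA` (flagged, never 0).
#'
#' @param fam An [aligned_family] with at least two sequences.
#' @param mode `"pairwise"` (default) or `"complete"` deletion.
#' @return A symmetric distance matrix (class `dist_matrix`) with a zero
#'   diagonal, sequence ids as dimnames, and attributes `method` and
#'   `deletion`.
#' @export
p_distance <- function(fam, mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  if (n_sequences(fam) < 2L) {
    abort("need at least two sequences", class = "coevo_input_error")
  }
  mat <- fam$mat
  usable <- !is_missing_char(mat, fam$alphabet)
  if (mode == "complete") {
    keep <- colSums(usable) == nrow(mat)
    mat <- mat[, keep, drop = FALSE]
    usable <- usable[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(fam$seq_ids, fam$seq_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- usable[i, ] & usable[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <-
        if (nc == 0L) NA_real_ else sum(mat[i, comp] != mat[j, comp]) / nc
    }
  }
  new_dist_matrix(d, method = "p-distance", deletion = mode)
}

new_dist_matrix <- function(m, method, deletion = "pairwise") {
  structure(m, method = method, deletion = deletion,
            class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d x %d, method = %s, deletion = %s\n",
              nrow(x), ncol(x), attr(x, "method"), attr(x, "deletion")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Long-format view of a distance matrix
#'
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `id_a`, `id_b`, `distance` over unordered
#'   pairs.
#' @export
tidy.dist_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
         distance = x[idx])
}

#' Poisson correction of a proportion of differing sites
#'
#' Corrects an observed proportion p of differing amino acids for multiple
#' hits under a Poisson model: d = -ln(1 - p).
#'
#' @param p Numeric vector of proportions in `[0, 1)`; `NA` passes through.
#' @return Corrected distances.
#' @export
poisson_correct <- function(p) {
  bad <- !is.na(p) & (p < 0 | p >= 1)
  if (any(bad)) {
    abort("p must be in [0, 1); p >= 1 is saturated",
          class = "coevo_saturation_error")
  }
  -log1p(-p)
}

#' Poisson-corrected distance matrix
#'
#' @param d A `dist_matrix` of p-distances.
#' @return A `dist_matrix` of Poisson-corrected distances; saturated cells
#'   (p >= 1) become `NA`.
#' @export
poisson_correct_matrix <- function(d) {
  out <- unclass(d)
  sat <- !is.na(out) & out >= 1
  out[sat] <- NA_real_
  out[!sat] <- -log1p(-out[!sat])
  new_dist_matrix(out, method = "poisson", deletion = attr(d, "deletion"))
}

#' Mean pairwise percent identity
#'
#' Mean over all unordered sequence pairs of the percentage of identical
#' residues among columns comparable in both sequences.
#'
#' @param fam An [aligned_family].
#' @return A single percentage in `[0, 100]`.
#' @export
mean_pairwise_identity <- function(fam) {
  d <- p_distance(fam, mode = "pairwise")
  p <- d[upper.tri(d)]
  mean(1 - p, na.rm = TRUE) * 100
}

#' Kimura two-parameter distance
#'
#' `kimura2p()` evaluates the closed form
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q) from transition (P) and
#' transversion (Q) proportions. `kimura2p_pair()` computes P and Q from an
#' aligned nucleotide pair (pairwise deletion) first.
#'
#' @param P Transition proportion(s).
#' @param Q Transversion proportion(s).
#' @return Distance(s); an error of class `coevo_saturation_error` if a log
#'   argument is non-positive.
#' @export
kimura2p <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (any(!is.na(a1) & a1 <= 0) || any(!is.na(a2) & a2 <= 0)) {
    abort("Kimura-2P distance saturated (log argument <= 0)",
          class = "coevo_saturation_error")
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

#' @rdname kimura2p
#' @param a,b Equal-length character vectors of nucleotides (or strings).
#' @export
kimura2p_pair <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1L]]
  a <- toupper(a); b <- toupper(b)
  comp <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (sum(comp) == 0L) {
    abort("no comparable sites", class = "coevo_input_error")
  }
  a <- a[comp]; b <- b[comp]
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / length(a)
  Q <- sum(diff & !is_transition(a, b)) / length(a)
  kimura2p(P, Q)
}

#' Kimura-2P distance matrix for a nucleotide alignment
#'
#' @param fam An [aligned_family] with DNA alphabet.
#' @return A `dist_matrix`; saturated pairs become `NA`.
#' @export
kimura2p_matrix <- function(fam) {
  n <- n_sequences(fam)
  d <- matrix(0, n, n, dimnames = list(fam$seq_ids, fam$seq_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tryCatch(
        kimura2p_pair(fam$mat[i, ], fam$mat[j, ]),
        coevo_saturation_error = function(e) NA_real_
      )
    }
  }
  new_dist_matrix(d, method = "kimura2p")
}

#' Two-sample Z comparison of means
#'
#' Z statistic on the difference of sample means with standard error
#' pooled from the two sample variances; two-sided p from the normal tail.
#' Used to compare per-pair rate values (e.g. dN or omega) between two
#' families; because pairwise values are not independent the p-value is an
#' approximation.
#'
#' @param sample_a,sample_b Numeric vectors (each length >= 2).
#' @return A tibble with `z`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
z_compare <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("each sample needs >= 2 values", class = "coevo_input_error")
  }
  se2 <- var(sample_a) / length(sample_a) + var(sample_b) / length(sample_b)
  dm <- mean(sample_a) - mean(sample_b)
  z <- if (se2 == 0) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else {
    dm / sqrt(se2)
  }
  tibble(z = z, p_value = 2 * pnorm(-abs(z)),
         mean_a = mean(sample_a), mean_b = mean(sample_b),
         n_a = length(sample_a), n_b = length(sample_b))
}
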