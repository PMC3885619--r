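#' Build index-aligned paired distance matrices for two families
#'
#' Expands two family distance matrices over the rows of a pairing table so
#' that cell (i, j) of X holds the distance between the family-A members of
#' pairing rows i and j, and Y likewise for family B. An organism carrying
#' m A-paralogs and n B-paralogs contributes m*n pairing rows, so a family
#' member can appear more than once — the paralog-expanded construction
#' used when correlating the evolutionary histories of two interacting
#' families. An optional neutral-marker matrix keyed by organism ids is
#' expanded the same way (same-organism cells are 0).
#'
#' @param distA,distB `dist_matrix` objects whose dimnames cover the
#'   pairing members.
#' @param pairing Pairing tibble from [read_pairing()].
#' @param marker Optional `dist_matrix` keyed by organism ids.
#' @return An object of class `paired_matrices`: list with `pair_index`
#'   (the pairing tibble), `X`, `Y` and optionally `S`.
#' @export
build_paired_matrices <- function(distA, distB, pairing, marker = NULL) {
  ia <- match(pairing$member_a, rownames(distA))
  ib <- match(pairing$member_b, rownames(distB))
  if (anyNA(ia) || anyNA(ib)) {
    abort("pairing member missing from a distance matrix",
          class = "coevo_crossref_error")
  }
  X <- unclass(distA)[ia, ia, drop = FALSE]
  Y <- unclass(distB)[ib, ib, drop = FALSE]
  labs <- paste(pairing$organism_id, pairing$member_a, pairing$member_b,
                sep = "|")
  dimnames(X) <- dimnames(Y) <- list(labs, labs)
  # rows for the same family member meet themselves off-diagonal at
  # distance zero; keep (construction mirrors the pairing expansion)
  out <- list(pair_index = pairing, X = X, Y = Y)
  if (!is.null(marker)) {
    io <- match(pairing$organism_id, rownames(marker))
    if (anyNA(io)) {
      abort("marker matrix missing organisms referenced by the pairing",
            class = "coevo_crossref_error")
    }
    S <- unclass(marker)[io, io, drop = FALSE]
    diag(S) <- 0
    dimnames(S) <- list(labs, labs)
    out$S <- S
  }
  structure(out, class = "paired_matrices")
}

#' @export
print.paired_matrices <- function(x, ...) {
  cat(sprintf("<paired_matrices> %d pairing rows%s\n", nrow(x$X),
              if (is.null(x$S)) "" else " (+ neutral marker)"))
  invisible(x)
}

offdiag_upper <- function(m) m[upper.tri(m)]

#' Remove the speciation signal from paired distance matrices
#'
#' Protein distance matrices of two families sharing one species tree are
#' correlated simply because both track speciation. This subtracts the
#' component explained by a clock-like neutral marker (an 18S rRNA analog):
#' in `"residual"` mode X' = X - beta_X * S where beta_X is the
#' least-squares slope of the off-diagonal X cells on the marker cells
#' (likewise Y); in `"subtract"` mode the marker is subtracted
#' element-wise. Same-organism cells (marker distance 0) pass through
#' unchanged in residual mode.
#'
#' @param pd A `paired_matrices` with the marker matrix `S` present.
#' @param mode `"residual"` (default) or `"subtract"`.
#' @return A `paired_matrices` with corrected `X` and `Y`; attributes
#'   `beta_x`, `beta_y` and `correction` record what was done. If the
#'   marker is constant the correction is skipped with a warning.
#' @export
speciation_correct <- function(pd, mode = c("residual", "subtract")) {
  mode <- match.arg(mode)
  if (is.null(pd$S)) {
    abort("no marker matrix present; build with marker=", class = "coevo_input_error")
  }
  s <- offdiag_upper(pd$S)
  if (isTRUE(all.equal(var(s), 0)) || length(unique(s)) == 1L) {
    warn("marker distances constant; speciation correction skipped")
    attr(pd, "correction") <- "skipped"
    return(pd)
  }
  if (mode == "subtract") {
    pd$X <- pd$X - pd$S
    pd$Y <- pd$Y - pd$S
    attr(pd, "correction") <- "subtract"
    return(pd)
  }
  beta_x <- unname(coef(lm(offdiag_upper(pd$X) ~ s))[2L])
  beta_y <- unname(coef(lm(offdiag_upper(pd$Y) ~ s))[2L])
  pd$X <- pd$X - beta_x * pd$S
  pd$Y <- pd$Y - beta_y * pd$S
  diag(pd$X) <- 0
  diag(pd$Y) <- 0
  attr(pd, "correction") <- "residual"
  attr(pd, "beta_x") <- beta_x
  attr(pd, "beta_y") <- beta_y
  pd
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation R of the off-diagonal upper-triangle cells, with a
#' null distribution built by jointly permuting the row/column labels of
#' the second matrix. One-sided by default for positive association:
#' p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm).
#'
#' @param X,Y Symmetric numeric matrices of identical dimension.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `mantel_result` with fields `R`, `p_value`,
#'   `n_perm`, `alternative`, `seed`, `n`.
#' @export
mantel_test <- function(X, Y, n_perm = 9999, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!all(dim(X) == dim(Y))) {
    abort("matrices must have the same shape", class = "coevo_input_error")
  }
  if (n_perm < 99) abort("n_perm must be >= 99", class = "coevo_input_error")
  n <- nrow(X)
  x <- offdiag_upper(X)
  y <- offdiag_upper(Y)
  if (anyNA(x) || anyNA(y)) {
    abort("NA distances; resolve saturated cells before the Mantel test",
          class = "coevo_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in a matrix; R undefined", class = "coevo_input_error")
  }
  R_obs <- cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  ut <- which(upper.tri(X), arr.ind = TRUE)
  iu <- ut[, 1L]; ju <- ut[, 2L]
  perms <- t(vapply(seq_len(n_perm), function(k) sample.int(n),
                    integer(n)))
  rows <- perms[, iu, drop = FALSE]
  cols <- perms[, ju, drop = FALSE]
  Yv <- matrix(Y[cbind(as.vector(rows), as.vector(cols))],
               nrow = n_perm)
  xc <- x - mean(x)
  Yc <- Yv - rowMeans(Yv)
  denom <- sqrt(rowSums(Yc^2)) * sqrt(sum(xc^2))
  R_perm <- as.vector(Yc %*% xc) / denom
  R_perm[denom == 0] <- 0
  p <- if (alternative == "greater") {
    (1 + sum(R_perm >= R_obs)) / (1 + n_perm)
  } else {
    (1 + sum(abs(R_perm) >= abs(R_obs))) / (1 + n_perm)
  }
  structure(
    list(R = R_obs, p_value = p, n_perm = n_perm, alternative = alternative,
         seed = seed, n = n),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble(R = x$R, p_value = x$p_value, n_perm = x$n_perm,
         alternative = x$alternative, n = x$n)
}

#' MirrorTree analysis with speciation correction
#'
#' Full distance-matrix co-evolution analysis of two interacting families:
#' Poisson-corrected p-distances per family, paralog-expanded paired
#' matrices via the pairing table, optional removal of the shared
#' speciation signal using a neutral marker alignment, and a Mantel
#' permutation test on the (corrected) matrices. Both the corrected and
#' uncorrected correlations are reported.
#'
#' @param famA,famB [aligned_family] protein alignments.
#' @param pairing Pairing tibble ([read_pairing()]).
#' @param marker Optional [aligned_family] for the neutral marker, with one
#'   sequence per organism (DNA markers use the Kimura-2P distance, protein
#'   markers the Poisson-corrected p-distance).
#' @inheritParams mantel_test
#' @param correction `"residual"` or `"subtract"`, see
#'   [speciation_correct()].
#' @return An object of class `tol_mirrortree`: list with `mantel`
#'   (corrected-matrix [mantel_test()] result), `R`, `p_value`,
#'   `R_uncorrected`, `paired` (corrected `paired_matrices`),
#'   `paired_uncorrected`, and the correction betas when applicable.
#' @export
tol_mirrortree <- function(famA, famB, pairing, marker = NULL,
                           n_perm = 9999, seed = NULL,
                           correction = c("residual", "subtract"),
                           alternative = c("greater", "two.sided")) {
  correction <- match.arg(correction)
  alternative <- match.arg(alternative)
  distA <- poisson_correct_matrix(p_distance(famA))
  distB <- poisson_correct_matrix(p_distance(famB))
  marker_dist <- NULL
  if (!is.null(marker)) {
    md <- if (marker$alphabet == "DNA") kimura2p_matrix(marker)
          else poisson_correct_matrix(p_distance(marker))
    if (anyDuplicated(marker$organisms)) {
      abort("marker must have one sequence per organism",
            class = "coevo_input_error")
    }
    dimnames(md) <- list(marker$organisms, marker$organisms)
    marker_dist <- md
  }
  pd_raw <- build_paired_matrices(distA, distB, pairing, marker = marker_dist)
  R_unc <- cor(offdiag_upper(pd_raw$X), offdiag_upper(pd_raw$Y),
               use = "complete.obs")
  pd <- if (!is.null(marker_dist)) speciation_correct(pd_raw, mode = correction)
        else pd_raw
  mt <- mantel_test(pd$X, pd$Y, n_perm = n_perm, seed = seed,
                    alternative = alternative)
  structure(
    list(mantel = mt, R = mt$R, p_value = mt$p_value,
         R_uncorrected = R_unc, paired = pd, paired_uncorrected = pd_raw,
         correction = attr(pd, "correction") %||% "none",
         beta_x = attr(pd, "beta_x"), beta_y = attr(pd, "beta_y")),
    class = "tol_mirrortree"
  )
}

#' @export
print.tol_mirrortree <- function(x, ...) {
  cat(sprintf(
    "MirrorTree: R = %.4f (uncorrected %.4f), p = %.4g [correction: %s]\n",
    x$R, x$R_uncorrected, x$p_value, x$correction))
  invisible(x)
}

#' @export
glance.tol_mirrortree <- function(x, ...) {
  tibble(R = x$R, p_value = x$p_value, R_uncorrected = x$R_uncorrected,
         correction = x$correction, n_pairs = nrow(x$paired$X),
         n_perm = x$mantel$n_perm)
}

#' @export
tidy.tol_mirrortree <- function(x, ...) {
  tibble(
    x_dist = offdiag_upper(x$paired$X),
    y_dist = offdiag_upper(x$paired$Y),
    marker_dist = if (!is.null(x$paired$S)) offdiag_upper(x$paired$S)
                  else NA_real_
  )
}

#' Scatter plot of paired family distances
#'
#' @param object A `tol_mirrortree` result.
#' @param ... Unused.
#' @return A ggplot: corrected family-A vs family-B distances per pair of
#'   pairing rows, with the fitted line and the Mantel R annotated.
#' @export
autoplot.tol_mirrortree <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_dist, y = .data$y_dist)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(
      x = "family A distance (corrected)",
      y = "family B distance (corrected)",
      title = sprintf("MirrorTree R = %.2f (p = %.3g)",
                      object$R, object$p_value)
    )
}
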