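check_tip_states <- function(tree, tips) {
  if (is.null(tree$tip.label)) {
    abort("tree has no tip labels", class = "coevo_input_error")
  }
  if (is.data.frame(tips)) {
    tips <- setNames(as.integer(tips$state), tips$organism_id)
  }
  miss <- setdiff(tree$tip.label, names(tips))
  if (length(miss) > 0L) {
    abort(paste0("tips without state: ", paste(miss, collapse = ", ")),
          class = "coevo_input_error")
  }
  st <- tips[tree$tip.label]
  if (!all(st %in% c(0L, 1L))) {
    abort("states must be 0 (no interaction) or 1 (interaction)",
          class = "coevo_input_error")
  }
  st
}

#' Fitch parsimony trace of a binary trait
#'
#' Standard Fitch bottom-up pass for a two-state character (0 = absence of
#' the interaction, 1 = presence) on a rooted tree: child state sets are
#' intersected where possible, unioned (scoring one change) otherwise.
#' Returns the most-parsimonious state set per internal node and the
#' minimum change count. Polytomies are resolved arbitrarily first, with a
#' warning.
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Named integer vector (names = tip labels, values 0/1) or a
#'   tibble with `organism_id` and `state`.
#' @return An object of class `fitch_trace`: list with `node_sets` (tibble
#'   `node`, `states` like "0", "1" or "0/1"), `root_set`, `min_changes`.
#' @export
fitch_trace <- function(tree, tips) {
  if (!ape::is.binary.phylo(tree)) {
    warn("tree has polytomies; resolving arbitrarily")
    tree <- ape::multi2di(tree)
  }
  st <- check_tip_states(tree, tips)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0, 1}
  sets <- integer(n_node)
  sets[seq_len(n_tip)] <- ifelse(st == 0L, 1L, 2L)
  changes <- 0L
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  # parents in first-appearance (postorder) order: children complete first
  for (parent in unique(edge[, 1L])) {
    kids <- edge[edge[, 1L] == parent, 2L]
    acc <- sets[kids[1L]]
    for (c2 in kids[-1L]) {
      inter <- bitwAnd(acc, sets[c2])
      if (inter == 0L) {
        acc <- bitwOr(acc, sets[c2])
        changes <- changes + 1L
      } else {
        acc <- inter
      }
    }
    sets[parent] <- acc
  }
  lab <- c("0", "1", "0/1")[sets]
  root <- n_tip + 1L
  structure(
    list(
      node_sets = tibble(
        node = seq_len(n_node),
        is_tip = seq_len(n_node) <= n_tip,
        label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
        states = lab
      ),
      root_set = lab[root],
      min_changes = changes,
      tree = tree
    ),
    class = "fitch_trace"
  )
}

#' @export
print.fitch_trace <- function(x, ...) {
  cat(sprintf("Fitch trace: root set {%s}, %d change(s)\n",
              x$root_set, x$min_changes))
  invisible(x)
}

#' @export
glance.fitch_trace <- function(x, ...) {
  tibble(root_set = x$root_set, min_changes = x$min_changes)
}

#' @export
tidy.fitch_trace <- function(x, ...) x$node_sets

mk2_pmat <- function(rate, t) {
  e <- exp(-2 * rate * t)
  stay <- 0.5 + 0.5 * e
  move <- 0.5 - 0.5 * e
  matrix(c(stay, move, move, stay), 2L, 2L)
}

#' Marginal ancestral reconstruction under a symmetric two-state Mk model
#'
#' Felsenstein pruning for a binary trait under a single symmetric rate,
#' with marginal posterior state probabilities at every internal node
#' computed by a down-pass/up-pass (outside-likelihood) sweep under an
#' equal root prior. The rate can be fixed or optimized by a bounded 1-D
#' search; a richer model is unidentifiable for an (almost) invariant
#' trait such as an obligate interaction present across the whole tree.
#'
#' @param tree An [ape::phylo]; missing branch lengths default to 1
#'   (cladogram convention).
#' @param tips As in [fitch_trace()].
#' @param rate Positive substitution rate, or `NULL` to optimize in
#'   `interval`.
#' @param interval Search interval for the rate when optimized.
#' @return An object of class `mk2_trace`: list with `marginals` (tibble
#'   `node`, `p_state0`, `p_state1`), `loglik`, `rate`, `root_p1`.
#' @export
mk2_marginal <- function(tree, tips, rate = NULL, interval = c(1e-6, 50)) {
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) {
    abort("branch lengths must be non-negative", class = "coevo_input_error")
  }
  if (sum(tree$edge.length) == 0) {
    abort("zero-length tree", class = "coevo_input_error")
  }
  if (!ape::is.binary.phylo(tree)) {
    warn("tree has polytomies; resolving arbitrarily")
    tree <- ape::multi2di(tree)
    tree$edge.length[tree$edge.length == 0] <- 1e-8
  }
  st <- check_tip_states(tree, tips)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length

  downpass <- function(r) {
    L <- matrix(0, n_node, 2L)
    L[cbind(seq_len(n_tip), st + 1L)] <- 1
    logscale <- 0
    # parents in first-appearance order of the postorder edge list: all
    # child subtrees are complete before their parent is combined
    parents <- unique(edge[, 1L])
    for (parent in parents) {
      rows <- which(edge[, 1L] == parent)
      acc <- c(1, 1)
      for (rk in rows) {
        child <- edge[rk, 2L]
        acc <- acc * as.vector(mk2_pmat(r, elen[rk]) %*% L[child, ])
      }
      mx <- max(acc)
      if (mx > 0) {
        logscale <- logscale + log(mx)
        acc <- acc / mx
      }
      L[parent, ] <- acc
    }
    list(L = L, logscale = logscale)
  }
  loglik_of <- function(r) {
    dp <- downpass(r)
    log(sum(0.5 * dp$L[root, ])) + dp$logscale
  }
  if (is.null(rate)) {
    opt <- optimize(loglik_of, interval = interval, maximum = TRUE)
    rate <- opt$maximum
  }
  dp <- downpass(rate)
  L <- dp$L
  # outside pass: out[v, s] = likelihood of everything except v's subtree,
  # given state s at v
  out <- matrix(NA_real_, n_node, 2L)
  out[root, ] <- c(0.5, 0.5)
  for (k in rev(seq_len(nrow(edge)))) {       # preorder over edges
    parent <- edge[k, 1L]
    child <- edge[k, 2L]
    sibs <- setdiff(edge[edge[, 1L] == parent, 2L], child)
    sib_contrib <- c(1, 1)
    for (b in sibs) {
      rk <- which(edge[, 2L] == b)
      sib_contrib <- sib_contrib * as.vector(mk2_pmat(rate, elen[rk]) %*% L[b, ])
    }
    pre <- out[parent, ] * sib_contrib
    out[child, ] <- as.vector(pre %*% mk2_pmat(rate, elen[k]))
    mx <- max(out[child, ])
    if (mx > 0) out[child, ] <- out[child, ] / mx
  }
  post <- out * L
  post <- post / rowSums(post)
  structure(
    list(
      marginals = tibble(
        node = seq_len(n_node),
        is_tip = seq_len(n_node) <= n_tip,
        label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
        p_state0 = post[, 1L], p_state1 = post[, 2L]
      ),
      loglik = loglik_of(rate), rate = rate,
      root_p1 = post[root, 2L], tree = tree
    ),
    class = "mk2_trace"
  )
}

#' @export
print.mk2_trace <- function(x, ...) {
  cat(sprintf(
    "Mk2 marginal trace: rate = %.4g, logLik = %.4f, P(root = 1) = %.4f\n",
    x$rate, x$loglik, x$root_p1))
  invisible(x)
}

#' @export
glance.mk2_trace <- function(x, ...) {
  tibble(rate = x$rate, loglik = x$loglik, root_p1 = x$root_p1)
}

#' @export
tidy.mk2_trace <- function(x, ...) x$marginals
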