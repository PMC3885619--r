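#' Physicochemical class of an amino acid
#'
#' Partition of the 20 standard residues into five classes: small nonpolar
#' (G, A, S, T), hydrophobic (C, V, I, L, P, F, Y, M, W), polar (N, Q, H),
#' negatively charged (D, E) and positively charged (K, R).
#'
#' @param aa Character vector of one-letter residue codes.
#' @return Character vector of class labels; non-standard symbols map to
#'   `"unknown"`.
#' @export
residue_class <- function(aa) {
  cls <- AA_CLASSES[toupper(aa)]
  cls[is.na(cls)] <- "unknown"
  unname(cls)
}

AA_CLASSES <- c(
  G = "small-nonpolar", A = "small-nonpolar", S = "small-nonpolar",
  T = "small-nonpolar",
  C = "hydrophobic", V = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", P = "hydrophobic", F = "hydrophobic",
  Y = "hydrophobic", M = "hydrophobic", W = "hydrophobic",
  N = "polar", Q = "polar", H = "polar",
  D = "negatively-charged", E = "negatively-charged",
  K = "positively-charged", R = "positively-charged"
)

#' Detect clade-specific residues in an alignment
#'
#' Scans every alignment column for a clade fixed for a residue (strict
#' rule) or for a residue class (class rule) that is absent from all
#' members of at least one other clade. A clade qualifies at a column only
#' if it meets `min_clade_size` and none of its members carries a gap or
#' missing symbol there. Disjointness between contrasted clades is always
#' checked on the residue sets themselves, so every strict call is also a
#' class-rule call. With `contrast = "pairwise"` (default) any qualifying
#' clade pair produces a call; `contrast = "all"` additionally requires
#' every qualifying clade to be uniform and pairwise disjoint.
#'
#' @param fam An [aligned_family].
#' @param clades Tibble with `organism_id`, `clade` ([read_clades()]).
#' @param rule `"strict"` or `"class"`.
#' @param min_clade_size Minimum organisms per clade (default 2);
#'   singleton clades are listed in compositions but never drive a call.
#' @param contrast `"pairwise"` (default) or `"all"`.
#' @param reference_seq_id Optional reference for residue numbering.
#' @return A tibble of calls with `column`, `reference_residue` (NA when
#'   no reference given or the reference is gapped), `qualifying_pairs`
#'   (semicolon-joined "cladeX|cladeY"), `composition` (per-clade residue
#'   sets), `rule`.
#' @export
detect_clade_specific <- function(fam, clades, rule = c("strict", "class"),
                                  min_clade_size = 2L,
                                  contrast = c("pairwise", "all"),
                                  reference_seq_id = NULL) {
  rule <- match.arg(rule)
  contrast <- match.arg(contrast)
  clades <- as_tibble(clades)
  idx <- match(fam$organisms, clades$organism_id)
  if (anyNA(idx)) {
    abort(paste0("organisms without clade assignment: ",
                 paste(unique(fam$organisms[is.na(idx)]), collapse = ", ")),
          class = "coevo_crossref_error")
  }
  seq_clade <- clades$clade[idx]
  clade_rows <- split(seq_along(fam$seq_ids), seq_clade)
  big <- names(clade_rows)[lengths(clade_rows) >= min_clade_size]
  if (length(big) < 2L) {
    abort("need at least two clades meeting min_clade_size",
          class = "coevo_input_error")
  }
  calls <- list()
  for (col in seq_len(fam$n_cols)) {
    column <- fam$mat[, col]
    # per qualifying clade: residue set, NULL when disqualified by a gap
    sets <- lapply(clade_rows[big], function(rows) {
      res <- column[rows]
      if (any(is_missing_char(res, fam$alphabet))) return(NULL)
      unique(res)
    })
    uniform <- vapply(names(sets), function(cl) {
      s <- sets[[cl]]
      if (is.null(s)) return(FALSE)
      if (rule == "strict") length(s) == 1L
      else length(unique(residue_class(s))) == 1L
    }, logical(1))
    qual <- names(sets)[uniform]
    if (length(qual) < 2L) next
    pair_idx <- combn(qual, 2L)
    disjoint <- vapply(seq_len(ncol(pair_idx)), function(k) {
      length(intersect(sets[[pair_idx[1L, k]]], sets[[pair_idx[2L, k]]])) == 0L
    }, logical(1))
    ok <- if (contrast == "pairwise") {
      any(disjoint)
    } else {
      length(qual) == length(big) && all(disjoint)
    }
    if (!ok) next
    qp <- paste(pair_idx[1L, disjoint], pair_idx[2L, disjoint], sep = "|",
                collapse = ";")
    comp <- paste(vapply(names(clade_rows), function(cl) {
      res <- column[clade_rows[[cl]]]
      paste0(cl, "=", paste(sort(unique(res)), collapse = "/"))
    }, character(1)), collapse = "; ")
    calls[[length(calls) + 1L]] <- tibble(
      column = col, qualifying_pairs = qp, composition = comp, rule = rule
    )
  }
  out <- if (length(calls) == 0L) {
    tibble(column = integer(), qualifying_pairs = character(),
           composition = character(), rule = character())
  } else {
    bind_rows(calls)
  }
  ref_res <- if (!is.null(reference_seq_id) && nrow(out) > 0L) {
    column_to_reference(fam, reference_seq_id, out$column)
  } else {
    rep(NA_integer_, nrow(out))
  }
  mutate(out, reference_residue = ref_res, .after = "column")
}

#' Overlap of clade-specific calls with correlated-mutation residues
#'
#' @param calls Tibble from [detect_clade_specific()] for one family.
#' @param caps A `caps_result`.
#' @param family `"A"` or `"B"`: which side of the scan the calls belong
#'   to (columns must refer to that family's alignment).
#' @return One-row tibble with `n_calls`, `n_caps_residues`, `n_overlap`,
#'   `pct_of_caps`, `covered_groups` (comma-joined ids), `n_groups_covered`.
#' @export
overlap_with_caps <- function(calls, caps, family = c("A", "B")) {
  family <- match.arg(family)
  caps_sites <- if (family == "A") unique(caps$significant$site_a)
                else unique(caps$significant$site_b)
  ov <- intersect(calls$column, caps_sites)
  site_col <- if (family == "A") "sites_a" else "sites_b"
  covered <- caps$groups$group_id[vapply(caps$groups[[site_col]],
                                         function(s) any(s %in% ov),
                                         logical(1))]
  tibble(
    n_calls = length(unique(calls$column)),
    n_caps_residues = length(caps_sites),
    n_overlap = length(ov),
    pct_of_caps = if (length(caps_sites) > 0) 100 * length(ov) / length(caps_sites)
                  else 0,
    covered_groups = paste(covered, collapse = ","),
    n_groups_covered = length(covered)
  )
}

#' Combined two-family clade/CAPS overlap summary
#'
#' Pools both families: the fraction of all unique correlated residues that
#' are clade-specific and the fraction of groups covered by at least one
#' clade-specific residue.
#'
#' @param caps A `caps_result`.
#' @param calls_a,calls_b Clade-specific calls for family A and B.
#' @return One-row tibble with per-family overlap counts, total counts and
#'   the pooled percentages.
#' @export
caps_clade_overlap <- function(caps, calls_a, calls_b) {
  oa <- overlap_with_caps(calls_a, caps, "A")
  ob <- overlap_with_caps(calls_b, caps, "B")
  groups_cov <- union(
    strsplit(oa$covered_groups, ",")[[1]],
    strsplit(ob$covered_groups, ",")[[1]]
  )
  groups_cov <- groups_cov[nzchar(groups_cov)]
  n_res_total <- oa$n_caps_residues + ob$n_caps_residues
  n_ov_total <- oa$n_overlap + ob$n_overlap
  tibble(
    n_overlap_a = oa$n_overlap, n_overlap_b = ob$n_overlap,
    n_caps_residues = n_res_total, n_overlap = n_ov_total,
    pct_residues = if (n_res_total > 0) 100 * n_ov_total / n_res_total else 0,
    n_groups = nrow(caps$groups),
    n_groups_covered = length(groups_cov),
    pct_groups = if (nrow(caps$groups) > 0)
      100 * length(groups_cov) / nrow(caps$groups) else 0
  )
}
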