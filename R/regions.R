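#' Count residues falling inside annotated regions
#'
#' Pure interval arithmetic on reference residue numbers: for each region,
#' how many of the supplied residues fall inside its 1-based inclusive
#' bounds, and what percentage of the residue set that is.
#'
#' @param residues Integer vector of residue numbers (NA dropped).
#' @param regions Tibble with `region_name`, `start`, `end` (e.g. from
#'   [read_regions()]).
#' @return A tibble with `region_name`, `n_total`, `n_in`, `pct`.
#' @export
region_overlap_counts <- function(residues, regions) {
  residues <- unique(residues[!is.na(residues)])
  bind_rows(lapply(seq_len(nrow(regions)), function(k) {
    n_in <- sum(residues >= regions$start[k] & residues <= regions$end[k])
    tibble(region_name = regions$region_name[k],
           n_total = length(residues), n_in = n_in,
           pct = if (length(residues) > 0) 100 * n_in / length(residues)
                 else 0)
  }))
}

#' Region overlap report for correlated-mutation results
#'
#' Maps the significant sites of a correlated-mutation scan to reference
#' residue numbers in each family, counts unique correlated residues inside
#' each annotated region (functional core domains, RNA-binding domain,
#' minimal interaction domains, ...), flags residues as conserved
#' (alignment column constant once gaps are ignored) or changed, and
#' classifies each group by whether it touches the designated domain of
#' both families, one, or neither.
#'
#' @param caps A `caps_result` from [caps_scan()].
#' @param regions Regions tibble ([read_regions()]); regions are assigned
#'   to the family whose alignment contains their `reference_seq_id`.
#' @param famA,famB The family alignments the scan used.
#' @param refA,refB Reference sequence ids used for residue numbering.
#' @param domain_a,domain_b Names of the regions used for the group-level
#'   both/one/neither classification (default: each family's first
#'   region).
#' @return A list of class `region_report` with tibbles `residues`
#'   (family, column, reference_residue, conserved), `region_summary`
#'   (family, region_name, n_total, n_in, pct) and `group_summary`
#'   (group_id, domain_class).
#' @export
residue_region_report <- function(caps, regions, famA, famB, refA, refB,
                                  domain_a = NULL, domain_b = NULL) {
  fam_of_region <- vapply(regions$reference_seq_id, function(r) {
    if (r %in% famA$seq_ids) "A" else if (r %in% famB$seq_ids) "B"
    else abort(paste0("region reference in neither family: ", r),
               class = "coevo_crossref_error")
  }, character(1))
  ref_len_a <- sum(!is_gap(ref_row(famA, refA)))
  ref_len_b <- sum(!is_gap(ref_row(famB, refB)))
  bad_a <- regions$end[fam_of_region == "A"] > ref_len_a
  bad_b <- regions$end[fam_of_region == "B"] > ref_len_b
  if (any(bad_a) || any(bad_b)) {
    abort("region exceeds reference length", class = "coevo_input_error")
  }

  residue_tab <- function(fam, ref, sites, fam_label) {
    sites <- sort(unique(sites))
    if (length(sites) == 0L) {
      return(tibble(family = character(), column = integer(),
                    reference_residue = integer(), conserved = logical()))
    }
    res <- column_to_reference(fam, ref, sites)
    cons <- vapply(sites, function(c) {
      col <- fam$mat[, c]
      col <- col[!is_missing_char(col, fam$alphabet)]
      length(unique(col)) <= 1L
    }, logical(1))
    tibble(family = fam_label, column = sites, reference_residue = res,
           conserved = cons)
  }
  res_a <- residue_tab(famA, refA, caps$significant$site_a, "A")
  res_b <- residue_tab(famB, refB, caps$significant$site_b, "B")
  residues <- bind_rows(res_a, res_b)

  region_summary <- bind_rows(lapply(c("A", "B"), function(f) {
    regs <- regions[fam_of_region == f, , drop = FALSE]
    if (nrow(regs) == 0L) return(NULL)
    rr <- residues$reference_residue[residues$family == f]
    mutate(region_overlap_counts(rr, regs), family = f, .before = 1L)
  }))

  pick_domain <- function(given, f) {
    if (!is.null(given)) return(given)
    nm <- regions$region_name[fam_of_region == f]
    if (length(nm) > 0L) nm[[1L]] else NA_character_
  }
  domain_a <- pick_domain(domain_a, "A")
  domain_b <- pick_domain(domain_b, "B")
  in_domain <- function(res_vec, domain) {
    if (is.na(domain)) return(FALSE)
    k <- which(regions$region_name == domain)[1L]
    any(!is.na(res_vec) & res_vec >= regions$start[k] &
          res_vec <= regions$end[k])
  }
  group_summary <- if (nrow(caps$groups) == 0L) {
    tibble(group_id = character(), domain_class = character())
  } else {
    bind_rows(lapply(seq_len(nrow(caps$groups)), function(g) {
      ra <- column_to_reference(famA, refA, caps$groups$sites_a[[g]])
      rb <- column_to_reference(famB, refB, caps$groups$sites_b[[g]])
      hit <- in_domain(ra, domain_a) + in_domain(rb, domain_b)
      tibble(group_id = caps$groups$group_id[g],
             domain_class = c("neither", "one-domain", "both-domains")[hit + 1L])
    }))
  }
  structure(
    list(residues = residues, region_summary = region_summary,
         group_summary = group_summary,
         domain_a = domain_a, domain_b = domain_b),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat("<region_report>\n")
  print(x$region_summary)
  if (nrow(x$group_summary) > 0L) {
    print(dplyr::count(x$group_summary, .data$domain_class))
  }
  invisible(x)
}
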