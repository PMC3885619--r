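#' Run the full co-evolution analysis pipeline
#'
#' Orchestrates an end-to-end run over either a simulated bundle or
#' user-supplied files: family identities and distances, the
#' speciation-corrected MirrorTree correlation with Mantel test (plus the
#' decoy control when available), the correlated-mutation scan with
#' grouping, clade-specific residue detection with overlap summaries, and
#' ancestral tracing of the binary interaction trait. Any stage failure
#' halts the run with a stage-labelled error. When `outdir` is given,
#' stage tables are written as TSV and the consolidated report as JSON
#' (written atomically via a temp file); every reported percentage is
#' recomputable from the stage TSVs.
#'
#' @param sim A `coevo_sim` from [simulate_families()]; alternatively
#'   supply `inputs`, a named list with `famA`, `famB`, `pairing` and
#'   optionally `marker`, `decoy`, `clades`, `tree`, `states`.
#' @param inputs See above; ignored when `sim` is given.
#' @param n_perm Mantel permutations.
#' @param alpha Significance level of the correlated-mutation filter.
#' @param n_resample Null draws for the filter.
#' @param seed Master seed; stage seeds derive from it.
#' @param outdir Optional output directory.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(sim = NULL, inputs = NULL, n_perm = 999,
                         alpha = 0.05, n_resample = 1000L, seed = 1L,
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "coevo_stage_error", parent = e)
    })
  }
  if (is.null(sim) && is.null(inputs)) {
    abort("supply either sim or inputs", class = "coevo_input_error")
  }
  x <- if (!is.null(sim)) sim else inputs
  if (is.null(x$famA) || is.null(x$famB) || is.null(x$pairing)) {
    abort("famA, famB and pairing are required", class = "coevo_input_error")
  }

  identity_tab <- stage("identity", tibble(
    family = c(x$famA$family_name, x$famB$family_name),
    mean_identity_pct = c(mean_pairwise_identity(x$famA),
                          mean_pairwise_identity(x$famB))
  ))

  mt <- stage("mirrortree", tol_mirrortree(
    x$famA, x$famB, x$pairing, marker = x$marker,
    n_perm = n_perm, seed = seed + 1L))
  decoy_R <- NULL
  if (!is.null(x$decoy)) {
    decoy_pairing <- mutate(x$pairing,
                            member_b = paste0(.data$organism_id, "_D1"))
    decoy_pairing <- filter(decoy_pairing,
                            .data$member_b %in% x$decoy$seq_ids)
    decoy_pairing <- distinct(decoy_pairing)
    decoy_R <- stage("mirrortree_decoy", tol_mirrortree(
      x$famA, x$decoy, decoy_pairing, marker = x$marker,
      n_perm = n_perm, seed = seed + 2L))
  }

  caps <- stage("caps", caps_scan(
    x$famA, x$famB, x$pairing, alpha = alpha,
    n_resample = n_resample, seed = seed + 3L))

  clade_section <- NULL
  if (!is.null(x$clades)) {
    clade_section <- stage("cladespec", {
      calls_a <- detect_clade_specific(x$famA, x$clades)
      calls_b <- detect_clade_specific(x$famB, x$clades)
      list(calls_a = calls_a, calls_b = calls_b,
           overlap = caps_clade_overlap(caps, calls_a, calls_b))
    })
  }

  anc_section <- NULL
  if (!is.null(x$tree)) {
    anc_section <- stage("ancstate", {
      states <- x$states
      if (is.null(states)) {
        # obligate-interaction default: every organism heterodimerizes
        states <- setNames(rep(1L, length(x$tree$tip.label)),
                           x$tree$tip.label)
      }
      ft <- fitch_trace(x$tree, states)
      mk <- mk2_marginal(x$tree, states)
      list(fitch = ft, mk2 = mk)
    })
  }

  report <- structure(
    list(
      seed = seed, n_perm = n_perm, alpha = alpha, n_resample = n_resample,
      identity = identity_tab,
      mirrortree = glance(mt),
      mirrortree_decoy = if (!is.null(decoy_R)) glance(decoy_R) else NULL,
      caps = glance(caps),
      caps_groups = caps$groups,
      cladespec = if (!is.null(clade_section)) clade_section$overlap else NULL,
      ancstate = if (!is.null(anc_section)) tibble(
        fitch_root = anc_section$fitch$root_set,
        fitch_changes = anc_section$fitch$min_changes,
        mk2_root_p1 = anc_section$mk2$root_p1
      ) else NULL,
      objects = list(mirrortree = mt, mirrortree_decoy = decoy_R,
                     caps = caps, cladespec = clade_section,
                     ancstate = anc_section)
    ),
    class = "run_report"
  )

  if (!is.null(outdir)) write_report(report, outdir,
                                     clade_section = clade_section)
  report
}

write_report <- function(report, outdir, clade_section = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  caps <- report$objects$caps
  readr::write_tsv(as_tibble(caps$correlations),
                   file.path(outdir, "caps_pairs.tsv"), progress = FALSE)
  groups_flat <- mutate(
    caps$groups,
    sites_a = map_chr(.data$sites_a, paste, collapse = ","),
    sites_b = map_chr(.data$sites_b, paste, collapse = ",")
  )
  readr::write_tsv(groups_flat, file.path(outdir, "caps_groups.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(report$objects$mirrortree),
                   file.path(outdir, "mirrortree_cells.tsv"),
                   progress = FALSE)
  if (!is.null(clade_section)) {
    readr::write_tsv(clade_section$calls_a,
                     file.path(outdir, "clade_calls_famA.tsv"),
                     progress = FALSE)
    readr::write_tsv(clade_section$calls_b,
                     file.path(outdir, "clade_calls_famB.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$objects$ancstate)) {
    readr::write_tsv(tidy(report$objects$ancstate$mk2),
                     file.path(outdir, "ancstate_nodes.tsv"),
                     progress = FALSE)
  }
  json <- report[c("seed", "n_perm", "alpha", "n_resample", "identity",
                   "mirrortree", "mirrortree_decoy", "caps", "cladespec",
                   "ancstate")]
  tmp <- file.path(outdir, ".report.json.tmp")
  jsonlite::write_json(json, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  file.rename(tmp, file.path(outdir, "report.json"))
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("identity:\n"); print(x$identity)
  cat("mirrortree:\n"); print(x$mirrortree)
  if (!is.null(x$mirrortree_decoy)) {
    cat("decoy:\n"); print(x$mirrortree_decoy)
  }
  cat("correlated mutations:\n"); print(x$caps)
  if (!is.null(x$cladespec)) { cat("clade overlap:\n"); print(x$cladespec) }
  if (!is.null(x$ancstate)) { cat("ancestral trait:\n"); print(x$ancstate) }
  invisible(x)
}
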