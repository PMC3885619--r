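#' Aligned sequence family
#'
#' An `aligned_family` holds a gapped multiple sequence alignment for one
#' gene/protein family together with the organism each sequence comes from.
#' Residues are stored as a character matrix (one row per sequence, one
#' column per alignment column) so column-wise operations are cheap.
#'
#' @param seq_ids Character vector of unique sequence identifiers.
#' @param organisms Character vector of organism identifiers, parallel to
#'   `seq_ids`.
#' @param residues Character vector of gapped sequences (all the same
#'   length), or a character matrix with one row per sequence.
#' @param family_name Label for the family.
#' @param alphabet `"AA"` (default) or `"DNA"`.
#'
#' @return An object of class `aligned_family` with fields `family_name`,
#'   `seq_ids`, `organisms`, `mat` (character matrix) and `n_cols`.
#' @export
aligned_family <- function(seq_ids, organisms, residues,
                           family_name = "family", alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  seq_ids <- as.character(seq_ids)
  organisms <- as.character(organisms)
  if (anyDuplicated(seq_ids)) {
    abort("duplicate seq_id in alignment", class = "coevo_input_error")
  }
  if (length(organisms) != length(seq_ids)) {
    abort("organisms must be parallel to seq_ids", class = "coevo_input_error")
  }
  if (is.matrix(residues)) {
    mat <- residues
  } else {
    residues <- toupper(as.character(residues))
    lens <- nchar(residues)
    if (length(unique(lens)) > 1L) {
      abort(
        paste0("aligned sequences must have equal length; got lengths ",
               paste(unique(lens), collapse = ", ")),
        class = "coevo_alignment_error"
      )
    }
    if (any(lens == 0L)) abort("empty sequence", class = "coevo_input_error")
    mat <- do.call(rbind, strsplit(residues, "", fixed = TRUE))
  }
  rownames(mat) <- seq_ids
  ok <- if (alphabet == "AA") c(AA_LETTERS, "-", "X", "*", ".")
        else c("A", "C", "G", "T", "U", "N", "-", ".")
  bad <- setdiff(unique(as.vector(mat)), ok)
  if (length(bad) > 0L) {
    # unknown symbols are coerced to the missing symbol rather than rejected
    mat[mat %in% bad] <- if (alphabet == "AA") "X" else "N"
  }
  structure(
    list(family_name = family_name, seq_ids = seq_ids, organisms = organisms,
         mat = mat, n_cols = ncol(mat), alphabet = alphabet),
    class = "aligned_family"
  )
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")
MISSING_AA <- "X"
MISSING_DNA <- "N"

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family '%s'> %d sequences x %d columns (%s)\n",
              x$family_name, length(x$seq_ids), x$n_cols, x$alphabet))
  invisible(x)
}

#' @export
#' @method as_tibble aligned_family
as_tibble.aligned_family <- function(x, ...) {
  tibble(
    seq_id = x$seq_ids,
    organism_id = x$organisms,
    residues = apply(x$mat, 1L, paste, collapse = "")
  )
}

#' @rdname aligned_family
#' @param x An `aligned_family`.
#' @export
n_sequences <- function(x) length(x$seq_ids)

is_gap <- function(chars) chars %in% GAP_CHARS

is_missing_char <- function(chars, alphabet = "AA") {
  chars %in% GAP_CHARS | chars == (if (alphabet == "AA") MISSING_AA else MISSING_DNA)
}

#' Read a gapped FASTA alignment
#'
#' Reads an aligned FASTA file into an [aligned_family]. Organism labels are
#' taken from an explicit two-column map (`seq_id`, `organism_id`) when
#' supplied; otherwise an optional regular expression with one capture group
#' is applied to each header; otherwise the full sequence id is used as the
#' organism id.
#'
#' @param path Path to an aligned FASTA file.
#' @param organism_map Optional path to a TSV with columns `seq_id` and
#'   `organism_id`, or a data frame with those columns.
#' @param family_name Family label; defaults to the file name sans extension.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param organism_regex Optional regex with one capture group applied to
#'   sequence ids to extract the organism id.
#'
#' @return An [aligned_family].
#' @export
read_alignment <- function(path, organism_map = NULL, family_name = NULL,
                           alphabet = c("AA", "DNA"), organism_regex = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "coevo_input_error")
  ss <- if (alphabet == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  if (length(ss) == 0L) abort("no sequences in file", class = "coevo_input_error")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  seqs <- as.character(ss)
  orgs <- resolve_organisms(ids, organism_map, organism_regex)
  if (is.null(family_name)) {
    family_name <- sub("\\.[^.]*$", "", basename(path))
  }
  aligned_family(ids, orgs, seqs, family_name = family_name, alphabet = alphabet)
}

resolve_organisms <- function(ids, organism_map, organism_regex) {
  if (!is.null(organism_map)) {
    map <- if (is.character(organism_map)) {
      readr::read_tsv(organism_map, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    } else {
      as_tibble(organism_map)
    }
    if (!all(c("seq_id", "organism_id") %in% names(map))) {
      abort("organism map needs columns seq_id and organism_id",
            class = "coevo_input_error")
    }
    idx <- match(ids, map$seq_id)
    if (anyNA(idx)) {
      abort(paste0("sequences missing from organism map: ",
                   paste(ids[is.na(idx)], collapse = ", ")),
            class = "coevo_crossref_error")
    }
    return(map$organism_id[idx])
  }
  if (!is.null(organism_regex)) {
    m <- regmatches(ids, regexec(organism_regex, ids))
    out <- vapply(m, function(g) if (length(g) >= 2L) g[[2L]] else NA_character_,
                  character(1))
    if (anyNA(out)) abort("organism_regex did not match all headers",
                          class = "coevo_input_error")
    return(out)
  }
  ids
}

#' Write an alignment back to FASTA
#'
#' @param fam An [aligned_family].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(fam, path) {
  seqs <- apply(fam$mat, 1L, paste, collapse = "")
  ss <- if (fam$alphabet == "AA") Biostrings::AAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  names(ss) <- fam$seq_ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Map alignment columns to ungapped reference coordinates
#'
#' `column_to_reference()` converts 1-based alignment column numbers into
#' 1-based residue numbers on the ungapped reference sequence (the numbering
#' convention used when reporting sites against a named reference such as a
#' rice paralog). Columns where the reference carries a gap map to `NA`.
#' `reference_to_column()` is the inverse for residue numbers.
#'
#' @param fam An [aligned_family].
#' @param reference_seq_id Sequence id of the reference.
#' @param column Integer vector of 1-based alignment columns.
#'
#' @return Integer vector of residue numbers (NA where the reference is
#'   gapped).
#' @export
column_to_reference <- function(fam, reference_seq_id, column) {
  row <- ref_row(fam, reference_seq_id)
  if (any(column < 1L | column > fam$n_cols)) {
    abort("column out of range", class = "coevo_input_error")
  }
  nongap <- !is_gap(row)
  pos <- cumsum(nongap)
  out <- pos[column]
  out[!nongap[column]] <- NA_integer_
  as.integer(out)
}

#' @rdname column_to_reference
#' @param residue Integer vector of 1-based residue numbers on the ungapped
#'   reference.
#' @export
reference_to_column <- function(fam, reference_seq_id, residue) {
  row <- ref_row(fam, reference_seq_id)
  cols <- which(!is_gap(row))
  if (any(residue < 1L | residue > length(cols))) {
    abort("residue out of range on reference", class = "coevo_input_error")
  }
  as.integer(cols[residue])
}

ref_row <- function(fam, reference_seq_id) {
  i <- match(reference_seq_id, fam$seq_ids)
  if (is.na(i)) abort(paste0("reference sequence not in alignment: ",
                             reference_seq_id),
                      class = "coevo_crossref_error")
  fam$mat[i, ]
}
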