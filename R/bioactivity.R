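#' Create a motif database of known bioactive peptides
#'
#' @param motifs Character vector of peptide sequences (length >= 2 each,
#'   20-letter alphabet). May be empty. Duplicates are collapsed with a
#'   warning.
#' @param activity_label Free-text activity the motifs share.
#' @param ic50_uM Optional per-motif IC50 (micromolar), recycled against
#'   `motifs` after deduplication only when lengths match.
#' @return An object of class `motif_db`.
#' @export
#' @examples
#' motif_db(c("IP", "VP", "FPL"), activity_label = "DPP-IV inhibitor")
motif_db <- function(motifs, activity_label = "DPP-IV inhibitor",
                     ic50_uM = NULL) {
  motifs <- vapply(as.character(motifs), validate_sequence, character(1),
                   USE.NAMES = FALSE)
  if (any(nchar(motifs) < 2L))
    stop("motifs must be at least 2 residues long", call. = FALSE)
  if (anyDuplicated(motifs)) {
    warning(sum(duplicated(motifs)), " duplicate motif(s) collapsed")
    keep <- !duplicated(motifs)
    motifs <- motifs[keep]
    if (!is.null(ic50_uM) && length(ic50_uM) == length(keep))
      ic50_uM <- ic50_uM[keep]
  }
  if (!is.null(ic50_uM) && length(ic50_uM) != length(motifs))
    ic50_uM <- NULL
  structure(list(motifs = motifs,
                 activity_label = as.character(activity_label),
                 ic50_uM = ic50_uM),
            class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  cat(sprintf("<motif_db> %d motifs [%s]\n", length(x$motifs),
              x$activity_label))
  invisible(x)
}

#' Load a motif database from a delimited table
#'
#' Expects columns `sequence`, `activity` and optionally `ic50_uM`. Rows
#' with invalid residues are rejected with an error listing their line
#' numbers; duplicate sequences are collapsed with a warning.
#'
#' @param path CSV (or TSV, by extension) file.
#' @return A [motif_db()].
#' @export
load_motif_db <- function(path) {
  tab <- read_table_auto(path)
  miss <- setdiff(c("sequence", "activity"), names(tab))
  if (length(miss) > 0L)
    stop("motif table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- vapply(tab$sequence, function(s)
    !inherits(try(validate_sequence(s), silent = TRUE), "try-error"),
    logical(1))
  if (!all(ok))
    stop("invalid motif sequence(s) at line(s): ",
         paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
  motif_db(tab$sequence,
           activity_label = tab$activity[1L],
           ic50_uM = if ("ic50_uM" %in% names(tab)) tab$ic50_uM)
}

## overlapping occurrence count of one motif in one sequence
.count_occurrences <- function(sequence, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

#' Frequency of bioactive fragment occurrence (A value)
#'
#' Computes A = a / N for a protein against a motif database, where `a` is
#' the number of database motifs found in the protein sequence and `N` is
#' the protein's total residue count. A higher A value marks the protein as
#' a more promising precursor of bioactive peptides.
#'
#' With `count = "occurrences"` (default, matching the theoretical-digestion
#' database convention) every — possibly overlapping — occurrence of every
#' motif contributes to `a`; with `count = "distinct_motifs"` each motif
#' present contributes once regardless of multiplicity.
#'
#' @param protein A [protein_record()] or sequence string.
#' @param motifs A [motif_db()].
#' @param count Occurrence-counting convention.
#' @return Non-negative rational A = a/N.
#' @export
#' @examples
#' a_value("IPIPI", motif_db(c("IP")))   # 2/5
a_value <- function(protein, motifs,
                    count = c("occurrences", "distinct_motifs")) {
  protein <- .as_protein(protein)
  stopifnot(inherits(motifs, "motif_db"))
  count <- match.arg(count)
  occ <- vapply(motifs$motifs, .count_occurrences,
                integer(1), sequence = protein$sequence)
  a <- if (count == "occurrences") sum(occ) else sum(occ > 0L)
  a / protein$length
}
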