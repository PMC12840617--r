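#' Read proteins from a FASTA file
#'
#' @param path FASTA file (single-line or wrapped sequences).
#' @return List of [protein_record()]s; ids are the FASTA names.
#' @export
read_fasta_proteins <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  lapply(names(recs), function(nm)
    protein_record(nm, as.character(recs[[nm]]),
                   source = attr(recs[[nm]], "Annot")))
}

#' Write proteins or peptides to a FASTA file
#'
#' @param records List of [protein_record()]s, or a named character vector
#'   of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_proteins <- function(records, path) {
  if (is.character(records)) {
    seqs <- as.list(records)
    ids <- names(records) %||% paste0("seq_", seq_along(records))
  } else {
    seqs <- lapply(records, `[[`, "sequence")
    ids <- vapply(records, `[[`, character(1), "id")
  }
  seqinr::write.fasta(seqs, names = ids, file.out = path, as.string = TRUE)
  invisible(path)
}

#' Read a delimited table, dialect by extension
#'
#' Comma-separated by default; tab-separated for `.tsv`/`.tab`/`.txt`.
#' A header row is mandatory; CRLF input is handled transparently.
#'
#' @param path Input file.
#' @param required Optional character vector of required columns; a schema
#'   mismatch raises an error listing what is missing.
#' @return Data frame.
#' @export
read_table_auto <- function(path, required = NULL) {
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t"
         else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(tab))
    if (length(miss) > 0L)
      stop("table ", path, " missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a delimited table, dialect by extension
#'
#' @param x Data frame.
#' @param path Output file (`.tsv`/`.tab`/`.txt` write tab-separated).
#' @return `path`, invisibly.
#' @export
write_table_auto <- function(x, path) {
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t"
         else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable JSON report
#'
#' @param x Named list.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
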