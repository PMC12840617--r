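#' The 20 standard amino acids
#'
#' One-letter codes of the 20 proteinogenic amino acids, alphabetically
#' ordered. This ordering fixes the layout of the first 20 components of the
#' PseAAC feature vector (see [featurize()]).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## Split a sequence into residues, validating against the 20-letter alphabet.
## Ambiguity/non-standard codes (B, J, O, U, X, Z) are rejected outright.
.residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), amino_acids())
  if (length(bad) > 0L)
    stop("invalid residue(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  res
}

#' Validate a peptide or protein sequence
#'
#' Checks that a sequence is a non-empty string over the 20 standard
#' one-letter amino acid codes. B, J, O, U, X and Z are rejected.
#'
#' @param sequence Character scalar.
#' @return The validated (upper-cased) sequence, invisibly usable.
#' @export
validate_sequence <- function(sequence) {
  paste(.residues(sequence), collapse = "")
}

.validate_residue_set <- function(set, what = "residue set") {
  if (length(set) == 0L) return(character(0))
  set <- toupper(as.character(set))
  bad <- setdiff(set, amino_acids())
  if (length(bad) > 0L)
    stop("invalid residue(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  unique(set)
}

#' Create a protein record
#'
#' A validated protein sequence with an identifier and free-text source,
#' the substrate of [digest()] and [a_value()].
#'
#' @param id Text identifier.
#' @param sequence Amino-acid sequence (20-letter alphabet).
#' @param source Optional free-text provenance.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `source` and `length` (total residue count, the `N` of the A-value).
#' @export
#' @examples
#' protein_record("hba1", "VLSAADKSNVKAA")
protein_record <- function(id, sequence, source = "") {
  sequence <- validate_sequence(sequence)
  structure(
    list(id = as.character(id), sequence = sequence,
         source = as.character(source), length = nchar(sequence)),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, x$length,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

.as_protein <- function(x) {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(protein_record(id = "protein", sequence = x))
  stop("expected a protein_record or a single sequence string", call. = FALSE)
}

#' Default physicochemical property scales
#'
#' Per-residue tables for the six properties used by the PseAAC featurizer:
#' hydrophobicity (Kyte-Doolittle hydropathy), hydrophilicity (Hopp-Woods),
#' residue mass (free amino-acid average molecular weight, Da), pK1
#' (alpha-carboxyl), pK2 (alpha-amino) and isoelectric point pI.
#'
#' Values are the standard free-amino-acid tables; any of them can be
#' replaced by supplying a scales data frame of the same shape (see
#' [read_scales()]).
#'
#' @return A data frame with 20 rows (one per residue, alphabetical) and
#'   columns `residue`, `hydrophobicity`, `hydrophilicity`, `mass`, `pk1`,
#'   `pk2`, `pi`.
#' @export
#' @examples
#' head(default_scales())
default_scales <- function() {
  data.frame(
    residue = amino_acids(),
    hydrophobicity = c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9,
                       3.8, 1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2,
                       -0.9, -1.3),
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0,
                       -1.8, -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5,
                       -3.4, -2.3),
    mass = c(89.09, 121.16, 133.10, 147.13, 165.19, 75.07, 155.16, 131.17,
             146.19, 131.17, 149.21, 132.12, 115.13, 146.15, 174.20,
             105.09, 119.12, 117.15, 204.23, 181.19),
    pk1 = c(2.34, 1.96, 1.88, 2.19, 1.83, 2.34, 1.82, 2.36, 2.18, 2.36,
            2.28, 2.02, 1.99, 2.17, 2.17, 2.21, 2.11, 2.32, 2.38, 2.20),
    pk2 = c(9.69, 10.28, 9.60, 9.67, 9.13, 9.60, 9.17, 9.60, 8.95, 9.60,
            9.21, 8.80, 10.60, 9.13, 9.04, 9.15, 9.62, 9.62, 9.39, 9.11),
    pi = c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
           5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.60, 5.96, 5.89, 5.66),
    stringsAsFactors = FALSE)
}

.validate_scales <- function(scales) {
  needed <- c("residue", "hydrophobicity", "hydrophilicity", "mass",
              "pk1", "pk2", "pi")
  miss <- setdiff(needed, names(scales))
  if (length(miss) > 0L)
    stop("scales table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  scales$residue <- toupper(scales$residue)
  if (!setequal(scales$residue, amino_acids()) ||
      nrow(scales) != 20L)
    stop("scales table must cover exactly the 20 standard residues",
         call. = FALSE)
  scales <- scales[match(amino_acids(), scales$residue), needed]
  for (col in needed[-1L])
    if (!is.numeric(scales[[col]]) || anyNA(scales[[col]]))
      stop("scales column '", col, "' must be numeric and complete",
           call. = FALSE)
  rownames(scales) <- scales$residue
  scales
}

#' Read a property-scales table from CSV
#'
#' @param path CSV with header
#'   `residue,hydrophobicity,hydrophilicity,mass,pk1,pk2,pi` and 20 rows.
#' @return Validated scales data frame ordered alphabetically by residue.
#' @export
read_scales <- function(path) {
  .validate_scales(utils::read.csv(path, stringsAsFactors = FALSE))
}
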