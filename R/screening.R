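#' Peptidomics screening criteria
#'
#' The multi-criteria filter applied to identified peptide tables:
#' relative abundance strictly above `min_abundance`, chain length strictly
#' below `max_length` residues, external bioactivity score strictly above
#' `min_score`, and the DPP-IV substrate-motif rule — Pro or Ala at the
#' second position from the N-terminus. All inequalities are strict.
#'
#' @param min_abundance Relative abundance threshold (default 1e7).
#' @param max_length Length threshold in residues (default 10).
#' @param min_score External bioactivity score threshold (default 0.9).
#' @param position2_residues Allowed position-2 residues (default P, A).
#' @return Object of class `screening_criteria`.
#' @export
screening_criteria <- function(min_abundance = 1e7, max_length = 10L,
                               min_score = 0.9,
                               position2_residues = c("P", "A")) {
  if (min_abundance <= 0 || max_length <= 0 || min_score <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(
    list(min_abundance = min_abundance,
         max_length = as.integer(max_length),
         min_score = min_score,
         position2_residues = .validate_residue_set(position2_residues)),
    class = "screening_criteria")
}

#' @export
print.screening_criteria <- function(x, ...) {
  cat(sprintf(
    "<screening_criteria> abundance > %g, length < %d, score > %g, position 2 in {%s}\n",
    x$min_abundance, x$max_length, x$min_score,
    paste(x$position2_residues, collapse = ", ")))
  invisible(x)
}

#' DPP-IV position-2 substrate rule
#'
#' DPP-IV preferentially cleaves (and is inhibited by) peptides carrying
#' Pro or Ala at the second position from the N-terminus. For dipeptides
#' the C-terminal residue is position 2 (consistent with the enzyme's
#' Xaa-Pro dipeptidase definition); single residues always fail.
#'
#' @param sequence Amino-acid string.
#' @param allowed Allowed residue set at position 2 (default P, A).
#' @return Logical.
#' @export
#' @examples
#' position2_rule("FPL")  # TRUE
#' position2_rule("YW")   # FALSE
position2_rule <- function(sequence, allowed = c("P", "A")) {
  res <- .residues(sequence)
  allowed <- .validate_residue_set(allowed, "allowed")
  if (length(res) < 2L) return(FALSE)
  res[2L] %in% allowed
}

#' Apply the peptidomics screening criteria
#'
#' A row survives iff it passes all four criteria; rejected rows are
#' attributed to the first criterion they fail, in the stated order
#' (abundance, length, score, position 2). Input order is preserved.
#'
#' @param rows Data frame with columns `sequence`, `abundance`, `score`
#'   (additional columns are carried through).
#' @param criteria A [screening_criteria()].
#' @return List with `survivors` (data frame) and `rejections` (named
#'   integer vector of per-criterion counts).
#' @export
#' @examples
#' tab <- data.frame(sequence = c("FPL", "YW"),
#'                   abundance = c(2.27e7, 5e8), score = c(0.979, 0.95))
#' apply_filters(tab, screening_criteria())
apply_filters <- function(rows, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  miss <- setdiff(c("sequence", "abundance", "score"), names(rows))
  if (length(miss) > 0L)
    stop("candidate table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(rows$abundance < 0)) stop("abundance must be >= 0", call. = FALSE)
  if (any(rows$score < 0 | rows$score > 1))
    stop("score must be in [0, 1]", call. = FALSE)

  pass_abundance <- rows$abundance > criteria$min_abundance
  pass_length <- nchar(rows$sequence) < criteria$max_length
  pass_score <- rows$score > criteria$min_score
  pass_pos2 <- vapply(rows$sequence, position2_rule, logical(1),
                      allowed = criteria$position2_residues)

  survivors <- pass_abundance & pass_length & pass_score & pass_pos2
  first_fail <- rep(NA_character_, nrow(rows))
  first_fail[!pass_pos2] <- "position2"
  first_fail[!pass_score] <- "score"
  first_fail[!pass_length] <- "length"
  first_fail[!pass_abundance] <- "abundance"

  rejections <- c(abundance = sum(first_fail == "abundance", na.rm = TRUE),
                  length = sum(first_fail == "length", na.rm = TRUE),
                  score = sum(first_fail == "score", na.rm = TRUE),
                  position2 = sum(first_fail == "position2", na.rm = TRUE))

  out <- rows[survivors, , drop = FALSE]
  rownames(out) <- NULL
  list(survivors = out, rejections = rejections)
}

#' Rank candidate rows by ordered sort keys
#'
#' Stable lexicographic sort on the named columns, descending by default;
#' ties preserve input order.
#'
#' @param rows Data frame.
#' @param keys Ordered character vector of column names.
#' @param descending Logical, sort direction (recycled over keys).
#' @return The reordered data frame.
#' @export
rank_candidates <- function(rows, keys, descending = TRUE) {
  miss <- setdiff(keys, names(rows))
  if (length(miss) > 0L)
    stop("missing sort key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  descending <- rep_len(descending, length(keys))
  cols <- lapply(seq_along(keys), function(i) {
    v <- rows[[keys[i]]]
    if (is.character(v)) v <- xtfrm(v)
    if (descending[i]) -v else v
  })
  ord <- do.call(order, c(cols, list(seq_len(nrow(rows)))))
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
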