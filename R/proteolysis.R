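#' Define a protease cleavage rule
#'
#' A protease's site specificity is expressed through two residue sets: the
#' bond after residue `i` is cut when residue `i` is in `c_terminal_of` or
#' residue `i + 1` is in `n_terminal_of`, unless residue `i + 1` is in
#' `blocked_p1prime` (a veto on the P1' position used to express classic
#' exceptions such as "no cut before proline").
#'
#' @param enzyme_name Text name.
#' @param c_terminal_of Residues after which the bond is cut (P1 side).
#' @param n_terminal_of Residues before which the bond is cut (P1' side).
#' @param blocked_p1prime Residues that veto a cut when immediately
#'   following the site. May be empty.
#' @return An object of class `cleavage_rule`.
#' @export
#' @examples
#' trypsin <- cleavage_rule("trypsin", c_terminal_of = c("H", "K", "R"))
#' find_cleavage_sites("FPHFDL", trypsin)
cleavage_rule <- function(enzyme_name, c_terminal_of = character(0),
                          n_terminal_of = character(0),
                          blocked_p1prime = character(0)) {
  c_terminal_of <- .validate_residue_set(c_terminal_of, "c_terminal_of")
  n_terminal_of <- .validate_residue_set(n_terminal_of, "n_terminal_of")
  blocked_p1prime <- .validate_residue_set(blocked_p1prime, "blocked_p1prime")
  if (length(c_terminal_of) == 0L && length(n_terminal_of) == 0L)
    stop("at least one of c_terminal_of / n_terminal_of must be non-empty",
         call. = FALSE)
  structure(
    list(enzyme_name = as.character(enzyme_name),
         c_terminal_of = c_terminal_of,
         n_terminal_of = n_terminal_of,
         blocked_p1prime = blocked_p1prime),
    class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = "") else "-"
  cat(sprintf("<cleavage_rule> %s: C-term of [%s], N-term of [%s], P1' block [%s]\n",
              x$enzyme_name, fmt(x$c_terminal_of), fmt(x$n_terminal_of),
              fmt(x$blocked_p1prime)))
  invisible(x)
}

#' Built-in protease rules
#'
#' The default registry ships four proteases. Pepsin cuts C-terminally of
#' Phe/Ile/Tyr/Trp and N-terminally of Met/Glu/Leu/Phe; trypsin cuts after
#' the basic residues His/Lys/Arg; chymotrypsin after the aromatic residues
#' Phe/Tyr/Trp; bromelain between hydrophobic and basic residues (a cut
#' after a hydrophobic residue only when the next residue is basic, encoded
#' through the P1' veto). Additional enzymes can be loaded from a YAML
#' registry with [read_enzyme_rules()].
#'
#' With `classic_exceptions = TRUE`, trypsin and chymotrypsin carry the
#' textbook "no cut before proline" veto (and trypsin drops the
#' non-canonical His site). The default is the plain rule set.
#'
#' @param name Optional enzyme name; if missing, the full named list.
#' @param classic_exceptions Use the proline-veto variants.
#' @return A `cleavage_rule`, or a named list of them.
#' @export
#' @examples
#' default_enzymes("pepsin")
#' names(default_enzymes())
default_enzymes <- function(name = NULL, classic_exceptions = FALSE) {
  hydrophobic <- c("A", "V", "L", "I", "P", "F", "M", "W", "G")
  basic <- c("H", "K", "R")
  rules <- list(
    pepsin = cleavage_rule("pepsin",
                           c_terminal_of = c("F", "I", "Y", "W"),
                           n_terminal_of = c("M", "E", "L", "F")),
    trypsin = cleavage_rule("trypsin", c_terminal_of = c("H", "K", "R")),
    chymotrypsin = cleavage_rule("chymotrypsin",
                                 c_terminal_of = c("F", "Y", "W")),
    bromelain = cleavage_rule("bromelain",
                              c_terminal_of = hydrophobic,
                              blocked_p1prime = setdiff(amino_acids(), basic)))
  if (classic_exceptions) {
    rules$trypsin <- cleavage_rule("trypsin",
                                   c_terminal_of = c("K", "R"),
                                   blocked_p1prime = "P")
    rules$chymotrypsin <- cleavage_rule("chymotrypsin",
                                        c_terminal_of = c("F", "Y", "W"),
                                        blocked_p1prime = "P")
  }
  if (is.null(name)) return(rules)
  name <- tolower(name)
  if (!name %in% names(rules))
    stop("unknown enzyme '", name, "'; built-ins: ",
         paste(names(rules), collapse = ", "), call. = FALSE)
  rules[[name]]
}

#' Read a protease rule registry from YAML
#'
#' The registry is a mapping of enzyme name to the fields of
#' [cleavage_rule()], so site specificities (for instance the 30-enzyme
#' panel of a theoretical-digestion database) can be added without code
#' changes. A template ships in `inst/extdata/enzymes.yaml`.
#'
#' @param path YAML file.
#' @return Named list of `cleavage_rule` objects.
#' @export
read_enzyme_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop("enzyme registry must be a named mapping", call. = FALSE)
  ## unquoted Y/N/T/F parse as YAML booleans, which cannot be mapped back
  ## to a residue unambiguously
  unbool <- function(x) {
    x <- unlist(x)
    if (is.null(x)) return(character(0))
    if (any(is.logical(x)))
      stop("residue letters in the registry must be quoted ",
           "(unquoted Y/N/T/F parse as YAML booleans)", call. = FALSE)
    as.character(x)
  }
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    cleavage_rule(nm,
                  c_terminal_of = unbool(entry$c_terminal_of),
                  n_terminal_of = unbool(entry$n_terminal_of),
                  blocked_p1prime = unbool(entry$blocked_p1prime))
  })
  names(out) <- names(raw)
  out
}

.as_rule <- function(rule) {
  if (inherits(rule, "cleavage_rule")) return(rule)
  if (is.character(rule) && length(rule) == 1L) return(default_enzymes(rule))
  stop("expected a cleavage_rule or a built-in enzyme name", call. = FALSE)
}

#' Find cleavage sites in a sequence
#'
#' Scans every peptide bond and returns the 1-based positions after which
#' the rule cuts: position `i` is a site iff residue `i` is in the rule's
#' `c_terminal_of` set or residue `i + 1` is in its `n_terminal_of` set,
#' and residue `i + 1` is not vetoed by `blocked_p1prime`.
#'
#' @param sequence Amino-acid string.
#' @param rule A [cleavage_rule()] or built-in enzyme name.
#' @return Strictly increasing integer vector of cut positions in
#'   `[1, nchar(sequence) - 1]`.
#' @export
#' @examples
#' find_cleavage_sites("FPHFDL", "trypsin")  # cut after His3
#' find_cleavage_sites("FPHFDL", "pepsin")
find_cleavage_sites <- function(sequence, rule) {
  rule <- .as_rule(rule)
  res <- .residues(sequence)
  n <- length(res)
  if (n < 2L) return(integer(0))
  p1 <- res[-n]       # residue i
  p1p <- res[-1L]     # residue i + 1
  hit <- (p1 %in% rule$c_terminal_of) | (p1p %in% rule$n_terminal_of)
  hit <- hit & !(p1p %in% rule$blocked_p1prime)
  which(hit)
}

.make_peptides <- function(parent_seq, parent_id, starts, ends) {
  data.frame(
    sequence = substring(parent_seq, starts, ends),
    parent_id = parent_id,
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    stringsAsFactors = FALSE)
}

#' Digest a protein with a cleavage rule
#'
#' Theoretical digestion cuts at every site (`missed_cleavages = 0`), so the
#' fragments partition the parent sequence. With `missed_cleavages = k`,
#' every run of at most `k + 1` consecutive fully-cleaved fragments is also
#' enumerated, expressing partial-digestion products. Fragments shorter than
#' `min_length` are dropped after enumeration.
#'
#' @param protein A [protein_record()] or sequence string.
#' @param rule A [cleavage_rule()] or built-in enzyme name.
#' @param missed_cleavages Non-negative integer.
#' @param min_length Positive integer, minimum fragment length to keep.
#' @return Data frame of peptides with columns `sequence`, `parent_id`,
#'   `start`, `end`, `length` (1-based inclusive coordinates). Duplicate
#'   sequences from different positions are distinct rows.
#' @export
#' @examples
#' digest("FPHFDL", "trypsin")               # FPH + FDL
#' digest("FPHFDL", "pepsin", missed_cleavages = 3)
digest <- function(protein, rule, missed_cleavages = 0L, min_length = 1L) {
  protein <- .as_protein(protein)
  rule <- .as_rule(rule)
  missed_cleavages <- as.integer(missed_cleavages)
  min_length <- as.integer(min_length)
  if (is.na(missed_cleavages) || missed_cleavages < 0L)
    stop("missed_cleavages must be a non-negative integer", call. = FALSE)
  if (is.na(min_length) || min_length < 1L)
    stop("min_length must be a positive integer", call. = FALSE)

  sites <- find_cleavage_sites(protein$sequence, rule)
  bounds <- c(0L, sites, protein$length)   # fragment j spans bounds[j]+1 .. bounds[j+1]
  nfrag <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0)
  for (mc in 0:min(missed_cleavages, nfrag - 1L)) {
    j <- seq_len(nfrag - mc)
    starts <- c(starts, bounds[j] + 1L)
    ends <- c(ends, bounds[j + 1L + mc])
  }
  out <- .make_peptides(protein$sequence, protein$id, starts, ends)
  out <- out[out$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## All fragments delimited by two cleavage boundaries (partial-digestion
## intermediates), including the intact input: the enumeration behind
## sequential_digest() when missed cleavages are allowed.
.all_spans <- function(sequence, sites) {
  n <- nchar(sequence)
  bounds <- c(0L, sites, n)
  k <- length(bounds)
  out <- character(0)
  for (i in seq_len(k - 1L))
    out <- c(out, substring(sequence, bounds[i] + 1L, bounds[(i + 1L):k]))
  unique(out)
}

#' Sequential (gastric then intestinal) digestion
#'
#' Models two-phase gastrointestinal digestion: the stage-1 rules (gastric,
#' typically pepsin) are applied to the input, then the stage-2 rules
#' (intestinal, typically trypsin plus chymotrypsin) are applied to every
#' stage-1 product. Rules within a stage act together (their site sets are
#' pooled, as the enzymes are co-incubated).
#'
#' With `missed_cleavages = 0` digestion is complete and only terminal
#' fragments are returned. With `missed_cleavages > 0` digestion is
#' incomplete: every partial-digestion intermediate (any fragment delimited
#' by two cleavage boundaries, including the undigested input) may survive
#' a phase, so the returned set is the union of terminal fragments and all
#' surviving intermediates of both stages.
#'
#' @param peptide Sequence string (or [protein_record()]).
#' @param stage1_rules List of [cleavage_rule()]s (or names) for the
#'   gastric phase.
#' @param stage2_rules List of rules for the intestinal phase.
#' @param missed_cleavages Non-negative integer.
#' @param min_length Minimum fragment length to report.
#' @return Character vector of unique fragment sequences (sorted).
#' @export
#' @examples
#' sequential_digest("FPHFDL")   # pepsin, then trypsin + chymotrypsin
#' sequential_digest("FPL", missed_cleavages = 0)
sequential_digest <- function(peptide,
                              stage1_rules = list("pepsin"),
                              stage2_rules = list("trypsin", "chymotrypsin"),
                              missed_cleavages = 1L, min_length = 1L) {
  protein <- .as_protein(peptide)
  missed_cleavages <- as.integer(missed_cleavages)
  if (is.na(missed_cleavages) || missed_cleavages < 0L)
    stop("missed_cleavages must be a non-negative integer", call. = FALSE)
  stage1_rules <- lapply(stage1_rules, .as_rule)
  stage2_rules <- lapply(stage2_rules, .as_rule)

  pooled_sites <- function(sequence, rules)
    sort(unique(unlist(lapply(rules, function(r)
      find_cleavage_sites(sequence, r)))))

  stage_products <- function(sequence, rules) {
    sites <- pooled_sites(sequence, rules)
    if (missed_cleavages == 0L) {
      bounds <- c(0L, sites, nchar(sequence))
      substring(sequence, bounds[-length(bounds)] + 1L, bounds[-1L])
    } else {
      .all_spans(sequence, sites)
    }
  }

  stage1 <- unique(unlist(lapply(protein$sequence, stage_products,
                                 rules = stage1_rules)))
  stage2 <- unique(unlist(lapply(stage1, stage_products,
                                 rules = stage2_rules)))
  out <- unique(c(if (missed_cleavages > 0L) stage1, stage2))
  sort(out[nchar(out) >= min_length])
}

#' Count bioactive fragments released by a protease
#'
#' Digests the protein to completion (`missed_cleavages = 0`) and counts
#' how many released fragments occur in the motif database; each released
#' fragment occurrence counts, so the same motif released from two loci
#' counts twice. Ranking proteases by this count identifies the enzyme
#' predicted to liberate the most known bioactive peptides.
#'
#' @param protein A [protein_record()] or sequence string.
#' @param rule A [cleavage_rule()] or built-in enzyme name.
#' @param motifs A [motif_db()].
#' @return Non-negative integer count.
#' @export
#' @examples
#' db <- motif_db(c("FPH", "FDL"))
#' count_released_bioactive("FPHFDL", "trypsin", db)
count_released_bioactive <- function(protein, rule, motifs) {
  stopifnot(inherits(motifs, "motif_db"))
  frags <- digest(protein, rule, missed_cleavages = 0L)
  sum(frags$sequence %in% motifs$motifs)
}
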