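#' Pipeline configuration
#'
#' Bundles the settings of every stage of [run_pipeline()]. Can be built
#' directly or loaded from a YAML file with [read_pipeline_config()].
#'
#' @param enzyme Protease for the digestion stage (built-in name or
#'   [cleavage_rule()]).
#' @param missed_cleavages,min_length Digestion settings.
#' @param criteria A [screening_criteria()].
#' @param algorithm,grid,seed,confidence Classifier settings; `confidence`
#'   is the high-confidence probability cutoff.
#' @param w,scales Featurization settings.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(enzyme = "bromelain", missed_cleavages = 0L,
                            min_length = 2L,
                            criteria = screening_criteria(),
                            algorithm = "lightgbm",
                            grid = data.frame(max_depth = 4L, eta = 0.1,
                                              nrounds = 100L),
                            seed = 1L, confidence = 0.9, w = 0.05,
                            scales = default_scales()) {
  structure(list(enzyme = enzyme,
                 missed_cleavages = as.integer(missed_cleavages),
                 min_length = as.integer(min_length),
                 criteria = criteria, algorithm = algorithm, grid = grid,
                 seed = as.integer(seed), confidence = confidence, w = w,
                 scales = .validate_scales(scales)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `enzyme`, `missed_cleavages`, `min_length`,
#' `algorithm`, `seed`, `confidence`, `w`, plus a `criteria` mapping with
#' `min_abundance`, `max_length`, `min_score`, `position2_residues` and an
#' optional `scales` path. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("enzyme", "missed_cleavages", "min_length", "algorithm",
             "seed", "confidence", "w", "criteria", "scales")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  crit <- if (is.null(raw$criteria)) screening_criteria()
          else do.call(screening_criteria, raw$criteria)
  args <- raw[setdiff(names(raw), c("criteria", "scales"))]
  args$criteria <- crit
  if (!is.null(raw$scales)) args$scales <- read_scales(raw$scales)
  do.call(pipeline_config, args)
}

#' Run the discovery pipeline end to end
#'
#' Executes the computational stages of the screening strategy in order:
#' digest the precursor proteins, score candidate fragments with a trained
#' activity classifier, apply the peptidomics screening criteria, and rank
#' the survivors. Every stage's candidate count, the seed and the
#' configuration are recorded in the returned report, and the run is
#' deterministic given identical inputs.
#'
#' Fragment abundance and external bioactivity score are taken from
#' `candidates` when supplied (matched by sequence); otherwise screening
#' operates on the digestion products with the classifier probability
#' only, skipping the abundance/score criteria it cannot evaluate.
#'
#' @param proteins List of [protein_record()]s (or a FASTA path).
#' @param model A fitted [dppiv_classifier()] (or a labeled training table
#'   from which one is fitted under the config's settings).
#' @param config A [pipeline_config()].
#' @param candidates Optional peptidomics table with `sequence`,
#'   `abundance`, `score`.
#' @return Object of class `pipeline_report`: `candidates` (final ranked
#'   table), `counts` (per-stage), `rejections`, `config`, `seed`.
#' @export
run_pipeline <- function(proteins, model, config = pipeline_config(),
                         candidates = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- read_fasta_proteins(proteins)
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  if (is.data.frame(model))
    model <- dppiv_classifier(model, algorithm = config$algorithm,
                              grid = config$grid, seed = config$seed,
                              w = config$w, scales = config$scales)
  stopifnot(inherits(model, "dppiv_classifier"))

  ## 1. digestion
  frags <- do.call(rbind, lapply(proteins, digest, rule = config$enzyme,
                                 missed_cleavages = config$missed_cleavages,
                                 min_length = config$min_length))
  n_frag <- nrow(frags)
  tab <- frags[!duplicated(frags$sequence), , drop = FALSE]

  ## 2. classifier scoring
  pred <- predict_candidates(model, tab$sequence,
                             threshold = config$confidence)
  tab$probability <- pred$probability
  tab$high_confidence <- pred$high_confidence
  tab <- tab[!is.na(tab$probability) & tab$high_confidence, , drop = FALSE]
  n_scored <- nrow(tab)

  ## 3. screening
  if (!is.null(candidates)) {
    idx <- match(tab$sequence, candidates$sequence)
    tab$abundance <- candidates$abundance[idx]
    tab$score <- candidates$score[idx]
    tab <- tab[!is.na(tab$abundance) & !is.na(tab$score), , drop = FALSE]
    screened <- apply_filters(tab, config$criteria)
  } else {
    keep <- vapply(tab$sequence, position2_rule, logical(1),
                   allowed = config$criteria$position2_residues) &
      nchar(tab$sequence) < config$criteria$max_length
    screened <- list(survivors = tab[keep, , drop = FALSE],
                     rejections = c(length = sum(
                       nchar(tab$sequence) >= config$criteria$max_length),
                       position2 = sum(!vapply(tab$sequence, position2_rule,
                                               logical(1)))))
  }

  ## 4. ranking
  final <- rank_candidates(screened$survivors, keys = "probability")
  structure(
    list(candidates = final,
         counts = c(fragments = n_frag,
                    unique_fragments = nrow(pred),
                    high_confidence = n_scored,
                    screened = nrow(screened$survivors)),
         rejections = screened$rejections,
         config = config, seed = config$seed),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-18s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  final candidates: %d (seed %d)\n",
              nrow(x$candidates), x$seed))
  invisible(x)
}

#' Write a pipeline report to JSON and TSV
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table_auto(report$candidates, file.path(dir, "candidates.tsv"))
  write_report_json(
    list(counts = as.list(report$counts),
         rejections = as.list(report$rejections),
         seed = report$seed,
         enzyme = if (is.character(report$config$enzyme))
           report$config$enzyme else report$config$enzyme$enzyme_name,
         confidence = report$config$confidence),
    file.path(dir, "report.json"))
  invisible(dir)
}
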