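## Hydrophobic residue set used by the generators (documented choice; the
## field's "hydrophobic amino acid" lists vary at the margins)
.hydrophobic_set <- c("A", "V", "L", "I", "P", "F", "M", "W", "G")

## run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Sequence-activity structure of the synthetic training sets
#'
#' Parameters of the generative model behind [gen_labeled_peptides()]:
#' active peptides are enriched for Pro/Ala at position 2 from the
#' N-terminus and for hydrophobic residues at both termini — the two
#' structural signatures of DPP-IV inhibitory peptides — and their IC50
#' values are drawn from a class-specific lognormal kept consistent with
#' the 2000 uM activity threshold.
#'
#' @param p_pro2_active,p_pro2_inactive Probability of Pro/Ala at position
#'   2 per class (defaults 0.7 / 0.2).
#' @param p_hydrophobic_terminal_active,p_hydrophobic_terminal_inactive
#'   Probability that each terminus is hydrophobic, per class.
#' @param length_range Residue-count range (default 2-8, the typical
#'   length of potent inhibitors).
#' @param active_meanlog,active_sdlog Lognormal IC50 parameters for
#'   actives (mode below 2000 uM).
#' @param inactive_meanlog,inactive_sdlog Lognormal IC50 parameters for
#'   inactives (mode at or above 2000 uM).
#' @return Object of class `activity_model`.
#' @export
activity_model <- function(p_pro2_active = 0.7, p_pro2_inactive = 0.2,
                           p_hydrophobic_terminal_active = 0.8,
                           p_hydrophobic_terminal_inactive = 0.4,
                           length_range = c(2L, 8L),
                           active_meanlog = log(200), active_sdlog = 1.2,
                           inactive_meanlog = log(6000),
                           inactive_sdlog = 0.6) {
  probs <- c(p_pro2_active, p_pro2_inactive,
             p_hydrophobic_terminal_active,
             p_hydrophobic_terminal_inactive)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (length_range[1L] < 2L || length_range[2L] < length_range[1L])
    stop("length_range must be increasing and start at >= 2", call. = FALSE)
  if (active_sdlog < 0 || inactive_sdlog < 0)
    stop("sdlog parameters must be >= 0", call. = FALSE)
  if (exp(active_meanlog) >= 2000 && active_sdlog == 0)
    stop("impossible model: active IC50 mode at/above the 2000 uM ",
         "threshold with zero variance", call. = FALSE)
  if (stats::plnorm(2000, active_meanlog, max(active_sdlog, 1e-12)) < 0.5)
    stop("impossible model: active IC50 mass predominantly above the ",
         "2000 uM threshold", call. = FALSE)
  structure(list(p_pro2_active = p_pro2_active,
                 p_pro2_inactive = p_pro2_inactive,
                 p_hydrophobic_terminal_active =
                   p_hydrophobic_terminal_active,
                 p_hydrophobic_terminal_inactive =
                   p_hydrophobic_terminal_inactive,
                 length_range = as.integer(length_range),
                 active_meanlog = active_meanlog,
                 active_sdlog = active_sdlog,
                 inactive_meanlog = inactive_meanlog,
                 inactive_sdlog = inactive_sdlog),
            class = "activity_model")
}

## position 2 is assigned last so its enrichment probability is exact even
## for dipeptides, where position 2 is also the C-terminus
.gen_sequence <- function(p_pro2, p_hydrophobic_terminal, length_range) {
  L <- sample(length_range[1L]:length_range[2L], 1L)
  res <- sample(amino_acids(), L, replace = TRUE)
  if (stats::runif(1) < p_hydrophobic_terminal)
    res[1L] <- sample(.hydrophobic_set, 1L)
  if (stats::runif(1) < p_hydrophobic_terminal)
    res[L] <- sample(.hydrophobic_set, 1L)
  if (stats::runif(1) < p_pro2)
    res[2L] <- sample(c("P", "A"), 1L)
  else
    res[2L] <- sample(setdiff(amino_acids(), c("P", "A")), 1L)
  paste(res, collapse = "")
}

.gen_ic50 <- function(n, meanlog, sdlog, below_threshold,
                      threshold = 2000) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(n, meanlog, sdlog)
    keep <- if (below_threshold) draw < threshold else draw >= threshold
    out <- c(out, draw[keep])
  }
  out[seq_len(n)]
}

#' Generate a labeled peptide training set
#'
#' Draws `n_active` + `n_inactive` peptides under an [activity_model()]:
#' class-specific position-2 Pro/Ala enrichment, hydrophobic-termini
#' enrichment, and class-consistent lognormal IC50 values (actives strictly
#' below 2000 uM, inactives at or above). Reproducible given the seed and
#' leaves the caller's RNG stream untouched.
#'
#' @param n_active,n_inactive Class sizes (defaults 588 / 210, the typical
#'   curated-set proportions).
#' @param model An [activity_model()].
#' @param seed Integer seed.
#' @return Data frame `sequence`, `ic50_uM`, `label` with exact class
#'   counts (actives first).
#' @export
#' @examples
#' head(gen_labeled_peptides(10, 5, seed = 1))
gen_labeled_peptides <- function(n_active = 588L, n_inactive = 210L,
                                 model = activity_model(), seed = 1L) {
  stopifnot(inherits(model, "activity_model"))
  if (n_active < 0 || n_inactive < 0)
    stop("class sizes must be >= 0", call. = FALSE)
  .with_seed(seed, {
    act <- vapply(seq_len(n_active), function(i)
      .gen_sequence(model$p_pro2_active,
                    model$p_hydrophobic_terminal_active,
                    model$length_range), character(1))
    inact <- vapply(seq_len(n_inactive), function(i)
      .gen_sequence(model$p_pro2_inactive,
                    model$p_hydrophobic_terminal_inactive,
                    model$length_range), character(1))
    data.frame(
      sequence = c(act, inact),
      ic50_uM = c(.gen_ic50(n_active, model$active_meanlog,
                            model$active_sdlog, TRUE),
                  .gen_ic50(n_inactive, model$inactive_meanlog,
                            model$inactive_sdlog, FALSE)),
      label = rep(c(1L, 0L), c(n_active, n_inactive)),
      stringsAsFactors = FALSE)
  })
}

#' Generate a kinetics dataset
#'
#' Simulates initial velocities on a substrate-by-inhibitor design under
#' one of the [kinetic_models()], with multiplicative lognormal noise of
#' coefficient of variation `cv` (mean-one noise; `cv = 0` is exact). The
#' default design mirrors a typical inhibition assay: substrate 0.025-0.4
#' (assay concentration units) crossed with inhibitor 0, 400 and 800 uM.
#'
#' @param model One of [kinetic_models()].
#' @param Km,Vmax,Ki,alpha Generating parameters.
#' @param S_grid Substrate concentrations.
#' @param I_grid Inhibitor concentrations (uM).
#' @param replicates Replicates per design point.
#' @param cv Multiplicative noise CV (>= 0).
#' @param seed Integer seed.
#' @param design `"grid"` crosses `S_grid` with `I_grid`; `"paired"` takes
#'   them elementwise (recycled).
#' @return Data frame with columns `S`, `I`, `v`.
#' @export
#' @examples
#' gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
#'              I_grid = c(0, 400), cv = 0)
gen_kinetics <- function(model, Km, Vmax, Ki = Inf, alpha = 1,
                         S_grid = seq(0.025, 0.4, length.out = 8),
                         I_grid = c(0, 400, 800), replicates = 1L,
                         cv = 0, seed = 1L, design = c("grid", "paired")) {
  model <- match.arg(model, kinetic_models())
  design <- match.arg(design)
  if (Km <= 0 || Vmax <= 0 || Ki <= 0 || alpha <= 0)
    stop("kinetic parameters must be positive", call. = FALSE)
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  d <- if (design == "grid")
    expand.grid(S = S_grid, I = I_grid, rep = seq_len(replicates))
  else {
    n <- max(length(S_grid), length(I_grid))
    expand.grid(idx = seq_len(n), rep = seq_len(replicates))
  }
  if (design == "paired") {
    d$S <- rep_len(S_grid, nrow(d))
    d$I <- rep_len(I_grid, nrow(d))
  }
  v <- velocity(model, S = d$S, I = d$I, Km = Km, Vmax = Vmax, Ki = Ki,
                alpha = alpha)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    v <- .with_seed(seed,
                    v * stats::rlnorm(length(v), -sdlog^2 / 2, sdlog))
  }
  data.frame(S = d$S, I = d$I, v = v)
}

#' Generate a synthetic peptidomics candidate table
#'
#' Emulates an identified-peptide table at reduced scale: lognormal
#' relative abundances, Beta-distributed external bioactivity scores, and
#' sequences drawn from a mixture of the active-like and inactive-like
#' arms of an [activity_model()]. Abundance, length, score and position-2
#' status are generated independently, so the expected survivor fraction
#' under the screening criteria is the product of the per-criterion tail
#' probabilities.
#'
#' @param n Number of rows.
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @param score_shape1,score_shape2 Beta parameters of the score column.
#' @param length_range Sequence length range (min >= 2).
#' @param model An [activity_model()] for the sequence structure.
#' @param frac_active_like Mixture weight of the active-like arm.
#' @param seed Integer seed.
#' @return Data frame `sequence`, `abundance`, `score`, `source`.
#' @export
gen_peptidomics_table <- function(n, abundance_meanlog = log(5e6),
                                  abundance_sdlog = 2,
                                  score_shape1 = 5, score_shape2 = 1,
                                  length_range = c(2L, 12L),
                                  model = activity_model(),
                                  frac_active_like = 0.3, seed = 1L) {
  stopifnot(inherits(model, "activity_model"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  .with_seed(seed, {
    active_like <- stats::runif(n) < frac_active_like
    seqs <- vapply(active_like, function(a) {
      p2 <- if (a) model$p_pro2_active else model$p_pro2_inactive
      ph <- if (a) model$p_hydrophobic_terminal_active
            else model$p_hydrophobic_terminal_inactive
      .gen_sequence(p2, ph, as.integer(length_range))
    }, character(1))
    data.frame(
      sequence = seqs,
      abundance = stats::rlnorm(n, abundance_meanlog, abundance_sdlog),
      score = stats::rbeta(n, score_shape1, score_shape2),
      source = "synthetic",
      stringsAsFactors = FALSE)
  })
}

#' Generate protein fixtures with planted motifs
#'
#' Random protein sequences with known bioactive motifs planted at
#' recorded, non-overlapping positions, for testing digestion and A-value
#' code without external sequence downloads.
#'
#' @param n Number of proteins.
#' @param length Residue count of each protein.
#' @param composition Optional named per-residue sampling weights
#'   (default uniform over the 20 residues).
#' @param planted_motifs Character vector of motifs planted once each, per
#'   protein.
#' @param seed Integer seed.
#' @return List of [protein_record()]s with attribute `planted`: a data
#'   frame of `protein`, `motif`, `start`.
#' @export
#' @examples
#' p <- gen_protein_fixtures(1, 50, planted_motifs = c("IP", "IP", "IP"))
#' attr(p, "planted")
gen_protein_fixtures <- function(n, length, composition = NULL,
                                 planted_motifs = character(0),
                                 seed = 1L) {
  if (length(planted_motifs) > 0L)
    planted_motifs <- vapply(planted_motifs, validate_sequence,
                             character(1), USE.NAMES = FALSE)
  if (sum(nchar(planted_motifs)) > length)
    stop("infeasible planting: motifs do not fit in the protein length",
         call. = FALSE)
  weights <- rep(1, 20L)
  if (!is.null(composition)) {
    if (is.null(names(composition)))
      stop("composition must be a named weight vector", call. = FALSE)
    weights <- rep(0, 20L)
    idx <- match(.validate_residue_set(names(composition)), amino_acids())
    weights[idx] <- composition
    if (any(weights < 0) || sum(weights) <= 0)
      stop("composition weights must be non-negative and sum > 0",
           call. = FALSE)
  }
  .with_seed(seed, {
    planted <- list()
    proteins <- lapply(seq_len(n), function(i) {
      res <- sample(amino_acids(), length, replace = TRUE, prob = weights)
      taken <- rep(FALSE, length)
      for (motif in planted_motifs) {
        k <- nchar(motif)
        placed <- FALSE
        for (try in seq_len(1000L)) {
          s <- sample.int(length - k + 1L, 1L)
          if (!any(taken[s:(s + k - 1L)])) {
            res[s:(s + k - 1L)] <- strsplit(motif, "")[[1L]]
            taken[s:(s + k - 1L)] <- TRUE
            planted[[length(planted) + 1L]] <<-
              data.frame(protein = paste0("synthetic_", i), motif = motif,
                         start = s, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("infeasible planting: could not place motif ", motif,
               call. = FALSE)
      }
      protein_record(paste0("synthetic_", i), paste(res, collapse = ""),
                     source = "synthetic fixture")
    })
    attr(proteins, "planted") <- if (length(planted))
      do.call(rbind, planted)
    else
      data.frame(protein = character(0), motif = character(0),
                 start = integer(0))
    proteins
  })
}
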