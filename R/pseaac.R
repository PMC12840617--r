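#' Feature names of the 27-component PseAAC vector
#'
#' Components 1-20 are the amino-acid composition terms in alphabetical
#' one-letter order, component 21 is the weighted first-order hydrophobicity
#' sequence-correlation factor, and components 22-27 are the sequence means
#' of the six physicochemical properties.
#'
#' @return Character vector of length 27.
#' @export
pseaac_feature_names <- function() {
  c(paste0("freq_", amino_acids()),
    "hydrophobicity_autocorr",
    "mean_hydrophobicity", "mean_hydrophilicity", "mean_mass",
    "mean_pk1", "mean_pk2", "mean_pi")
}

## normalize a 20-value property vector to zero mean / unit variance over
## the 20 residues (population convention)
.normalize_scale <- function(x) {
  mu <- mean(x)
  sdev <- sqrt(sum((x - mu)^2) / length(x))
  (x - mu) / sdev
}

#' Pseudo amino acid composition featurization
#'
#' Transforms a peptide into the 27-component PseAAC vector used by the
#' DPP-IV activity classifier. Writing `f_u` for the relative frequency of
#' residue `u` and `theta1` for the first-order squared-difference
#' autocorrelation of (normalized) hydrophobicity along the chain,
#' components 1-20 are `f_u / (1 + w * theta1)`, component 21 is
#' `w * theta1 / (1 + w * theta1)` (so components 1-21 sum to one), and
#' components 22-27 are the unweighted means of the raw hydrophobicity,
#' hydrophilicity, residue mass, pK1, pK2 and pI over the residues — the
#' mass mean therefore stays interpretable in Daltons.
#'
#' For a single-residue peptide `theta1` is defined as 0.
#'
#' @param peptide Amino-acid string.
#' @param w Positive sequence-order weight (default 0.05).
#' @param scales Property table, see [default_scales()].
#' @return Named numeric vector of length 27.
#' @export
#' @examples
#' featurize("FPL")
#' sum(featurize("FPHFDL")[1:21])  # 1
featurize <- function(peptide, w = 0.05, scales = default_scales()) {
  if (!is.numeric(w) || length(w) != 1L || w < 0)
    stop("w must be a non-negative number", call. = FALSE)
  scales <- .validate_scales(scales)
  res <- .residues(peptide, "peptide")
  L <- length(res)

  counts <- table(factor(res, levels = amino_acids()))
  f <- as.numeric(counts) / L

  hnorm <- .normalize_scale(scales$hydrophobicity)
  names(hnorm) <- scales$residue
  theta1 <- if (L < 2L) 0 else
    mean((hnorm[res[-1L]] - hnorm[res[-L]])^2)

  denom <- 1 + w * theta1
  comp <- c(f / denom, (w * theta1) / denom)

  idx <- match(res, scales$residue)
  means <- c(mean(scales$hydrophobicity[idx]),
             mean(scales$hydrophilicity[idx]),
             mean(scales$mass[idx]),
             mean(scales$pk1[idx]),
             mean(scales$pk2[idx]),
             mean(scales$pi[idx]))

  out <- c(comp, means)
  names(out) <- pseaac_feature_names()
  out
}

#' Featurize a set of peptides into a matrix
#'
#' @param peptides Character vector of sequences.
#' @inheritParams featurize
#' @return Numeric matrix, one row per peptide, 27 named columns; row names
#'   are the sequences.
#' @export
featurize_matrix <- function(peptides, w = 0.05, scales = default_scales()) {
  scales <- .validate_scales(scales)
  m <- t(vapply(peptides, featurize, numeric(27L), w = w, scales = scales))
  rownames(m) <- peptides
  m
}

#' Fit a feature standardizer
#'
#' Learns per-column mean and standard deviation (population convention,
#' denominator n) from a training matrix so that the identical
#' transformation can be replayed on new candidates at prediction time.
#' Constant columns are flagged and passed through unscaled.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return Object of class `standardizer` with fields `mean`, `sd`,
#'   `constant` (logical flag per column).
#' @export
#' @examples
#' s <- fit_standardizer(featurize_matrix(c("FPL", "FPH", "YPW")))
#' colMeans(apply_standardizer(s, featurize_matrix(c("FPL", "FPH", "YPW"))))
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("need at least 2 rows to fit a standardizer", call. = FALSE)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
  constant <- !is.finite(sdev) | sdev <= 0
  sdev[constant] <- 1
  structure(list(mean = mu, sd = sdev, constant = constant),
            class = "standardizer")
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer> %d features (%d constant)\n",
              length(x$mean), sum(x$constant)))
  invisible(x)
}

#' Apply a fitted standardizer
#'
#' @param standardizer A [fit_standardizer()] result.
#' @param x Matrix with the same columns as the training matrix.
#' @return Standardized matrix; constant training columns are returned
#'   centred but unscaled.
#' @export
apply_standardizer <- function(standardizer, x) {
  stopifnot(inherits(standardizer, "standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(standardizer$mean))
    stop("column count does not match the fitted standardizer",
         call. = FALSE)
  out <- sweep(x, 2L, standardizer$mean, "-")
  sweep(out, 2L, standardizer$sd, "/")
}
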