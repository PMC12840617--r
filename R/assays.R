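#' Fit a dose-response curve and estimate IC50
#'
#' Fits residual enzyme activity (%) against inhibitor concentration with a
#' logistic curve on log10 concentration. By default the asymptotes are
#' fixed at 0 and 100 because the assay normalizes activity to the
#' uninhibited control, so the model is
#' `activity = 100 / (1 + (conc / IC50)^h)` with Hill slope `h` free, and
#' the fitted IC50 is exactly the concentration at 50% activity. With
#' `fix_asymptotes = FALSE` both asymptotes are free and the reported IC50
#' is still the concentration where the fitted curve crosses 50%.
#'
#' @param data Data frame with columns `conc_uM` (positive) and
#'   `activity_pct`.
#' @param fix_asymptotes Fix bottom/top at 0/100 (default TRUE).
#' @return Object of class `ic50_fit` with fields `ic50`, `hill`,
#'   `coefficients`, `in_range` (whether the IC50 lies within the tested
#'   concentrations), `data`, `fit`.
#' @export
#' @examples
#' d <- data.frame(conc_uM = c(50, 150, 450, 1350, 4050),
#'                 activity_pct = 100 / (1 + (c(50, 150, 450, 1350, 4050) /
#'                                             321.5)^1.1))
#' coef(fit_ic50(d))
fit_ic50 <- function(data, fix_asymptotes = TRUE) {
  miss <- setdiff(c("conc_uM", "activity_pct"), names(data))
  if (length(miss) > 0L)
    stop("dose-response table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(data$conc_uM <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (length(unique(data$conc_uM)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (suppressWarnings(stats::cor(data$conc_uM, data$activity_pct,
                                  method = "kendall")) > 0.3)
    warning("activity increases with concentration beyond noise; ",
            "check the response column")

  lc <- log10(data$conc_uM)
  ## start: log-IC50 at the concentration nearest 50% activity
  start_lic50 <- lc[which.min(abs(data$activity_pct - 50))]
  if (fix_asymptotes) {
    fit <- minpack.lm::nlsLM(
      activity_pct ~ 100 / (1 + 10^(h * (log10(conc_uM) - lic50))),
      data = data, start = list(lic50 = start_lic50, h = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- stats::coef(fit)
    ic50 <- 10^est[["lic50"]]
    hill <- est[["h"]]
  } else {
    fit <- minpack.lm::nlsLM(
      activity_pct ~ bottom + (top - bottom) /
        (1 + 10^(h * (log10(conc_uM) - lic50))),
      data = data,
      start = list(lic50 = start_lic50, h = 1,
                   bottom = min(data$activity_pct),
                   top = max(data$activity_pct)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- stats::coef(fit)
    hill <- est[["h"]]
    ## concentration at 50% activity from the free-asymptote curve
    frac <- (est[["top"]] - 50) / (50 - est[["bottom"]])
    ic50 <- if (frac > 0) 10^(est[["lic50"]] + log10(frac) / hill)
            else NA_real_
  }
  structure(
    list(ic50 = ic50, hill = hill, coefficients = stats::coef(fit),
         in_range = is.finite(ic50) && ic50 >= min(data$conc_uM) &&
           ic50 <= max(data$conc_uM),
         data = data, fit = fit),
    class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<ic50_fit> IC50 = %.*g uM (Hill slope %.3g)%s\n",
              digits, x$ic50, x$hill,
              if (x$in_range) "" else " [outside tested range]"))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50_uM = object$ic50, hill = object$hill)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  conc <- if (is.data.frame(newdata)) newdata$conc_uM else newdata
  est <- as.list(object$coefficients)
  if (is.null(est$bottom))
    100 / (1 + 10^(est$h * (log10(conc) - est$lic50)))
  else
    est$bottom + (est$top - est$bottom) /
      (1 + 10^(est$h * (log10(conc) - est$lic50)))
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc_uM, d$activity_pct, log = "x", pch = 16,
                 xlab = "concentration (uM)", ylab = "DPP-IV activity (%)",
                 ...)
  grid_c <- 10^seq(log10(min(d$conc_uM)), log10(max(d$conc_uM)),
                   length.out = 200)
  graphics::lines(grid_c, predict(x, grid_c))
  graphics::abline(v = x$ic50, h = 50, lty = 3)
  invisible(x)
}

#' Degree of hydrolysis from free amino groups
#'
#' `DH = 100 * ([NH2] V1 m) / ([NH2]tot V m1)`, where `[NH2]` is the free
#' amino-group concentration of the hydrolysate (M), `V1`/`m1` its volume
#' (mL) and sample mass (g), and `[NH2]tot`, `V`, `m` the same quantities
#' for the completely hydrolyzed reference.
#'
#' @param free_amino,total_amino Free amino-group concentrations (M).
#' @param V1,V Volumes (mL).
#' @param m1,m Masses (g).
#' @return DH in percent.
#' @export
#' @examples
#' dh_percent(0.02, 10, 0.5, 0.25, 10, 0.5)  # 8%
dh_percent <- function(free_amino, V1, m1, total_amino, V, m) {
  if (any(c(V1, m1, total_amino, V, m) <= 0))
    stop("all reference quantities must be positive", call. = FALSE)
  if (any(free_amino < 0))
    stop("free amino concentration must be >= 0", call. = FALSE)
  100 * (free_amino * V1 * m) / (total_amino * V * m1)
}

#' Kjeldahl protein content
#'
#' `X (g/100 g) = ((V1 - V2) / m) * (V_aliquot / 100) * c * 0.014 * F * 100`
#' where `V1` and `V2` are the titrant volumes (mL) for sample and blank,
#' `c` the acid molarity, `m` the sample mass (g), `V_aliquot` the digestion
#' volume taken (mL), 0.014 the milliequivalent mass of nitrogen and `F`
#' the nitrogen-to-protein conversion factor (5.7 for blood meal).
#'
#' @param V1,V2 Titrant volumes, sample and blank (mL), `V1 >= V2`.
#' @param c Acid concentration (M).
#' @param m Sample mass (g).
#' @param V_aliquot Digestion-solution volume taken (mL).
#' @param F_factor Nitrogen-to-protein factor (default 5.7).
#' @return Protein content in g per 100 g.
#' @export
protein_content_kjeldahl <- function(V1, V2, c, m, V_aliquot,
                                     F_factor = 5.7) {
  if (any(c(c, m, V_aliquot, F_factor) <= 0))
    stop("c, m, V_aliquot and F_factor must be positive", call. = FALSE)
  if (any(V1 < V2)) stop("V1 must be >= V2", call. = FALSE)
  ((V1 - V2) / m) * (V_aliquot / 100) * c * 0.014 * F_factor * 100
}

#' Molecular weight from a size-exclusion calibration
#'
#' Fits the SEC standard curve `log10(MW) = a * RT + b` to the calibration
#' standards and converts a sample retention time to its estimated
#' molecular weight. Retention times outside the calibrated range are
#' estimated by extrapolation and flagged.
#'
#' @param standards Data frame with columns `mw` (Da) and `rt` (min), at
#'   least 2 rows with distinct retention times.
#' @param sample_rt Sample retention time(s) in minutes.
#' @return Numeric vector of estimated molecular weights (Da), with
#'   attribute `extrapolated` (logical vector) when any sample falls
#'   outside the calibrated range.
#' @export
#' @examples
#' std <- data.frame(mw = c(451.48, 6511, 12500, 66000),
#'                   rt = c(14.2, 11.8, 10.9, 8.3))
#' mw_from_sec(std, 12.5)
mw_from_sec <- function(standards, sample_rt) {
  miss <- setdiff(c("mw", "rt"), names(standards))
  if (length(miss) > 0L)
    stop("standards table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(standards) < 2L || length(unique(standards$rt)) < 2L)
    stop("need at least 2 standards with distinct retention times",
         call. = FALSE)
  if (any(standards$mw <= 0)) stop("standard MW must be positive",
                                   call. = FALSE)
  fit <- stats::lm(log10(mw) ~ rt, data = standards)
  mw <- 10^as.numeric(stats::predict(fit, data.frame(rt = sample_rt)))
  outside <- sample_rt < min(standards$rt) | sample_rt > max(standards$rt)
  if (any(outside)) attr(mw, "extrapolated") <- outside
  mw
}
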