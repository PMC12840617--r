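## ---------------------------------------------------------------------------
## Enzyme inhibition kinetics
##
## The primary estimator is a global nonlinear least-squares fit across all
## inhibitor levels (shared Km, Vmax, Ki), with the double-reciprocal
## Lineweaver-Burk regression used only for starting values and diagnostics:
## the reciprocal transform amplifies noise at low velocities and is kept out
## of the estimation path.
## ---------------------------------------------------------------------------

#' Inhibition model velocity functions
#'
#' Initial velocity as a function of substrate concentration `S` and
#' inhibitor concentration `I` for the five supported models:
#' plain Michaelis-Menten `v = Vmax S / (Km + S)` (Ki unused), competitive
#' `v = Vmax S / (Km (1 + I/Ki) + S)`, non-competitive
#' `v = (Vmax / (1 + I/Ki)) S / (Km + S)`, uncompetitive
#' `v = Vmax S / (Km + S (1 + I/Ki))`, and mixed
#' `v = Vmax S / (Km (1 + I/Ki) + S (1 + I/(alpha Ki)))`.
#'
#' @param model Model name.
#' @param S,I Substrate and inhibitor concentrations.
#' @param Km,Vmax,Ki,alpha Kinetic parameters.
#' @return Numeric vector of velocities.
#' @export
#' @examples
#' velocity("competitive", S = 0.1, I = 400, Km = 0.2684, Vmax = 1.4428,
#'          Ki = 709)
velocity <- function(model, S, I = 0, Km, Vmax, Ki = Inf, alpha = 1) {
  switch(match.arg(model, kinetic_models()),
         michaelis_menten = Vmax * S / (Km + S),
         competitive = Vmax * S / (Km * (1 + I / Ki) + S),
         noncompetitive = (Vmax / (1 + I / Ki)) * S / (Km + S),
         uncompetitive = Vmax * S / (Km + S * (1 + I / Ki)),
         mixed = Vmax * S /
           (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki))))
}

#' Supported kinetic model names
#' @return Character vector.
#' @export
kinetic_models <- function() {
  c("michaelis_menten", "competitive", "noncompetitive", "uncompetitive",
    "mixed")
}

.check_kinetics_data <- function(data, need_inhibitor = FALSE) {
  if (!is.data.frame(data))
    stop("kinetics data must be a data frame", call. = FALSE)
  if (!"I" %in% names(data) && !need_inhibitor) data$I <- 0
  miss <- setdiff(c("S", "I", "v"), names(data))
  if (length(miss) > 0L)
    stop("kinetics data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(data$S <= 0)) stop("substrate concentrations must be > 0",
                             call. = FALSE)
  if (any(data$I < 0)) stop("inhibitor concentrations must be >= 0",
                            call. = FALSE)
  if (any(data$v <= 0)) stop("velocities must be > 0 (clean the data first)",
                             call. = FALSE)
  data
}

## number of free parameters per model
.model_npar <- function(model) {
  switch(model, michaelis_menten = 2L, mixed = 4L, 3L)
}

## Gaussian AICc from the residual sum of squares, with the error variance
## floored at a tiny fraction of the signal so that numerically perfect fits
## (noiseless data) compare by parameter count instead of floating-point
## residual dust.
.aicc <- function(fit, data) {
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1L    # parameters + residual sigma
  rss <- sum(stats::residuals(fit)^2)
  floor_rss <- n * (1e-8 * mean(abs(data$v)))^2
  s2 <- max(rss, floor_rss) / n
  n * log(s2) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

## Lineweaver-Burk start values from the uninhibited points
.lb_start <- function(data) {
  d0 <- data[data$I == min(data$I), , drop = FALSE]
  lb <- stats::lm(I(1 / v) ~ I(1 / S), data = d0)
  b <- stats::coef(lb)
  Vmax0 <- 1 / b[[1L]]
  Km0 <- b[[2L]] / b[[1L]]
  if (!is.finite(Vmax0) || Vmax0 <= 0) Vmax0 <- max(data$v)
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(data$S)
  list(Km = Km0, Vmax = Vmax0)
}

.fit_one_model <- function(model, data, start) {
  form <- switch(model,
    michaelis_menten = v ~ Vmax * S / (Km + S),
    competitive = v ~ Vmax * S / (Km * (1 + I / Ki) + S),
    noncompetitive = v ~ (Vmax / (1 + I / Ki)) * S / (Km + S),
    uncompetitive = v ~ Vmax * S / (Km + S * (1 + I / Ki)),
    mixed = v ~ Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki))))
  s <- list(Km = start$Km, Vmax = start$Vmax)
  lower <- c(Km = 0, Vmax = 0)
  if (model %in% c("competitive", "noncompetitive", "uncompetitive",
                   "mixed")) {
    s$Ki <- start$Ki
    lower <- c(lower, Ki = 0)
  }
  if (model == "mixed") {
    s$alpha <- 1
    lower <- c(lower, alpha = 1e-6)
  }
  minpack.lm::nlsLM(form, data = data, start = s,
                    lower = lower[names(s)],
                    control = minpack.lm::nls.lm.control(maxiter = 500))
}

.fit_summary <- function(model, fit, data) {
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  list(model = model, coefficients = est,
       std_errors = stats::setNames(se[names(est)], names(est)),
       rss = sum(stats::residuals(fit)^2), aicc = .aicc(fit, data),
       fit = fit)
}

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least-squares fit of `v = Vmax S / (Km + S)` to uninhibited
#' velocity data, with starting values from the Lineweaver-Burk linear fit.
#'
#' @param data Data frame with columns `S` and `v` (an `I` column, if
#'   present, must be constant; only its lowest level is used).
#' @return An `inhibition_fit` object with `model = "michaelis_menten"`.
#' @export
#' @examples
#' d <- gen_kinetics("michaelis_menten", Km = 0.2684, Vmax = 1.4428,
#'                   I_grid = 0, cv = 0)
#' coef(fit_michaelis_menten(d))
fit_michaelis_menten <- function(data) {
  data <- .check_kinetics_data(data)
  data <- data[data$I == min(data$I), , drop = FALSE]
  if (length(unique(data$S)) < 3L)
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  start <- .lb_start(data)
  fit <- .fit_one_model("michaelis_menten", data, start)
  cands <- list(michaelis_menten = .fit_summary("michaelis_menten", fit,
                                                data))
  structure(list(model = "michaelis_menten", best = cands[[1L]],
                 candidates = cands, data = data),
            class = "inhibition_fit")
}

#' Global inhibition-model fitting and mode discrimination
#'
#' Fits each candidate inhibition model globally — a single (Km, Vmax, Ki)
#' shared across all inhibitor levels — by nonlinear least squares, and
#' ranks the candidates by small-sample-corrected AIC (AICc). The
#' lowest-AICc model is the selected inhibition mode; the visual
#' Lineweaver-Burk intersection argument is available as a diagnostic
#' through [lineweaver_burk()] and [plot.inhibition_fit()].
#'
#' With data at a single inhibitor level the fit reduces to plain
#' Michaelis-Menten.
#'
#' @param data Data frame with columns `S`, `I`, `v`; must include `I = 0`
#'   and at least 3 distinct `S` per inhibitor level.
#' @param models Candidate model names (subset of [kinetic_models()]).
#' @return An `inhibition_fit` object: `model` (selected), `best`
#'   (coefficients, standard errors, RSS, AICc), `candidates` (all fits
#'   ordered by AICc), `data`.
#' @export
#' @examples
#' d <- gen_kinetics("noncompetitive", Km = 0.2684, Vmax = 1.4428,
#'                   Ki = 186, cv = 0)
#' fit <- fit_inhibition(d)
#' fit$model
#' coef(fit)
fit_inhibition <- function(data,
                           models = c("competitive", "noncompetitive",
                                      "uncompetitive", "mixed")) {
  data <- .check_kinetics_data(data)
  models <- match.arg(models, kinetic_models(), several.ok = TRUE)
  levels_I <- sort(unique(data$I))
  if (length(levels_I) < 2L) return(fit_michaelis_menten(data))
  if (min(levels_I) != 0)
    stop("data must include an uninhibited (I = 0) level", call. = FALSE)
  per_level <- tapply(data$S, data$I, function(s) length(unique(s)))
  if (any(per_level < 3L))
    stop("need at least 3 distinct substrate concentrations per inhibitor level",
         call. = FALSE)

  start <- .lb_start(data)
  start$Ki <- stats::median(levels_I[levels_I > 0])
  models <- setdiff(models, "michaelis_menten")

  cands <- list()
  for (m in models) {
    f <- tryCatch(.fit_one_model(m, data, start), error = function(e) NULL)
    if (!is.null(f)) cands[[m]] <- .fit_summary(m, f, data)
  }
  if (length(cands) == 0L)
    stop("no candidate inhibition model converged", call. = FALSE)
  ## ties (e.g. nested models both fitting perfectly) go to fewer parameters
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "aicc"),
                       vapply(cands, function(cc)
                         length(cc$coefficients), integer(1)))]
  structure(list(model = cands[[1L]]$model, best = cands[[1L]],
                 candidates = cands, data = data),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<inhibition_fit> selected model: %s\n", x$model))
  est <- x$best$coefficients
  se <- x$best$std_errors
  for (p in names(est))
    cat(sprintf("  %-6s %.*g (se %.3g)\n", p, digits, est[[p]], se[[p]]))
  cat(sprintf("  RSS %.4g, AICc %.4g, n = %d\n", x$best$rss, x$best$aicc,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.inhibition_fit <- function(object, ...) {
  print(object)
  if (length(object$candidates) > 1L) {
    cat("\nCandidate models by AICc:\n")
    tab <- data.frame(
      model = vapply(object$candidates, `[[`, character(1), "model"),
      rss = vapply(object$candidates, `[[`, numeric(1), "rss"),
      aicc = vapply(object$candidates, `[[`, numeric(1), "aicc"),
      row.names = NULL)
    tab$delta_aicc <- tab$aicc - tab$aicc[1L]
    print(tab, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.inhibition_fit <- function(object, ...) object$best$coefficients

#' @export
residuals.inhibition_fit <- function(object, ...) {
  stats::residuals(object$best$fit)
}

#' @export
fitted.inhibition_fit <- function(object, ...) {
  stats::fitted(object$best$fit)
}

#' Predict velocities from a fitted inhibition model
#'
#' @param object An `inhibition_fit`.
#' @param newdata Data frame with `S` and (optionally) `I`; defaults to the
#'   training data.
#' @param ... Unused.
#' @return Numeric vector of predicted initial velocities.
#' @export
predict.inhibition_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (!"I" %in% names(newdata)) newdata$I <- 0
  est <- as.list(object$best$coefficients)
  velocity(object$model, S = newdata$S, I = newdata$I,
           Km = est$Km, Vmax = est$Vmax, Ki = est$Ki %||% Inf,
           alpha = est$alpha %||% 1)
}

#' Simulate datasets from a fitted inhibition model
#'
#' Draws new velocity datasets at the fitted parameters on the training
#' design, with multiplicative lognormal noise of coefficient of variation
#' `cv`.
#'
#' @param object An `inhibition_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param cv Multiplicative noise CV (default 0.02).
#' @param ... Unused.
#' @return List of data frames with columns `S`, `I`, `v`.
#' @export
simulate.inhibition_fit <- function(object, nsim = 1, seed = 1, cv = 0.02,
                                    ...) {
  est <- as.list(object$best$coefficients)
  lapply(seq_len(nsim), function(i)
    gen_kinetics(object$model, Km = est$Km, Vmax = est$Vmax,
                 Ki = est$Ki %||% Inf, alpha = est$alpha %||% 1,
                 S_grid = object$data$S, I_grid = unique(object$data$I),
                 replicates = 1L, cv = cv, seed = seed + i - 1L,
                 design = "paired"))
}

#' Lineweaver-Burk diagnostic plot
#'
#' Double-reciprocal plot of the data with the fitted model's reciprocal
#' lines per inhibitor level. Competitive families share the 1/Vmax
#' y-intercept; non-competitive families share the -1/Km x-intercept.
#'
#' @param x An `inhibition_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-level line table from [lineweaver_burk()].
#' @export
plot.inhibition_fit <- function(x, ...) {
  d <- x$data
  lev <- sort(unique(d$I))
  cols <- stats::setNames(seq_along(lev), lev)
  graphics::plot(1 / d$S, 1 / d$v, col = cols[as.character(d$I)], pch = 16,
                 xlab = "1/[S]", ylab = "1/v",
                 main = sprintf("Lineweaver-Burk (%s)", x$model), ...)
  lines_tab <- lineweaver_burk(d)
  for (i in seq_len(nrow(lines_tab)))
    graphics::abline(lines_tab$intercept[i], lines_tab$slope[i],
                     col = cols[as.character(lines_tab$I[i])], lty = 2)
  graphics::legend("topleft", legend = paste("I =", lev), col = cols,
                   pch = 16, bty = "n")
  invisible(lines_tab)
}

#' Lineweaver-Burk lines per inhibitor level
#'
#' Ordinary least squares of `1/v` on `1/S` within each inhibitor level.
#'
#' @param data Data frame with `S`, `I` (optional), `v`.
#' @return Data frame with one row per level: `I`, `slope`, `intercept`
#'   (y-intercept) and `x_intercept`.
#' @export
#' @examples
#' d <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
#'                   cv = 0)
#' lineweaver_burk(d)
lineweaver_burk <- function(data) {
  data <- .check_kinetics_data(data)
  lev <- sort(unique(data$I))
  out <- lapply(lev, function(ii) {
    d <- data[data$I == ii, , drop = FALSE]
    if (nrow(d) < 2L)
      stop("need at least 2 points per inhibitor level", call. = FALSE)
    b <- stats::coef(stats::lm(I(1 / v) ~ I(1 / S), data = d))
    data.frame(I = ii, slope = b[[2L]], intercept = b[[1L]],
               x_intercept = -b[[1L]] / b[[2L]])
  })
  do.call(rbind, out)
}

#' Closed-form Ki for a competitive inhibitor
#'
#' From `Km_app = Km (1 + I/Ki)`: `Ki = I / (Km_app/Km - 1)`.
#'
#' @param Km Uninhibited Michaelis constant.
#' @param Km_app Apparent Km at inhibitor concentration `I`.
#' @param I Inhibitor concentration (micromolar).
#' @return Ki in the units of `I`.
#' @export
#' @examples
#' ki_competitive(0.2684, 0.4196, 400)  # ~710 uM
ki_competitive <- function(Km, Km_app, I) {
  if (Km <= 0 || I <= 0) stop("Km and I must be positive", call. = FALSE)
  if (Km_app <= Km)
    stop("Km_app must exceed Km (no competitive inhibition signal)",
         call. = FALSE)
  I / (Km_app / Km - 1)
}

#' Closed-form Ki for a non-competitive inhibitor
#'
#' From `Vmax_app = Vmax / (1 + I/Ki)`: `Ki = I / (Vmax/Vmax_app - 1)`.
#'
#' @param Vmax Uninhibited maximal velocity.
#' @param Vmax_app Apparent Vmax at inhibitor concentration `I`.
#' @param I Inhibitor concentration (micromolar).
#' @return Ki in the units of `I`.
#' @export
#' @examples
#' ki_noncompetitive(1.4428, 0.4580, 400)  # ~186 uM
ki_noncompetitive <- function(Vmax, Vmax_app, I) {
  if (Vmax <= 0 || I <= 0) stop("Vmax and I must be positive", call. = FALSE)
  if (Vmax_app >= Vmax || Vmax_app <= 0)
    stop("Vmax_app must be in (0, Vmax)", call. = FALSE)
  I / (Vmax / Vmax_app - 1)
}

#' Percent enzyme inhibition from assay slopes
#'
#' `100 (1 - slope_sample / slope_control)` from the slopes of the
#' time-absorbance progress curves. A negative value (apparent activation)
#' is returned as-is with attribute `clamped_zero = TRUE` flagged for
#' reporting.
#'
#' @param slope_sample Slope of the sample progress curve.
#' @param slope_control Positive slope of the uninhibited control.
#' @return Inhibition percentage.
#' @export
#' @examples
#' inhibition_percent(0.3, 0.9)  # 66.67
inhibition_percent <- function(slope_sample, slope_control) {
  if (any(slope_control <= 0))
    stop("control slope must be positive", call. = FALSE)
  out <- 100 * (1 - slope_sample / slope_control)
  if (any(out < 0)) attr(out, "clamped_zero") <- TRUE
  out
}
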