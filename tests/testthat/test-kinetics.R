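# Generating parameters throughout are the characterized values for the two
# goat-blood peptides: Km = 0.2684, Vmax = 1.4428 (uninhibited), Ki = 709 uM
# (competitive, FPL) and Ki = 186 uM (non-competitive, FPHFDL).

test_that("Michaelis-Menten fitting recovers noiseless parameters exactly", {
  d <- gen_kinetics("michaelis_menten", Km = 0.2684, Vmax = 1.4428,
                    I_grid = 0, cv = 0)
  fit <- fit_michaelis_menten(d)
  expect_equal(coef(fit)[["Km"]], 0.2684, tolerance = 1e-6)
  expect_equal(coef(fit)[["Vmax"]], 1.4428, tolerance = 1e-6)
  # half-maximal velocity at S = Km is a property of the fitted curve
  expect_equal(predict(fit, data.frame(S = coef(fit)[["Km"]])),
               coef(fit)[["Vmax"]] / 2, tolerance = 1e-9)
  expect_error(fit_michaelis_menten(data.frame(S = c(1, 2), I = 0,
                                               v = c(1, 2))),
               "3 distinct")
})

test_that("Michaelis-Menten fitting is robust to 5% multiplicative noise", {
  rel_err <- vapply(1:100, function(s) {
    d <- gen_kinetics("michaelis_menten", Km = 0.2684, Vmax = 1.4428,
                      I_grid = 0, replicates = 3, cv = 0.05, seed = s)
    est <- coef(fit_michaelis_menten(d))
    max(abs(est[["Km"]] / 0.2684 - 1), abs(est[["Vmax"]] / 1.4428 - 1))
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("global fitting identifies the generating inhibition mode on clean data", {
  dc <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
                     cv = 0)
  fc <- fit_inhibition(dc)
  expect_identical(fc$model, "competitive")
  expect_equal(coef(fc)[["Ki"]], 709, tolerance = 1e-6)
  expect_equal(coef(fc)[["Km"]], 0.2684, tolerance = 1e-6)

  dn <- gen_kinetics("noncompetitive", Km = 0.2684, Vmax = 1.4428,
                     Ki = 186, cv = 0)
  fn <- fit_inhibition(dn)
  expect_identical(fn$model, "noncompetitive")
  expect_equal(coef(fn)[["Ki"]], 186, tolerance = 1e-6)

  # I = 0 only: reduces to plain Michaelis-Menten
  d0 <- gen_kinetics("michaelis_menten", Km = 0.3, Vmax = 1.2, I_grid = 0,
                     cv = 0)
  expect_identical(fit_inhibition(d0)$model, "michaelis_menten")
  expect_error(fit_inhibition(transform(dc, I = I + 1)), "I = 0")
})

test_that("global Ki agrees with the closed-form apparent-parameter route", {
  # competitive: fit the I = 400 slice as apparent Michaelis-Menten
  dc <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
                     I_grid = c(0, 400), cv = 0)
  km_app <- coef(fit_michaelis_menten(
    subset(dc, I == 400)))[["Km"]]
  km0 <- coef(fit_michaelis_menten(subset(dc, I == 0)))[["Km"]]
  expect_equal(ki_competitive(km0, km_app, 400),
               coef(fit_inhibition(dc))[["Ki"]], tolerance = 1e-6)

  dn <- gen_kinetics("noncompetitive", Km = 0.2684, Vmax = 1.4428,
                     Ki = 186, I_grid = c(0, 400), cv = 0)
  vmax_app <- coef(fit_michaelis_menten(subset(dn, I == 400)))[["Vmax"]]
  vmax0 <- coef(fit_michaelis_menten(subset(dn, I == 0)))[["Vmax"]]
  expect_equal(ki_noncompetitive(vmax0, vmax_app, 400),
               coef(fit_inhibition(dn))[["Ki"]], tolerance = 1e-6)
})

test_that("closed-form Ki identities and guards hold", {
  # doubling the apparent Km at concentration I gives Ki = I
  expect_equal(ki_competitive(0.25, 0.5, 350), 350)
  expect_equal(ki_noncompetitive(1.2, 0.6, 350), 350)
  # roundtrip: reconstruct the apparent parameter from the returned Ki
  ki <- ki_competitive(0.2684, 0.4196, 400)
  expect_equal(0.2684 * (1 + 400 / ki), 0.4196, tolerance = 1e-12)
  kin <- ki_noncompetitive(1.4428, 0.4580, 400)
  expect_equal(1.4428 / (1 + 400 / kin), 0.4580, tolerance = 1e-12)
  expect_error(ki_competitive(0.4, 0.3, 100), "exceed")
  expect_error(ki_noncompetitive(1.0, 1.1, 100), "Vmax")
})

test_that("Lineweaver-Burk geometry matches the inhibition mode", {
  dc <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
                     cv = 0)
  lbc <- lineweaver_burk(dc)
  # competitive family: common y-intercept 1/Vmax
  expect_equal(lbc$intercept, rep(1 / 1.4428, 3), tolerance = 1e-6)
  dn <- gen_kinetics("noncompetitive", Km = 0.2684, Vmax = 1.4428,
                     Ki = 186, cv = 0)
  lbn <- lineweaver_burk(dn)
  # non-competitive family: lines intersect on the negative x-axis at -1/Km
  expect_equal(lbn$x_intercept, rep(-1 / 0.2684, 3), tolerance = 1e-6)
  # two-point hand computation: points (S, v) = (1, 1), (0.5, 0.8)
  hand <- lineweaver_burk(data.frame(S = c(1, 0.5), I = 0, v = c(1, 0.8)))
  expect_equal(hand$slope, 0.25)
  expect_equal(hand$intercept, 0.75)
  expect_error(lineweaver_burk(data.frame(S = 1, I = 0, v = 1)),
               "2 points")
})

test_that("inhibition mode and parameters are recovered under 2% noise", {
  truth <- list(competitive = 709, noncompetitive = 186)
  for (model in names(truth)) {
    ki <- truth[[model]]
    picked <- 0L
    errs <- matrix(NA_real_, nrow = 50, ncol = 3)
    for (s in 1:50) {
      d <- gen_kinetics(model, Km = 0.2684, Vmax = 1.4428, Ki = ki,
                        cv = 0.02, seed = s)
      f <- fit_inhibition(d, models = c("competitive", "noncompetitive",
                                        "uncompetitive"))
      picked <- picked + (f$model == model)
      est <- coef(f)
      errs[s, ] <- abs(c(est[["Km"]] / 0.2684, est[["Vmax"]] / 1.4428,
                         est[["Ki"]] / ki) - 1)
    }
    expect_gte(picked / 50, 0.9)
    expect_lt(max(apply(errs, 2, median)), 0.10)
  }
})

test_that("inhibition_fit methods behave like a model object", {
  d <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
                    cv = 0.02, seed = 3)
  fit <- fit_inhibition(d, models = c("competitive", "noncompetitive"))
  expect_s3_class(fit, "inhibition_fit")
  expect_named(coef(fit), c("Km", "Vmax", "Ki"))
  expect_length(residuals(fit), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$v, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_output(print(fit), "selected model")
  expect_output(summary(fit), "AICc")
  sims <- simulate(fit, nsim = 2, seed = 5, cv = 0.02)
  expect_length(sims, 2L)
  expect_identical(simulate(fit, nsim = 1, seed = 5, cv = 0.02)[[1]],
                   sims[[1]])
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("percent inhibition follows the slope ratio", {
  expect_equal(inhibition_percent(0, 0.9), 100)
  expect_equal(inhibition_percent(0.9, 0.9), 0)
  expect_equal(inhibition_percent(0.3, 0.9), 66.67, tolerance = 1e-3)
  neg <- inhibition_percent(1.2, 0.9)
  expect_true(isTRUE(attr(neg, "clamped_zero")))
  expect_error(inhibition_percent(0.5, 0), "positive")
})
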