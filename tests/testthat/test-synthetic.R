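test_that("labeled peptide generation honours class counts and the IC50 rule", {
  d <- gen_labeled_peptides(588, 210, seed = 1)
  expect_equal(nrow(d), 798L)
  expect_equal(sum(d$label), 588L)
  expect_identical(label_by_ic50(d$ic50_uM), d$label)
  expect_true(all(d$label[d$ic50_uM >= 2000] == 0L))
  d0 <- gen_labeled_peptides(0, 25, seed = 2)
  expect_true(all(d0$label == 0L))
  # reproducibility and purity of the caller RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_labeled_peptides(20, 20, seed = 5))
  expect_equal(runif(1), before)
  expect_identical(gen_labeled_peptides(50, 20, seed = 9),
                   gen_labeled_peptides(50, 20, seed = 9))
})

test_that("position-2 enrichment matches the generating probability", {
  m <- activity_model()
  d <- gen_labeled_peptides(2000, 2000, model = m, seed = 42)
  pos2 <- substr(d$sequence, 2, 2) %in% c("P", "A")
  p_hat_act <- mean(pos2[d$label == 1])
  p_hat_inact <- mean(pos2[d$label == 0])
  # 99% binomial CI around the generating probabilities at n = 2000
  expect_lt(abs(p_hat_act - m$p_pro2_active),
            2.58 * sqrt(0.7 * 0.3 / 2000))
  expect_lt(abs(p_hat_inact - m$p_pro2_inactive),
            2.58 * sqrt(0.2 * 0.8 / 2000))
})

test_that("impossible activity models are rejected", {
  expect_error(activity_model(active_meanlog = log(5000),
                              active_sdlog = 0), "impossible")
  expect_error(activity_model(active_meanlog = log(1e5),
                              active_sdlog = 0.1), "impossible")
  expect_error(activity_model(p_pro2_active = 1.4), "probabilities")
})

test_that("kinetics generation is exact at zero noise and seed-stable", {
  d <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428, Ki = 709,
                    I_grid = 0, cv = 0)
  expect_equal(d$v, 1.4428 * d$S / (0.2684 + d$S))
  # apparent Km of the inhibited slice matches the closed form
  d400 <- gen_kinetics("competitive", Km = 0.2684, Vmax = 1.4428,
                       Ki = 709, I_grid = c(0, 400), cv = 0)
  km_app <- coef(fit_michaelis_menten(subset(d400, I == 400)))[["Km"]]
  expect_equal(km_app, 0.2684 * (1 + 400 / 709), tolerance = 1e-6)
  expect_identical(
    gen_kinetics("noncompetitive", Km = 0.3, Vmax = 1, Ki = 200,
                 cv = 0.05, seed = 7),
    gen_kinetics("noncompetitive", Km = 0.3, Vmax = 1, Ki = 200,
                 cv = 0.05, seed = 7))
  expect_error(gen_kinetics("competitive", Km = -1, Vmax = 1, Ki = 1),
               "positive")
  expect_error(gen_kinetics("banana", Km = 1, Vmax = 1, Ki = 1))
})

test_that("peptidomics tables have independent, analytic survivor structure", {
  tab <- gen_peptidomics_table(1000, seed = 3)
  expect_equal(nrow(tab), 1000L)
  expect_true(all(tab$abundance > 0))
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  # scores drawn essentially below 0.9 leave no survivors
  low <- gen_peptidomics_table(500, score_shape1 = 1, score_shape2 = 200,
                               seed = 4)
  expect_equal(nrow(apply_filters(low, screening_criteria())$survivors),
               0L)
  expect_identical(gen_peptidomics_table(100, seed = 8),
                   gen_peptidomics_table(100, seed = 8))
})

test_that("protein fixtures plant motifs at recorded positions", {
  p <- gen_protein_fixtures(1, 50, planted_motifs = c("IP", "IP", "IP"),
                            seed = 2)
  planted <- attr(p, "planted")
  expect_equal(nrow(planted), 3L)
  for (i in seq_len(3))
    expect_equal(substr(p[[1]]$sequence, planted$start[i],
                        planted$start[i] + 1), "IP")
  expect_gte(a_value(p[[1]], motif_db("IP")), 3 / 50)
  # uniform composition approaches 1/20 per residue
  big <- gen_protein_fixtures(1, 20000, seed = 3)
  freqs <- table(strsplit(big[[1]]$sequence, "")[[1]]) / 20000
  expect_true(all(abs(freqs - 0.05) < 0.01))
  expect_identical(gen_protein_fixtures(2, 30, seed = 5),
                   gen_protein_fixtures(2, 30, seed = 5))
  expect_error(gen_protein_fixtures(1, 3, planted_motifs = c("AAAA")),
               "infeasible")
})
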