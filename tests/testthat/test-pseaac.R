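# recover theta1 from a feature vector (w fixed at 0.05)
attr_theta <- function(f) {
  c21 <- f[["hydrophobicity_autocorr"]]
  c21 / (0.05 * (1 - c21))
}

test_that("featurization yields the 27-component layout", {
  f <- featurize("FPL")
  expect_length(f, 27L)
  expect_named(f, pseaac_feature_names())
  expect_true(all(is.finite(f)))
  # homopolymer: zero autocorrelation, unit composition, raw property means
  a <- featurize("AAAA")
  expect_equal(a[["freq_A"]], 1)
  expect_equal(a[["hydrophobicity_autocorr"]], 0)
  sc <- default_scales()
  ala <- sc[sc$residue == "A", ]
  expect_equal(unname(a[22:27]),
               c(ala$hydrophobicity, ala$hydrophilicity, ala$mass,
                 ala$pk1, ala$pk2, ala$pi))
  # single residue: correlation factor defined as 0
  expect_equal(featurize("W")[["hydrophobicity_autocorr"]], 0)
  expect_error(featurize("FPX"), "X")
})

test_that("featurization matches an independent implementation", {
  set.seed(3)
  peptides <- c("FPL", "FPHFDL", vapply(1:50, function(i)
    random_sequence(1, 15), character(1)))
  for (p in peptides)
    expect_equal(unname(featurize(p)), brute_featurize(p),
                 tolerance = 1e-12)
})

test_that("components 1-21 are normalized and composition is order-invariant", {
  set.seed(17)
  for (i in 1:50) {
    p <- random_sequence(2, 20)
    f <- featurize(p)
    expect_equal(sum(f[1:21]), 1, tolerance = 1e-9)
    # shuffling residues keeps composition and property means, and (for
    # peptides with distinct neighbours) can move only component 21
    shuffled <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    g <- featurize(shuffled)
    expect_equal(sum(g[1:21]), 1, tolerance = 1e-9)
    expect_equal(unname(f[22:27]), unname(g[22:27]))
    expect_equal(unname(f[1:20] * (1 + 0.05 * attr_theta(f))),
                 unname(g[1:20] * (1 + 0.05 * attr_theta(g))),
                 tolerance = 1e-9)
  }
})

test_that("component 21 is sequence-order sensitive and vanishes as w -> 0", {
  # alternating vs blocked arrangement of the same composition
  f1 <- featurize("IDIDID")
  f2 <- featurize("IIIDDD")
  expect_gt(f1[["hydrophobicity_autocorr"]],
            f2[["hydrophobicity_autocorr"]])
  # w -> 0 limit: composition components converge to raw frequencies
  p <- "FPHFDL"
  raw <- featurize(p, w = 1e-12)[1:20]
  counts <- table(factor(strsplit(p, "")[[1]], levels = amino_acids()))
  expect_equal(unname(raw), as.numeric(counts) / nchar(p),
               tolerance = 1e-9)
})

test_that("standardizer replays the training transformation", {
  x <- featurize_matrix(c("FPL", "FPHFDL", "YPW", "HPYF", "IPIPI"))
  s <- fit_standardizer(x)
  z <- apply_standardizer(s, x)
  expect_true(all(abs(colMeans(z[, !s$constant])) < 1e-12))
  # population variance of each fitted column is 1
  expect_equal(unname(colMeans(z[, !s$constant]^2)),
               rep(1, sum(!s$constant)))
  # two-row worked case
  s2 <- fit_standardizer(matrix(c(0, 2), ncol = 1))
  expect_equal(as.numeric(apply_standardizer(s2, matrix(c(0, 2)))),
               c(-1, 1))
  # constant columns flagged and passed through centred
  xc <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- fit_standardizer(xc)
  expect_true(sc$constant[["b"]])
  expect_equal(unname(apply_standardizer(sc, xc)[, "b"]), c(0, 0, 0))
  expect_error(fit_standardizer(matrix(1, nrow = 1)), "2 rows")
  # new data reuses training parameters
  xnew <- featurize_matrix("AAPK")
  expect_equal(as.numeric(apply_standardizer(s, xnew)),
               as.numeric((featurize("AAPK") - s$mean) / s$sd))
})

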