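test_that("cleavage sites follow the per-bond predicate", {
  expect_equal(find_cleavage_sites("FPHFDL", "trypsin"), 3L)
  expect_equal(find_cleavage_sites("AAAA", "chymotrypsin"), integer(0))
  expect_equal(find_cleavage_sites("FPHFDL", "pepsin"), c(1L, 3L, 4L, 5L))
  # P1' veto: bromelain cuts only before basic residues
  expect_equal(find_cleavage_sites("ALKAG", "bromelain"), 2L)
  expect_error(find_cleavage_sites("FPXDL", "trypsin"), "X")
  expect_error(cleavage_rule("none"), "non-empty")
})

test_that("site finding agrees with brute-force predicate evaluation", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_sequence()
    r <- random_rule()
    expect_identical(find_cleavage_sites(s, r), brute_sites(s, r))
  }
})

test_that("complete digestion partitions the parent", {
  frags <- digest("FPHFDL", "trypsin")
  expect_equal(frags$sequence, c("FPH", "FDL"))
  expect_equal(frags$start, c(1L, 4L))
  expect_equal(frags$end, c(3L, 6L))
  expect_equal(frags$length, c(3L, 3L))

  # no matching residues: one full-length peptide
  none <- digest("AAAA", cleavage_rule("k-only", c_terminal_of = "K"))
  expect_equal(none$sequence, "AAAA")

  set.seed(99)
  for (i in 1:100) {
    s <- random_sequence()
    r <- random_rule()
    frags <- digest(s, r)
    expect_identical(paste(frags$sequence, collapse = ""), s)
    # no fragment retains an internal cut position
    for (fs in frags$sequence)
      expect_length(find_cleavage_sites(fs, r), 0)
  }
})

test_that("missed-cleavage enumeration is monotone and complete", {
  # partial pepsin products of FPHFDL: FPHF and DL need 2 internal sites,
  # FPHFD needs 3
  mc2 <- digest("FPHFDL", "pepsin", missed_cleavages = 2)$sequence
  expect_true(all(c("FPHF", "DL") %in% mc2))
  expect_false("FPHFD" %in% mc2)
  mc3 <- digest("FPHFDL", "pepsin", missed_cleavages = 3)$sequence
  expect_true(all(c("FPHF", "FPHFD", "DL") %in% mc3))

  set.seed(7)
  for (i in 1:50) {
    s <- random_sequence()
    r <- random_rule()
    n0 <- nrow(digest(s, r, missed_cleavages = 0))
    n1 <- nrow(digest(s, r, missed_cleavages = 1))
    n2 <- nrow(digest(s, r, missed_cleavages = 2))
    expect_true(n1 >= n0 && n2 >= n1)
  }

  # min_length drops fragments after enumeration
  kept <- digest("FPHFDL", "pepsin", missed_cleavages = 1, min_length = 2)
  expect_true(all(kept$length >= 2))
  expect_error(digest("AAA", "pepsin", missed_cleavages = -1))
})

test_that("coordinates reference the parent subsequence", {
  set.seed(13)
  for (i in 1:30) {
    s <- random_sequence(10, 40)
    frags <- digest(s, random_rule(), missed_cleavages = 2)
    expect_identical(frags$sequence,
                     substring(s, frags$start, frags$end))
    expect_identical(frags$length, frags$end - frags$start + 1L)
  }
})

test_that("sequential gastric-intestinal digestion reports products and intermediates", {
  out <- sequential_digest("FPHFDL", missed_cleavages = 1)
  expect_true(all(c("FPH", "FDL", "DL") %in% out))
  # no sites for any rule: the peptide itself survives
  expect_equal(sequential_digest("AAAA"), "AAAA")
  # complete digestion of FPL under the stated rules: pepsin cuts after
  # Phe1 (C-term F) and before Leu3 (N-term L)
  expect_equal(sequential_digest("FPL", missed_cleavages = 0),
               c("F", "L", "P"))
  # deterministic
  expect_identical(sequential_digest("FPHFDL"), sequential_digest("FPHFDL"))
})

test_that("released bioactive fragments are counted by set membership", {
  empty <- motif_db(character(0))
  expect_equal(count_released_bioactive("FPHFDL", "trypsin", empty), 0L)
  # protein equal to a single motif, rule with no sites
  db1 <- motif_db("AAAA")
  expect_equal(count_released_bioactive(
    "AAAA", cleavage_rule("k-only", c_terminal_of = "K"), db1), 1L)
  # planted motifs between trypsin sites: K|FPH (cut after H)|K|IA
  db <- motif_db(c("FPH", "IA"))
  expect_equal(count_released_bioactive("KFPHKIA", "trypsin", db), 2L)
})

test_that("enzyme registry round-trips through YAML", {
  path <- system.file("extdata", "enzymes.yaml", package = "peptiforge")
  rules <- read_enzyme_rules(path)
  defaults <- default_enzymes()
  expect_setequal(names(rules), names(defaults))
  for (nm in names(rules)) {
    expect_setequal(rules[[nm]]$c_terminal_of, defaults[[nm]]$c_terminal_of)
    expect_setequal(rules[[nm]]$n_terminal_of, defaults[[nm]]$n_terminal_of)
    expect_setequal(rules[[nm]]$blocked_p1prime,
                    defaults[[nm]]$blocked_p1prime)
  }
})
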