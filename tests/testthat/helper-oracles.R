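# Independent brute-force oracles and shared fixtures. Each oracle is a
# deliberately naive re-derivation of an operation from its definition, kept
# free of the package's code paths.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(min_len = 2, max_len = 30) {
  paste(sample(AA, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

random_rule <- function() {
  ct <- sample(AA, sample(0:4, 1))
  nt <- sample(AA, sample(0:4, 1))
  if (length(ct) == 0 && length(nt) == 0) ct <- sample(AA, 1)
  cleavage_rule("random", c_terminal_of = ct, n_terminal_of = nt)
}

# per-bond predicate evaluation, straight from the site definition
brute_sites <- function(sequence, rule) {
  res <- strsplit(sequence, "")[[1]]
  out <- integer(0)
  for (i in seq_len(length(res) - 1)) {
    hit <- (res[i] %in% rule$c_terminal_of) ||
      (res[i + 1] %in% rule$n_terminal_of)
    if (hit && !(res[i + 1] %in% rule$blocked_p1prime))
      out <- c(out, i)
  }
  out
}

# O(N*M*L) substring scan for the A-value numerator
brute_a_value <- function(sequence, motifs) {
  n <- nchar(sequence)
  a <- 0
  for (m in motifs) {
    k <- nchar(m)
    if (k > n) next
    for (s in seq_len(n - k + 1))
      if (substr(sequence, s, s + k - 1) == m) a <- a + 1
  }
  a / n
}

# second, loop-based implementation of the 27-component featurization
brute_featurize <- function(peptide, w = 0.05) {
  sc <- default_scales()
  res <- strsplit(peptide, "")[[1]]
  L <- length(res)
  f <- numeric(20)
  for (u in seq_len(20)) f[u] <- sum(res == AA[u]) / L
  h <- sc$hydrophobicity
  h <- (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  names(h) <- sc$residue
  theta <- 0
  if (L > 1) {
    for (i in seq_len(L - 1))
      theta <- theta + (h[[res[i + 1]]] - h[[res[i]]])^2
    theta <- theta / (L - 1)
  }
  props <- c("hydrophobicity", "hydrophilicity", "mass", "pk1", "pk2", "pi")
  means <- numeric(6)
  for (j in seq_along(props)) {
    vals <- sc[[props[j]]]
    names(vals) <- sc$residue
    means[j] <- mean(vals[res])
  }
  c(f / (1 + w * theta), w * theta / (1 + w * theta), means)
}

# row-by-row screening filter straight from the criteria statement
brute_filter <- function(rows, min_abundance = 1e7, max_length = 10,
                         min_score = 0.9) {
  keep <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    s <- rows$sequence[i]
    pos2 <- nchar(s) >= 2 && substr(s, 2, 2) %in% c("P", "A")
    keep[i] <- rows$abundance[i] > min_abundance &&
      nchar(s) < max_length && rows$score[i] > min_score && pos2
  }
  keep
}

# the nine identified peptides with their printed peak areas and scores
table1_candidates <- function() {
  data.frame(
    sequence = c("FPL", "YPW", "FPH", "FPHF", "FPHFD", "FPHFDL", "FPFA",
                 "HPYF", "YPWTQRFF"),
    abundance = c(2.27e7, 3.12e7, 1.02e9, 2.56e9, 8.32e8, 4.33e9, 1.28e7,
                  7.75e8, 2.26e8),
    score = c(0.9790, 0.9751, 0.9401, 0.9872, 0.9274, 0.9448, 0.9843,
              0.9396, 0.9556),
    stringsAsFactors = FALSE)
}

# small fully separable training set: disjoint residue alphabets
separable_peptides <- function(n_per_class = 150, seed = 7) {
  mk <- function(n, pool, pos2) vapply(seq_len(n), function(i) {
    L <- sample(3:8, 1)
    r <- sample(pool, L, replace = TRUE)
    r[2] <- pos2
    paste(r, collapse = "")
  }, character(1))
  set.seed(seed)
  data.frame(
    sequence = c(mk(n_per_class, c("A", "V", "L", "I", "F"), "P"),
                 mk(n_per_class, c("D", "E", "K", "N", "Q", "R"), "S")),
    label = rep(1:0, each = n_per_class),
    stringsAsFactors = FALSE)
}
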