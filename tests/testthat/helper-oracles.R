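# Independent oracles, deliberately written as straight-line textbook code
# with no shared machinery with the package internals.

# Gotoh local alignment (match/gap-in-seq/gap-in-profile states), plain R
# loops; returns the best local score. Gap of length k costs
# gap_open + k * gap_extend.
oracle_local_score <- function(pssm, codes, gap_open, gap_extend) {
  L <- nrow(pssm)
  n <- length(codes)
  NEG <- -1e9
  M <- matrix(0, L + 1, n + 1)
  X <- matrix(NEG, L + 1, n + 1)
  Y <- matrix(NEG, L + 1, n + 1)
  best <- 0
  for (i in 1:L) {
    for (j in 1:n) {
      s <- if (codes[j] >= 1) pssm[i, codes[j]] else 0
      m <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      M[i + 1, j + 1] <- max(0, m)
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

oracle_codes <- function(sequence) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  match(strsplit(sequence, "")[[1]], aa, nomatch = 0L)
}

random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Literal re-derivation of the classification verdict from ranked hits:
# 4-of-5 vote, then 3-of-3 vote, then the 5-orders-of-magnitude gap rule,
# then NBD-count architecture for ABC-B.
oracle_classify <- function(ranked, nbd_count) {
  lab <- ranked$subject_family
  lab[lab %in% c("BF", "BH")] <- "B"
  fam <- NA_character_; rule <- "NONE"
  if (nrow(ranked) >= 5) {
    for (f in setdiff(unique(lab[1:5]), "NONABC")) {
      if (sum(lab[1:5] == f) >= 4) { fam <- f; rule <- "VOTE_4OF5" }
    }
  }
  if (is.na(fam) && nrow(ranked) >= 3) {
    if (lab[1] != "NONABC" && lab[1] == lab[2] && lab[2] == lab[3]) {
      fam <- lab[1]; rule <- "VOTE_TOP3"
    }
  }
  if (is.na(fam) && nrow(ranked) >= 1 && lab[1] != "NONABC") {
    fire <- if (nrow(ranked) == 1) {
      TRUE
    } else if (ranked$evalue[2] == 0) {
      ranked$evalue[1] == 0 &&
        ranked$bitscore[1] - ranked$bitscore[2] >= 50
    } else {
      ranked$evalue[1] <= ranked$evalue[2] * 1e-5
    }
    if (fire) { fam <- lab[1]; rule <- "EVALUE_GAP" }
  }
  if (is.na(fam) || fam == "I") return(list(family = "EXCLUDED",
                                            rule = "NONE"))
  if (fam == "B") fam <- if (nbd_count >= 2) "BF" else "BH"
  list(family = fam, rule = rule)
}

# Tie-corrected Kruskal-Wallis H straight from the rank formula.
oracle_kw_h <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  Rsum <- tapply(r, groups, sum)
  nn <- tapply(r, groups, length)
  H0 <- 12 / (N * (N + 1)) * sum(Rsum^2 / nn) - 3 * (N + 1)
  tt <- as.numeric(table(values))
  H0 / (1 - sum(tt^3 - tt) / (N^3 - N))
}

# global (ungapped-ends) identity between equal-length sequences
pairwise_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}
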