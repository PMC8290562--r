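test_that("candidate filter keeps strictly sub-cutoff e-values", {
  hits <- tibble::tibble(protein_id = c("keep", "drop", "keep2"),
                         profile_id = "NBD", seq_start = 1L, seq_end = 50L,
                         full_seq_evalue = c(9.9, 10.0, 1e-5),
                         domain_ievalue = 1e-6, bitscore = 30)
  expect_setequal(filter_candidates(hits, 10), c("keep", "keep2"))
  expect_equal(filter_candidates(hits[0, ]), character())
  # best e-value per protein decides
  two <- tibble::tibble(protein_id = "p", profile_id = "NBD",
                        seq_start = 1L, seq_end = 50L,
                        full_seq_evalue = c(50, 0.5),
                        domain_ievalue = 1, bitscore = 10)
  expect_equal(filter_candidates(two, 10), "p")
})

test_that("profile construction gives log-odds favouring observed residues", {
  seqs <- c("GGGGGGGGGGAA", "GGGGGGGGGGAA", "GGGGGGGGGGAC",
            "GGGGGGGGGGAA", "GGGGGGGGGGAA")
  prof <- build_profile(seqs, pseudocount = 0.1)
  expect_equal(prof$length, 12)
  expect_gt(prof$match_scores[1, "G"], prof$match_scores[1, "W"])
  expect_error(build_profile(seqs[1]), "at least 2")

  # columns with >50% gaps are removed before scoring (2 of 13 here)
  gappy <- c("GG-GGGGGGGG-A", "GG-GGGGGGGGGA", "GGCGGGGGGGG-A")
  expect_equal(build_profile(gappy, 0.1)$length, 11)

  # identical sequences: the consensus residue maximizes every column
  same <- rep("MKVLSTGAQWER", 3)
  p2 <- build_profile(same, pseudocount = 0.1)
  cons <- strsplit(same[1], "")[[1]]
  for (i in seq_along(cons)) {
    expect_equal(names(which.max(p2$match_scores[i, ])), cons[i])
  }
})

test_that("profile serialization round-trips", {
  prof <- nbd_profile(7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$length, prof$length)
  expect_equal(back$gap_open, prof$gap_open)
  expect_equal(back$score_threshold, prof$score_threshold)
  expect_equal(back$match_scores, prof$match_scores, tolerance = 1e-9)
})

test_that("planted consensus domains are recovered at exact coordinates", {
  arch <- make_family_archetypes(3)
  prof <- nbd_profile(3)
  withr::with_seed(11, {
    rec <- tibble::tibble(
      protein_id = "one",
      sequence = paste0(random_protein(49), arch$nbd[["E"]],
                        random_protein(60)))
  })
  h <- scan_protein(prof, rec)
  expect_equal(nrow(h), 1)
  expect_equal(h$seq_start, 50)
  expect_equal(h$seq_end, 49 + 180)

  # k planted copies -> k disjoint hits, for k = 1..3
  for (k in 1:3) {
    withr::with_seed(20 + k, {
      blocks <- paste0(
        vapply(seq_len(k), function(i) {
          paste0(arch$nbd[["G"]], random_protein(60))
        }, character(1)), collapse = "")
      rec <- tibble::tibble(protein_id = "multi",
                            sequence = paste0(random_protein(50), blocks))
    })
    h <- scan_protein(prof, rec)
    expect_equal(nrow(h), k)
    ints <- h[order(h$seq_start), ]
    if (k > 1) {
      expect_true(all(ints$seq_start[-1] > ints$seq_end[-k]))
    }
  }
})

test_that("random proteins yield no hits at the reporting threshold", {
  prof <- nbd_profile(3)
  withr::with_seed(42, {
    for (i in 1:5) {
      rec <- tibble::tibble(protein_id = "r",
                            sequence = random_protein(300))
      expect_equal(nrow(scan_protein(prof, rec)), 0)
    }
  })
})

test_that("local profile scan matches the dynamic-programming oracle", {
  arch <- make_family_archetypes(5)
  small <- build_profile(substr(unname(arch$nbd), 1, 40),
                         score_threshold = 0)
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(30:200, 1)
      seqn <- if (i %% 3 == 0) {
        # embed a (mutated) profile fragment so positive scores occur
        paste0(random_protein(sample(5:30, 1)),
               mutate_seq(substr(arch$nbd[[sample(9, 1)]], 1, 40), 0.2),
               random_protein(sample(5:30, 1)))
      } else {
        random_protein(n)
      }
      codes <- oracle_codes(seqn)
      got <- abcfam:::cpp_pssm_local(small$match_scores, codes,
                                     small$consensus, -10, -1)
      want <- oracle_local_score(small$match_scores, codes, -10, -1)
      expect_equal(got$score, want, tolerance = 1e-9)
    }
  })
})

test_that("NBD counting resolves overlaps and ignores weak domains", {
  mk <- function(starts, ends, iev, bits = NULL) {
    tibble::tibble(protein_id = "p", profile_id = "NBD",
                   seq_start = starts, seq_end = ends,
                   full_seq_evalue = iev, domain_ievalue = iev,
                   bitscore = bits %||% -log10(iev))
  }
  expect_equal(count_nbds(mk(c(10L, 300L), c(190L, 480L),
                             c(1e-40, 1e-30)))$count, 2)
  expect_equal(count_nbds(mk(10L, 190L, 1e-40))$count, 1)
  # 90% overlap of the shorter interval -> one NBD
  expect_equal(count_nbds(mk(c(10L, 28L), c(190L, 208L),
                             c(1e-40, 1e-35)))$count, 1)
  # weak second domain (i-Evalue above the 0.01 gate) is not counted
  expect_equal(count_nbds(mk(c(10L, 300L), c(190L, 480L),
                             c(1e-40, 0.02)))$count, 1)
  # count is invariant to input order
  h <- mk(c(300L, 10L), c(480L, 190L), c(1e-30, 1e-40))
  expect_equal(count_nbds(h)$count, count_nbds(h[2:1, ])$count)
  expect_error(count_nbds(dplyr::mutate(h, protein_id = c("a", "b"))),
               "one protein")
})

test_that("scan scores degrade monotonically in expectation with mutation load", {
  arch <- make_family_archetypes(6)
  prof <- nbd_profile(6)
  rates <- c(0, 0.15, 0.35)
  mean_bits <- withr::with_seed(7, {
    vapply(rates, function(r) {
      bits <- vapply(1:20, function(i) {
        rec <- tibble::tibble(
          protein_id = "m",
          sequence = paste0(random_protein(30),
                            mutate_seq(arch$nbd[["A"]], r),
                            random_protein(30)))
        h <- scan_protein(prof, rec)
        if (nrow(h) == 0) 0 else max(h$bitscore)
      }, numeric(1))
      mean(bits)
    }, numeric(1))
  })
  expect_true(all(diff(mean_bits) < 0))
})
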