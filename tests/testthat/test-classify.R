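test_that("hit ranking sorts by e-value with bitscore and id tie-breaks", {
  h <- tibble::tibble(query_id = "q",
                      subject_id = c("s1", "s1", "s2", "s3"),
                      subject_family = c("C", "C", "G", "A"),
                      percent_identity = 50,
                      evalue = c(1e-20, 1e-10, 1e-20, 1e-30),
                      bitscore = c(90, 50, 95, 120))
  r <- rank_hits(h)
  expect_equal(r$subject_id, c("s3", "s2", "s1"))  # dedup keeps best s1
  expect_equal(r$evalue[r$subject_id == "s1"], 1e-20)
  # equal e-values: higher bitscore first; then lexicographic id
  h2 <- tibble::tibble(query_id = "q", subject_id = c("b", "a"),
                       subject_family = "C", percent_identity = 50,
                       evalue = 1e-10, bitscore = c(50, 80))
  expect_equal(rank_hits(h2)$subject_id, c("a", "b"))
  expect_equal(nrow(rank_hits(h[0, ])), 0)
})

test_that("family vote follows the 4-of-5 then 3-of-3 rules", {
  expect_equal(vote_family(sim_hits(c("C", "C", "C", "G", "C"))),
               list(family = "C", rule = "VOTE_4OF5"))
  expect_equal(vote_family(sim_hits(c("G", "G", "G", "A", "BF"))),
               list(family = "G", rule = "VOTE_TOP3"))
  expect_equal(vote_family(sim_hits(c("A", "BF", "C", "D", "E")))$rule,
               "NONE")
  # a non-ABC consensus never names a family
  expect_equal(vote_family(sim_hits(rep("NONABC", 5)))$rule, "NONE")
  # BF and BH reference hits reinforce each other as the B super-label
  expect_equal(vote_family(sim_hits(c("BF", "BH", "BF", "G", "BF")))$family,
               "B")
  # with only 4 hits the 4-of-5 rule cannot fire, the top-3 rule can
  expect_equal(vote_family(sim_hits(c("C", "C", "C", "G"))),
               list(family = "C", rule = "VOTE_TOP3"))
  expect_equal(vote_family(sim_hits(c("C", "C", "G", "C")))$rule, "NONE")
})

test_that("e-value gap rule needs five orders of magnitude", {
  g6 <- sim_hits(c("G", "C"), evalues = c(1e-40, 1e-34))
  expect_equal(gap_rule(g6), list(family = "G", rule = "EVALUE_GAP"))
  g3 <- sim_hits(c("G", "C"), evalues = c(1e-40, 1e-37))
  expect_equal(gap_rule(g3)$rule, "NONE")
  # boundary is inclusive
  g5 <- sim_hits(c("G", "C"), evalues = c(1e-39, 1e-34))
  expect_equal(gap_rule(g5)$family, "G")
  # single hits: family only if the subject is an ABC transporter
  expect_equal(gap_rule(sim_hits("NONABC"))$rule, "NONE")
  expect_equal(gap_rule(sim_hits("H"))$family, "H")
  # degenerate zero e-values fall back to a 50-bit score margin
  z <- sim_hits(c("G", "C"), evalues = c(0, 0), bitscores = c(900, 820))
  expect_equal(gap_rule(z)$family, "G")
  z2 <- sim_hits(c("G", "C"), evalues = c(0, 0), bitscores = c(900, 880))
  expect_equal(gap_rule(z2)$rule, "NONE")
  z3 <- sim_hits(c("G", "C"), evalues = c(1e-200, 0),
                 bitscores = c(900, 700))
  expect_equal(gap_rule(z3)$rule, "NONE")
})

test_that("family assignment resolves ABC-B architecture by NBD count", {
  b_vote <- sim_hits(c("BF", "BH", "BF", "BF", "BH"))
  expect_equal(assign_family(b_vote, nbd_count = 2)$family, "BF")
  expect_equal(assign_family(b_vote, nbd_count = 1)$family, "BH")
  expect_equal(assign_family(b_vote, nbd_count = 2)$rule_used, "VOTE_4OF5")
  # fall-through to exclusion
  none <- sim_hits(c("A", "BF", "C", "D", "E"),
                   evalues = rep(1e-20, 5), bitscores = rep(80, 5))
  call <- assign_family(none, 1)
  expect_equal(call$family, "EXCLUDED")
  expect_equal(call$rule_used, "NONE")
  # ABC-I consensus is excluded outright
  i_vote <- sim_hits(c("I", "I", "I", "I", "I"))
  expect_equal(assign_family(i_vote, 1)$family, "EXCLUDED")
  # no hits at all
  expect_equal(assign_family(sim_hits(character(0)), 0)$family, "EXCLUDED")
})

test_that("vote precedes the gap rule and ties never change the verdict", {
  # evalues that would also satisfy the gap rule: provenance must say vote
  h <- sim_hits(c("C", "C", "C", "C", "G"),
                evalues = c(1e-60, 1e-40, 1e-39, 1e-38, 1e-20))
  expect_equal(assign_family(h, 1)$rule_used, "VOTE_4OF5")
  # permuting rows with equal sort keys leaves the call unchanged
  tied <- sim_hits(c("C", "G", "C", "C", "C", "A"),
                   evalues = rep(1e-30, 6), bitscores = rep(77, 6))
  calls <- lapply(list(tied, tied[sample(6), ], tied[6:1, ]),
                  function(x) assign_family(rank_hits(x), 1))
  expect_length(unique(vapply(calls, function(c) c$family, "")), 1)
})

test_that("length filter excludes classified fragments under 250 aa", {
  records <- tibble::tibble(
    protein_id = c("short", "exact", "long", "was_excluded"),
    species_id = "sp",
    sequence = c(strrep("M", 249), strrep("M", 250), strrep("M", 400),
                 strrep("M", 100)))
  calls <- tibble::tibble(
    protein_id = records$protein_id,
    family = c("C", "C", "G", "EXCLUDED"),
    rule_used = c("VOTE_4OF5", "VOTE_4OF5", "EVALUE_GAP", "NONE"),
    top_hit_id = "x", top_evalue = 1e-50, nbd_count = 1L,
    length_filtered = FALSE)
  out <- apply_length_filter(calls, records)
  expect_equal(out$family, c("EXCLUDED", "C", "G", "EXCLUDED"))
  expect_equal(out$rule_used[1], "VOTE_4OF5")  # provenance preserved
  expect_true(out$length_filtered[1])
  expect_false(any(out$length_filtered[2:4]))
  expect_error(apply_length_filter(calls, records[1:2, ]), "no sequence")
})
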