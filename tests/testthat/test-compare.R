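test_that("H statistic matches the worked two-group example and symmetry", {
  d <- tibble::tibble(group = c("A", "A", "B", "B"), value = c(1, 2, 3, 4))
  kw <- kruskal_wallis(d, letters = FALSE)
  expect_equal(kw$H, 2.4, tolerance = 1e-12)
  expect_equal(kw$df, 1)

  same <- tibble::tibble(group = rep(c("A", "B"), each = 4),
                         value = rep(c(1, 5, 7, 9), 2))
  expect_equal(kruskal_wallis(same, letters = FALSE)$H, 0, tolerance = 1e-12)

  flat <- tibble::tibble(group = rep(c("A", "B"), each = 3), value = 2)
  kwf <- kruskal_wallis(flat, letters = FALSE)
  expect_equal(kwf$H, 0)
  expect_equal(kwf$p_value, 1)
})

test_that("H agrees with independent oracles on random data with ties", {
  withr::with_seed(123, {
    for (i in 1:100) {
      k <- sample(2:5, 1)
      d <- tibble::tibble(
        group = rep(sprintf("g%d", seq_len(k)),
                    times = sample(4:12, k, replace = TRUE)))
      # mix of continuous and tied integer data
      d$value <- if (i %% 2 == 0) rnorm(nrow(d)) else rpois(nrow(d), 4)
      kw <- kruskal_wallis(d, letters = FALSE)
      expect_equal(kw$H, oracle_kw_h(d$value, d$group), tolerance = 1e-9)
      ref <- stats::kruskal.test(value ~ factor(group), data = d)
      expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(kw$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("H is invariant under monotone transforms of the values", {
  withr::with_seed(5, {
    d <- make_grouped_counts(5, k_groups = 3, n_per_group = 8)
    h1 <- kruskal_wallis(d, letters = FALSE)$H
    d2 <- dplyr::mutate(d, value = exp(value / 2))
    expect_equal(kruskal_wallis(d2, letters = FALSE)$H, h1,
                 tolerance = 1e-12)
    d3 <- dplyr::mutate(d, value = value + 1000)
    expect_equal(kruskal_wallis(d3, letters = FALSE)$H, h1,
                 tolerance = 1e-12)
  })
})

test_that("identically-drawn groups share one letter", {
  d <- make_grouped_counts(31, k_groups = 4, n_per_group = 10,
                           base_mean = 6)
  letters_out <- posthoc_letters(d)
  expect_true(all(letters_out$letter == letters_out$letter[1]))
})

test_that("fully separated groups get distinct letters", {
  # exact rank-sum oracle: with complete separation at n = 10 vs 10 the
  # two-sided exact p is 2 / choose(20, 10), far below alpha
  expect_lt(2 / choose(20, 10), 0.05)
  d <- tibble::tibble(group = rep(c("lo", "hi"), each = 10),
                      value = c(1:10, 101:110))
  lt <- posthoc_letters(d)
  expect_equal(length(unique(lt$letter)), 2)

  # three well-separated groups: three letters, contiguous over rank order
  d3 <- tibble::tibble(group = rep(c("a", "b", "c"), each = 10),
                       value = c(1:10, 101:110, 201:210))
  lt3 <- posthoc_letters(d3)
  expect_equal(length(unique(lt3$letter)), 3)
})

test_that("letters are relabelling-symmetric and shift-invariant", {
  d <- make_grouped_counts(17, k_groups = 4, n_per_group = 8,
                           base_mean = 4, shifted_group = 2, shift = 6)
  lt <- posthoc_letters(d)
  # rename groups: the letter partition must be identical up to names
  d2 <- dplyr::mutate(d, group = chartr("1234", "4321", group))
  lt2 <- posthoc_letters(d2)
  key <- function(x) {
    m <- setNames(x$letter, x$group)
    unname(m[order(names(m))])
  }
  expect_equal(sort(table(lt$letter)), sort(table(lt2$letter)),
               ignore_attr = TRUE)
  d3 <- dplyr::mutate(d, value = value + 7)
  expect_equal(posthoc_letters(d3), lt)

  # letters are contiguous along the mean-rank ordering of groups
  ord <- lt$group[order(-lt$mean_rank)]
  for (l in unique(unlist(strsplit(lt$letter, "")))) {
    has <- vapply(ord, function(g) {
      grepl(l, lt$letter[lt$group == g], fixed = TRUE)
    }, logical(1))
    expect_equal(sum(rle(has)$values), 1)  # one contiguous block
  }
})

test_that("per-family tests flag a planted expansion and only that", {
  mat <- make_family_matrix(41, n_per_order = 12,
                            shifted_order = "Lepidoptera",
                            shifted_family = "BF", shift = 8)
  res <- family_size_tests(mat)
  s <- res$summary
  expect_true(s$p_adjusted[s$family == "BF"] < 0.05)
  quiet <- s$family[!(s$family %in% c("BF", "total"))]
  expect_true(all(s$p_adjusted[s$family %in% quiet] > 0.05))
  # Lepidoptera must not share a letter with every other order for BF
  g <- res$results$BF$groups
  lep <- g$letter[g$group == "Lepidoptera"]
  others <- g$letter[g$group != "Lepidoptera"]
  expect_true(any(!mapply(function(a, b) {
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  }, lep, others)))
})

test_that("degenerate family matrices are handled explicitly", {
  mat <- make_family_matrix(42, n_per_order = 4)
  mat$D <- 2L  # constant column
  res <- family_size_tests(mat)
  expect_equal(res$summary$H[res$summary$family == "D"], 0)
  expect_error(family_size_tests(mat[0, ]), "empty")
  # groups under the minimum size are dropped with a warning
  small <- mat[c(1:4, 5:8, 9:10), ]  # third order has only 2 species
  expect_warning(family_size_tests(small, min_group_n = 3),
                 "fewer than")
})

test_that("null rejection rate of the chi-square approximation is nominal", {
  # moderate replicate count here; the acceptance suite runs the full one
  withr::with_seed(77, {
    rej <- mean(vapply(1:2000, function(i) {
      v <- rnorm(40)
      g <- rep(1:4, each = 10)
      abcfam:::kw_core(v, g)$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("tidy and glance expose the test results as tibbles", {
  d <- make_grouped_counts(3, k_groups = 3, n_per_group = 6)
  kw <- kruskal_wallis(d)
  expect_s3_class(tidy(kw), "tbl_df")
  expect_named(glance(kw), c("H", "df", "p_value", "N", "k"))
  expect_equal(nrow(tidy(kw)), 3)
  expect_true(all(c("mean_rank", "letter") %in% names(tidy(kw))))
})
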