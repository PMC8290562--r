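# Rank-based comparison of gene-family sizes across taxonomic groups:
# tie-corrected Kruskal-Wallis omnibus test, Conover-style pairwise
# comparisons on rank means with Bonferroni adjustment, and a compact
# letter display summarizing which groups differ.

# lean internal core shared by the user functions and by simulation loops
kw_core <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  k <- length(unique(groups))
  r <- rank(values)
  n_i <- tapply(r, groups, length)
  R_i <- tapply(r, groups, sum)
  H0 <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C <= 0) 0 else H0 / C
  H <- max(H, 0)
  p <- if (C <= 0) 1 else pchisq(H, df = k - 1, lower.tail = FALSE)
  list(H = H, df = k - 1L, p_value = p, N = N, k = k, ranks = r,
       groups = groups, n = n_i, mean_rank = R_i / n_i)
}

check_grouped <- function(data, value, group) {
  values <- data[[value]]
  groups <- data[[group]]
  if (is.null(values) || is.null(groups)) {
    abort(paste0("columns '", value, "' and '", group, "' are required"))
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  if (length(unique(groups)) < 2) abort("need at least 2 groups")
  if (length(values) < 3) abort("need at least 3 observations in total")
  list(values = values, groups = groups)
}

#' Kruskal-Wallis rank test over grouped family sizes
#'
#' Tie-corrected H statistic with mid-ranks,
#' `H = [12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)] / [1 - sum(t^3-t)/(N^3-N)]`,
#' compared against the chi-square distribution with k-1 degrees of
#' freedom. When every observation is identical the statistic is 0 with
#' p = 1.
#'
#' @param data A data frame in long format.
#' @param value,group Column names (strings) of the numeric values and the
#'   group labels.
#' @param alpha Significance level used for the post-hoc letters.
#' @param p_adjust Pairwise adjustment for the letters: `"bonferroni"`
#'   (default, alpha split over all k(k-1)/2 pairs) or `"none"`.
#' @param letters Compute the compact letter display (default TRUE).
#' @return An object of class `abc_kw` with the statistic, per-group mean
#'   ranks and letters; see [tidy.abc_kw()] and [glance.abc_kw()].
#' @export
kruskal_wallis <- function(data, value = "value", group = "group",
                           alpha = 0.05,
                           p_adjust = c("bonferroni", "none"),
                           letters = TRUE) {
  p_adjust <- match.arg(p_adjust)
  gv <- check_grouped(data, value, group)
  core <- kw_core(gv$values, gv$groups)
  out <- structure(
    list(H = core$H, df = core$df, p_value = core$p_value,
         N = core$N, k = core$k,
         groups = tibble(group = names(core$n),
                         n = as.integer(core$n),
                         mean_rank = as.numeric(core$mean_rank)),
         alpha = alpha, p_adjust = p_adjust, core = core),
    class = "abc_kw")
  if (letters) {
    out$groups$letter <- posthoc_letters_core(core, alpha, p_adjust)
  }
  out
}

#' @export
print.abc_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (N = %d)\n",
              x$H, x$df, x$p_value, x$N))
  print(x$groups)
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x An `abc_kw` object.
#' @param ... Unused.
#' @method tidy abc_kw
#' @export
tidy.abc_kw <- function(x, ...) x$groups

#' @rdname kruskal_wallis
#' @method glance abc_kw
#' @export
glance.abc_kw <- function(x, ...) {
  tibble(H = x$H, df = x$df, p_value = x$p_value, N = x$N, k = x$k)
}

# Conover-style pairwise comparison of rank means. Two groups differ when
# |Rbar_i - Rbar_j| > t_{1-a/2, N-k} * sqrt(S2 * (N-1-H)/(N-k) *
# (1/n_i + 1/n_j)), with S2 the variance of all ranks and a the
# (optionally Bonferroni-split) significance level.
conover_pairs <- function(core, alpha, p_adjust) {
  g <- names(core$n)
  k <- core$k; N <- core$N
  m <- k * (k - 1) / 2
  a <- if (p_adjust == "bonferroni") alpha / m else alpha
  r <- core$ranks
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale <- S2 * (N - 1 - core$H) / (N - k)
  scale <- max(scale, 0)
  tcrit <- qt(1 - a / 2, df = N - k)
  pairs <- utils::combn(g, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    diff <- abs(core$mean_rank[[i]] - core$mean_rank[[j]])
    crit <- tcrit * sqrt(scale * (1 / core$n[[i]] + 1 / core$n[[j]]))
    tibble(group1 = i, group2 = j, rank_diff = diff, critical = crit,
           significant = is.finite(crit) && diff > crit)
  })
}

# insert-and-absorb compact letter display over groups ordered by
# descending mean rank
cld_insert_absorb <- function(group_order, sig_pairs) {
  cols <- list(group_order)
  for (p in seq_len(nrow(sig_pairs))) {
    i <- sig_pairs$group1[p]; j <- sig_pairs$group2[p]
    newcols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) {
      for (b in seq_along(newcols)) {
        if (a != b && keep[a] &&
            all(newcols[[a]] %in% newcols[[b]]) &&
            (length(newcols[[a]]) < length(newcols[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- newcols[keep]
  }
  # order columns by the best-ranked group they contain, letter them
  first_pos <- vapply(cols, function(col) {
    min(match(col, group_order))
  }, numeric(1))
  cols <- cols[order(first_pos)]
  lab <- stats::setNames(rep("", length(group_order)), group_order)
  for (ci in seq_along(cols)) {
    for (gr in cols[[ci]]) lab[gr] <- paste0(lab[gr], letters[ci])
  }
  lab
}

posthoc_letters_core <- function(core, alpha, p_adjust) {
  pairs <- conover_pairs(core, alpha, p_adjust)
  ord <- names(sort(unlist(core$mean_rank), decreasing = TRUE))
  lab <- cld_insert_absorb(ord, pairs[pairs$significant, , drop = FALSE])
  unname(lab[names(core$n)])
}

#' Compact letter display from pairwise rank comparisons
#'
#' Groups sharing a letter are not significantly different in the
#' Conover-style pairwise comparison at level `alpha` (Bonferroni-split
#' over pairs by default). Letters are assigned over groups sorted by
#' descending mean rank with the insert-and-absorb algorithm.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble with `group`, `n`, `mean_rank`, `letter`.
#' @export
posthoc_letters <- function(data, value = "value", group = "group",
                            alpha = 0.05,
                            p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  kw <- kruskal_wallis(data, value, group, alpha, p_adjust, letters = TRUE)
  kw$groups
}

#' Per-family Kruskal-Wallis tests over a family-size matrix
#'
#' Runs one test per ABC family (plus the total) with taxonomic order as
#' the grouping variable. Orders with fewer than `min_group_n` species are
#' dropped with a warning; families left with fewer than 2 eligible orders
#' are skipped. P-values are additionally Bonferroni-adjusted across the
#' family-level tests.
#'
#' @param matrix An `abc_family_matrix` (or any tibble with family count
#'   columns and a `taxon_order` column).
#' @param min_group_n Minimum species per taxonomic order.
#' @param alpha Significance level for the letters.
#' @param p_adjust Pairwise adjustment within each family's letters.
#' @return A list with `summary` (tibble: family, H, df, p, p_adjusted,
#'   n_groups) and `results` (named list of `abc_kw` objects).
#' @export
family_size_tests <- function(matrix, min_group_n = 3, alpha = 0.05,
                              p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(matrix) == 0) abort("empty family-size matrix")
  if (!"taxon_order" %in% names(matrix)) {
    abort("matrix must carry a taxon_order column")
  }
  fams <- intersect(c(ABC_FAMILIES, "total"), names(matrix))
  grp_n <- table(matrix$taxon_order)
  small <- names(grp_n)[grp_n < min_group_n]
  if (length(small) > 0) {
    warn(paste0("dropping order(s) with fewer than ", min_group_n,
                " species: ", paste(small, collapse = ", ")))
  }
  dat <- matrix[!(matrix$taxon_order %in% small), , drop = FALSE]
  results <- list()
  for (f in fams) {
    sub <- tibble(value = dat[[f]], group = dat$taxon_order)
    if (length(unique(sub$group)) < 2) {
      warn(paste0("family ", f, ": fewer than 2 eligible orders, skipped"))
      next
    }
    results[[f]] <- kruskal_wallis(sub, "value", "group", alpha, p_adjust)
  }
  if (length(results) == 0) abort("no family had >= 2 eligible orders")
  m <- length(results)
  summary <- purrr::map_dfr(names(results), function(f) {
    x <- results[[f]]
    tibble(family = f, H = x$H, df = x$df, p = x$p_value,
           p_adjusted = min(1, x$p_value * m), n_groups = x$k)
  })
  list(summary = summary, results = results)
}

#' Write family-size test results to TSV
#'
#' One row per family and taxonomic order with the omnibus statistic,
#' adjusted p-value, per-group mean rank and letter.
#'
#' @param tests Output of [family_size_tests()].
#' @param path Output path.
#' @export
write_family_tests <- function(tests, path) {
  tab <- purrr::map_dfr(names(tests$results), function(f) {
    x <- tests$results[[f]]
    s <- tests$summary[tests$summary$family == f, ]
    g <- x$groups
    tibble(family = f, H = x$H, df = x$df, p = x$p_value,
           p_adjusted = s$p_adjusted, group = g$group, n = g$n,
           mean_rank = g$mean_rank,
           letter = g$letter %||% NA_character_)
  })
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
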