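# Family assignment from ranked similarity hits: best-hit voting first,
# then an e-value-gap fallback; ABC-B architecture resolved by NBD count;
# short fragments removed last.

# voting super-label: reference ABC-B records of either architecture count
# as one family "B"; the NBD count decides BF vs BH afterwards.
vote_label <- function(family) ifelse(family %in% c("BF", "BH"), "B", family)

#' Rank and deduplicate similarity hits for one query
#'
#' Sorts by ascending e-value, breaking ties by descending bitscore then
#' lexicographic subject id, and keeps only the best hit per subject.
#'
#' @param hits Similarity-hit tibble for a single query.
#' @return The ranked, per-subject-deduplicated tibble.
#' @export
rank_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$query_id)) != 1) {
    abort("rank_hits expects hits for a single query")
  }
  hits |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$subject_id) |>
    distinct(.data$subject_id, .keep_all = TRUE)
}

#' Family vote over the top similarity hits
#'
#' If at least 5 ranked hits exist and 4 or more of the top 5 share one
#' family, that family wins; otherwise, if at least 3 hits exist and the
#' top 3 all share one family, that family wins. Non-ABC reference hits
#' participate in the tallies but a non-ABC consensus returns no family.
#'
#' @param ranked Output of [rank_hits()].
#' @return A list `(family, rule)` where `family` is the winning voting
#'   label (`"B"` possible) or `NA`, and `rule` is `"VOTE_4OF5"`,
#'   `"VOTE_TOP3"` or `"NONE"`.
#' @export
vote_family <- function(ranked) {
  labels <- vote_label(ranked$subject_family)
  if (length(labels) >= 5) {
    top5 <- labels[1:5]
    tab <- sort(table(top5), decreasing = TRUE)
    win <- names(tab)[1]
    if (tab[1] >= 4 && win != "NONABC") {
      return(list(family = win, rule = "VOTE_4OF5"))
    }
  }
  if (length(labels) >= 3) {
    top3 <- labels[1:3]
    if (length(unique(top3)) == 1 && top3[1] != "NONABC") {
      return(list(family = top3[1], rule = "VOTE_TOP3"))
    }
  }
  list(family = NA_character_, rule = "NONE")
}

#' E-value-gap fallback rule
#'
#' Fires when the top hit is an ABC reference and its e-value is at least
#' five orders of magnitude below the next-best hit's (to a different
#' subject): `e1 <= e2 * 1e-5`, boundary inclusive. With a single hit the
#' rule fires whenever that hit is ABC. When the second e-value underflows
#' to 0 the ratio is undefined; the rule then requires the top e-value to
#' be 0 as well and the top bitscore to exceed the second by at least 50
#' bits.
#'
#' @param ranked Output of [rank_hits()].
#' @return A list `(family, rule)` as in [vote_family()], with rule
#'   `"EVALUE_GAP"` or `"NONE"`.
#' @export
gap_rule <- function(ranked) {
  none <- list(family = NA_character_, rule = "NONE")
  if (nrow(ranked) == 0) return(none)
  top_fam <- vote_label(ranked$subject_family[1])
  if (top_fam == "NONABC") return(none)
  hit <- list(family = top_fam, rule = "EVALUE_GAP")
  if (nrow(ranked) == 1) return(hit)
  e1 <- ranked$evalue[1]; e2 <- ranked$evalue[2]
  if (e2 == 0) {
    if (e1 == 0 && (ranked$bitscore[1] - ranked$bitscore[2]) >= 50) {
      return(hit)
    }
    return(none)
  }
  if (e1 <= e2 * 1e-5) hit else none
}

#' Assign an ABC family to one candidate
#'
#' Applies the vote first, then the e-value-gap rule; candidates passing
#' neither are excluded. A winning ABC-B label is resolved to the full
#' transporter (BF) when the protein carries two or more NBDs, otherwise
#' the half transporter (BH). A winning ABC-I label is excluded outright.
#'
#' @param ranked Output of [rank_hits()] for the candidate.
#' @param nbd_count Number of NBDs detected on the candidate (from
#'   [count_nbds()]).
#' @return One-row family-call tibble: `protein_id`, `family` (A, BF, BH,
#'   C-H or `"EXCLUDED"`), `rule_used`, `top_hit_id`, `top_evalue`,
#'   `nbd_count`, `length_filtered`.
#' @export
assign_family <- function(ranked, nbd_count) {
  pid <- if (nrow(ranked) > 0) ranked$query_id[1] else NA_character_
  verdict <- vote_family(ranked)
  if (verdict$rule == "NONE") verdict <- gap_rule(ranked)
  fam <- verdict$family
  rule <- verdict$rule
  if (is.na(fam) || fam == "I") {
    fam <- "EXCLUDED"
    rule <- "NONE"
  } else if (fam == "B") {
    fam <- if (nbd_count >= 2) "BF" else "BH"
  }
  tibble(protein_id = pid, family = fam, rule_used = rule,
         top_hit_id = if (nrow(ranked) > 0) ranked$subject_id[1] else "",
         top_evalue = if (nrow(ranked) > 0) ranked$evalue[1] else NA_real_,
         nbd_count = as.integer(nbd_count), length_filtered = FALSE)
}

#' Exclude short fragments
#'
#' Classified proteins shorter than `min_len` residues are demoted to
#' `EXCLUDED` (strictly-under comparison; the rule that classified them is
#' preserved and `length_filtered` set). Short fragments of real
#' transporters otherwise inflate family counts.
#'
#' @param calls Family-call tibble.
#' @param records Proteome tibble with sequences for every call.
#' @param min_len Minimum retained length, in residues.
#' @return The updated calls tibble.
#' @export
apply_length_filter <- function(calls, records, min_len = 250) {
  if (nrow(calls) == 0) return(calls)
  idx <- match(calls$protein_id, records$protein_id)
  if (anyNA(idx)) {
    abort(paste0("no sequence record for: ",
                 paste(calls$protein_id[is.na(idx)], collapse = ", ")))
  }
  len <- nchar(records$sequence[idx])
  short <- calls$family != "EXCLUDED" & len < min_len
  calls |>
    mutate(length_filtered = .data$length_filtered | short,
           family = ifelse(short, "EXCLUDED", .data$family))
}

#' Classify a set of candidates
#'
#' Convenience wrapper: ranks hits per query, computes NBD counts from the
#' domain hits and assigns a family to every candidate (candidates with no
#' similarity hits are excluded with rule `NONE`).
#'
#' @param candidate_ids Character vector of candidate protein ids.
#' @param sim_hits Similarity-hit tibble (all queries).
#' @param domain_hits Domain-hit tibble (all proteins).
#' @param domain_evalue_cutoff,max_overlap_frac Passed to [count_nbds()].
#' @return Family-call tibble, one row per candidate.
#' @export
classify_candidates <- function(candidate_ids, sim_hits, domain_hits,
                                domain_evalue_cutoff = 0.01,
                                max_overlap_frac = 0.5) {
  purrr::map_dfr(candidate_ids, function(pid) {
    ranked <- rank_hits(sim_hits[sim_hits$query_id == pid, , drop = FALSE])
    nbd <- count_nbds(domain_hits[domain_hits$protein_id == pid, ,
                                  drop = FALSE],
                      domain_evalue_cutoff = domain_evalue_cutoff,
                      max_overlap_frac = max_overlap_frac)
    call <- assign_family(ranked, nbd$count)
    call$protein_id <- pid
    call
  })
}
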