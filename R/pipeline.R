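# Orchestration: per-species scans, the BUSCO quality gate, aggregation
# into a species x family count matrix, and benchmarking against
# literature counts.

#' Pipeline configuration
#'
#' Collects every threshold of the scan chain with its default: candidate
#' e-value < 10 (sequence level, permissive), similarity e-value < 1e-5,
#' per-domain independent e-value < 0.01 for NBD counting, maximum NBD
#' interval overlap 0.5 of the shorter interval, minimum length 250
#' residues, BUSCO single-copy completeness >= 80%.
#'
#' @param candidate_evalue,sim_evalue,domain_evalue_cutoff Strict e-value
#'   cutoffs for the candidate gate, similarity hits and NBD counting.
#' @param max_overlap_frac Overlap tolerance in NBD counting.
#' @param min_len Length filter, residues.
#' @param busco_threshold BUSCO completeness gate, percent.
#' @return A list of class `abc_config`.
#' @export
abc_config <- function(candidate_evalue = 10, sim_evalue = 1e-5,
                       domain_evalue_cutoff = 0.01, max_overlap_frac = 0.5,
                       min_len = 250, busco_threshold = 80) {
  structure(list(candidate_evalue = candidate_evalue,
                 sim_evalue = sim_evalue,
                 domain_evalue_cutoff = domain_evalue_cutoff,
                 max_overlap_frac = max_overlap_frac,
                 min_len = min_len, busco_threshold = busco_threshold),
            class = "abc_config")
}

#' BUSCO completeness gate
#'
#' Species whose proteome single-copy completeness is strictly below the
#' threshold are removed: incomplete protein sets would bias family counts
#' downward.
#'
#' @param meta Species metadata tibble from [read_species_meta()].
#' @param threshold Completeness threshold in percent (default 80).
#' @return Character vector of retained species ids.
#' @export
busco_gate <- function(meta, threshold = 80) {
  if (nrow(meta) == 0) return(character())
  check_busco(meta$busco_single_copy_pct)
  meta$species_id[meta$busco_single_copy_pct >= threshold]
}

#' Scan one proteome and classify its ABC transporters
#'
#' Full per-species chain: NBD domain detection (built-in profile scan or a
#' supplied domtblout table) -> candidate e-value filter -> similarity
#' ranking (built-in aligner against the reference database or a supplied
#' tabular file) -> family assignment with NBD-count architecture calls ->
#' length filter. Deterministic for fixed inputs.
#'
#' @param proteome Proteome tibble from [read_fasta()].
#' @param reference_db Reference tibble from [read_reference_db()].
#' @param profile `abc_profile` used for NBD detection when `domain_hits`
#'   is not supplied.
#' @param domain_hits Optional pre-computed domain-hit tibble
#'   ([parse_domtblout()]).
#' @param sim_hits Optional pre-computed similarity-hit tibble
#'   ([parse_blast_tab()]).
#' @param config An [abc_config()].
#' @param verbose Log per-stage record counts to stderr.
#' @return Family-call tibble with one row per candidate (classified or
#'   excluded, with rule provenance).
#' @export
scan_species <- function(proteome, reference_db, profile = NULL,
                         domain_hits = NULL, sim_hits = NULL,
                         config = abc_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message("[scan] ", ...)
  if (nrow(proteome) == 0) {
    return(tibble(protein_id = character(), family = character(),
                  rule_used = character(), top_hit_id = character(),
                  top_evalue = double(), nbd_count = integer(),
                  length_filtered = logical()))
  }
  if (is.null(domain_hits)) {
    if (is.null(profile)) {
      abort("scan stage: supply either a profile or pre-computed domain_hits")
    }
    domain_hits <- scan_proteome(profile, proteome)
  }
  say("domain hits: ", nrow(domain_hits))
  candidates <- filter_candidates(domain_hits, config$candidate_evalue)
  say("candidates passing e<", config$candidate_evalue, ": ",
      length(candidates), " / ", nrow(proteome))
  if (length(candidates) == 0) {
    return(tibble(protein_id = character(), family = character(),
                  rule_used = character(), top_hit_id = character(),
                  top_evalue = double(), nbd_count = integer(),
                  length_filtered = logical()))
  }
  if (is.null(sim_hits)) {
    sim_hits <- similarity_search(
      proteome[proteome$protein_id %in% candidates, , drop = FALSE],
      reference_db, evalue_cutoff = config$sim_evalue)
  } else {
    sim_hits <- sim_hits[sim_hits$evalue < config$sim_evalue, , drop = FALSE]
  }
  say("similarity hits: ", nrow(sim_hits))
  calls <- classify_candidates(candidates, sim_hits, domain_hits,
                               config$domain_evalue_cutoff,
                               config$max_overlap_frac)
  say("classified: ", sum(calls$family != "EXCLUDED"))
  calls <- apply_length_filter(calls, proteome, config$min_len)
  say("after length filter (>=", config$min_len, " aa): ",
      sum(calls$family != "EXCLUDED"),
      " (", sum(calls$length_filtered), " length-filtered)")
  calls
}

#' Aggregate family calls into a species x family count matrix
#'
#' @param calls_by_species Named list (species id -> family-call tibble) or
#'   one tibble with a `species_id` column.
#' @param meta Species metadata; every species must be present.
#' @return A tibble of class `abc_family_matrix`: one row per species with
#'   integer columns A, BF, BH, C, D, E, F, G, H, `total`, plus
#'   `taxon_order` and `busco_single_copy_pct`.
#' @export
aggregate_counts <- function(calls_by_species, meta) {
  if (is.data.frame(calls_by_species)) {
    calls_by_species <- split(calls_by_species,
                              calls_by_species$species_id)
  }
  sp <- names(calls_by_species)
  missing <- setdiff(sp, meta$species_id)
  if (length(missing) > 0) {
    abort(paste0("species without metadata: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::map_dfr(sp, function(s) {
    calls <- calls_by_species[[s]]
    kept <- calls$family[calls$family %in% ABC_FAMILIES]
    cnt <- table(factor(kept, levels = ABC_FAMILIES))
    out <- tibble(species_id = s)
    for (f in ABC_FAMILIES) out[[f]] <- as.integer(cnt[[f]])
    out$total <- as.integer(sum(cnt))
    out
  })
  out <- rows |>
    left_join(meta, by = "species_id") |>
    arrange(.data$species_id)
  class(out) <- c("abc_family_matrix", class(out))
  out
}

#' Benchmark predicted totals against literature counts
#'
#' Signed percent deviation per species, `100 * (predicted - literature) /
#' literature`, with the mean absolute and mean signed deviations.
#'
#' @param predicted Named numeric vector or tibble
#'   (`species_id`, `predicted`).
#' @param literature Named numeric vector or tibble
#'   (`species_id`, `literature`); counts must be positive.
#' @return A list of class `abc_benchmark`: `per_species` tibble
#'   (`species_id`, `predicted`, `literature`, `pct_deviation`),
#'   `mean_abs_deviation`, `mean_signed_deviation`.
#' @export
benchmark_counts <- function(predicted, literature) {
  as_tab <- function(x, nm) {
    if (is.data.frame(x)) {
      tibble(species_id = x$species_id, value = x[[nm]])
    } else {
      tibble(species_id = names(x), value = unname(x))
    }
  }
  p <- as_tab(predicted, "predicted")
  l <- as_tab(literature, "literature")
  tab <- dplyr::inner_join(p, l, by = "species_id",
                           suffix = c("_pred", "_lit"))
  if (nrow(tab) == 0) abort("no shared species between the two count sets")
  if (any(tab$value_lit <= 0)) {
    abort("literature counts must be positive")
  }
  per <- tibble(species_id = tab$species_id,
                predicted = tab$value_pred, literature = tab$value_lit,
                pct_deviation = 100 * (tab$value_pred - tab$value_lit) /
                  tab$value_lit)
  structure(list(per_species = per,
                 mean_abs_deviation = mean(abs(per$pct_deviation)),
                 mean_signed_deviation = mean(per$pct_deviation)),
            class = "abc_benchmark")
}

#' @export
print.abc_benchmark <- function(x, ...) {
  cat("<abc_benchmark>", nrow(x$per_species), "species | mean |dev|",
      sprintf("%.2f%%", x$mean_abs_deviation), "| mean signed",
      sprintf("%+.2f%%", x$mean_signed_deviation), "\n")
  invisible(x)
}

#' Built-in similarity search against the reference database
#'
#' Aligns every query locally against every reference record (BLOSUM62
#' scores through the degenerate per-sequence profile) and keeps hits below
#' the e-value cutoff, the same cutoff an external BLASTP run would use.
#'
#' @param queries Proteome tibble of query proteins.
#' @param reference_db Reference database tibble.
#' @param evalue_cutoff Strict e-value cutoff (default 1e-5).
#' @return Similarity-hit tibble ordered by query then ascending e-value.
#' @export
similarity_search <- function(queries, reference_db, evalue_cutoff = 1e-5) {
  profs <- lapply(reference_db$sequence, seq_profile)
  nref <- length(profs)
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    codes <- aa_codes(queries$sequence[i])
    bits <- pid <- numeric(nref)
    ev <- numeric(nref)
    for (j in seq_len(nref)) {
      p <- profs[[j]]
      al <- cpp_pssm_local(p$match_scores, codes, p$consensus,
                           p$gap_open, p$gap_extend)
      bits[j] <- al$score / 2
      ev[j] <- 2^(-bits[j]) * length(codes) * p$length
      pid[j] <- if (al$n_cols > 0) 100 * al$n_ident / al$n_cols else NA_real_
    }
    keep <- which(ev < evalue_cutoff)
    keep <- keep[order(ev[keep], -bits[keep],
                       reference_db$subject_id[keep])]
    out[[i]] <- tibble(query_id = queries$protein_id[i],
                       subject_id = reference_db$subject_id[keep],
                       subject_family = reference_db$family[keep],
                       percent_identity = pid[keep],
                       evalue = ev[keep], bitscore = bits[keep])
  }
  bind_rows(out)
}

#' Run a batch of species from a JSON configuration
#'
#' The configuration lists per-species proteome FASTA paths (and optional
#' domtblout / tabular similarity files), the reference database, a species
#' metadata TSV, thresholds and a seed. Species failing the BUSCO gate are
#' skipped. Writes per-species result files plus a `family_counts.tsv`
#' matrix under `out_dir`, byte-deterministic for a fixed configuration and
#' seed.
#'
#' @param config Path to a JSON file or an equivalent named list. Fields:
#'   `species` (list of `{id, proteome, domtblout?, blast_tab?}`), `refdb`,
#'   `meta`, `out_dir`, `seed`, optional `profile` (TSV from
#'   [write_profile()]; defaults to the built-in NBD profile for `seed`)
#'   and any [abc_config()] threshold.
#' @return The aggregated `abc_family_matrix`, invisibly.
#' @export
run_batch <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  cfg_args <- intersect(names(config), names(formals(abc_config)))
  cfg <- do.call(abc_config, config[cfg_args])
  seed <- config$seed %||% 1L
  meta <- read_species_meta(config$meta)
  refdb <- read_reference_db(config$refdb)
  profile <- if (!is.null(config$profile)) {
    read_profile(config$profile)
  } else {
    nbd_profile(seed)
  }
  keep <- busco_gate(meta, cfg$busco_threshold)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls_by_species <- list()
  for (sp in config$species) {
    if (!(sp$id %in% keep)) {
      message("[batch] ", sp$id, ": skipped (BUSCO below threshold)")
      next
    }
    proteome <- read_fasta(sp$proteome, species_id = sp$id)
    dom <- if (!is.null(sp$domtblout)) parse_domtblout(sp$domtblout)
    sim <- if (!is.null(sp$blast_tab)) parse_blast_tab(sp$blast_tab, refdb)
    calls <- scan_species(proteome, refdb, profile = profile,
                          domain_hits = dom, sim_hits = sim, config = cfg,
                          verbose = TRUE)
    write_results(calls, proteome, file.path(out_dir, sp$id))
    calls_by_species[[sp$id]] <- calls
  }
  mat <- aggregate_counts(calls_by_species,
                          meta[meta$species_id %in% names(calls_by_species),
                               , drop = FALSE])
  readr::write_tsv(as_tibble(as.data.frame(mat)),
                   file.path(out_dir, "family_counts.tsv"), progress = FALSE)
  invisible(mat)
}
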