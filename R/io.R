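#' Read a predicted proteome from FASTA
#'
#' Reads one protein sequence per record. The protein id is the header token
#' before the first whitespace; sequences are uppercased and terminal `*`
#' stop characters are stripped. Records whose sequence is more than 50%
#' unknown residues (`X`) are dropped with a warning, so degraded gene
#' models cannot silently enter classification.
#'
#' @param path Path to a FASTA file.
#' @param species_id Species identifier attached to every record.
#' @return A tibble with columns `protein_id`, `species_id`, `sequence`.
#' @export
read_fasta <- function(path, species_id = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  first_data <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first_data) && !startsWith(trimws(lines[first_data]), ">")) {
    abort(paste0("malformed FASTA: line ", first_data,
                 " is not a header in ", path))
  }
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) {
    return(tibble(protein_id = character(), species_id = character(),
                  sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(aas))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate protein id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  seqs <- unname(toupper(as.character(aas)))
  seqs <- gsub("\\*+$", "", gsub("^\\*+", "", seqs))
  x_frac <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0) 1 else lengths(regmatches(s, gregexpr("X", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
  bad <- x_frac > 0.5
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad),
                " record(s) with >50% unknown residues: ",
                paste(ids[bad], collapse = ", ")))
  }
  tibble(protein_id = ids[!bad],
         species_id = species_id,
         sequence = seqs[!bad])
}

#' Write protein records to FASTA
#'
#' @param records A tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aas <- Biostrings::AAStringSet(setNames(records$sequence,
                                          records$protein_id))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Expects the whitespace-delimited per-domain table written by `hmmsearch
#' --domtblout`, where each row is one domain match of the query profile on
#' a target protein. Sequence coordinates are taken from the `ali from`/`ali
#' to` columns, the sequence-level significance from the full-sequence
#' E-value column and the domain-level significance from the independent
#' (i-Evalue) column.
#'
#' @param path Path to a domtblout file. Lines starting with `#` are
#'   comments.
#' @return A tibble of domain hits with columns `protein_id`, `profile_id`,
#'   `seq_start`, `seq_end` (1-based inclusive), `full_seq_evalue`,
#'   `domain_ievalue`, `bitscore`.
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  empty <- tibble(protein_id = character(), profile_id = character(),
                  seq_start = integer(), seq_end = integer(),
                  full_seq_evalue = double(), domain_ievalue = double(),
                  bitscore = double())
  if (length(keep) == 0) return(empty)
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 19) {
      abort(paste0("domtblout line ", i, ": expected >= 19 fields, got ",
                   length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(7, 13, 14, 18, 19)]))
    if (anyNA(num)) {
      abort(paste0("domtblout line ", i, ": non-numeric value in ",
                   "e-value/score/coordinate fields"))
    }
    tibble(protein_id = f[1], profile_id = f[4],
           seq_start = as.integer(num[4]), seq_end = as.integer(num[5]),
           full_seq_evalue = num[1], domain_ievalue = num[2],
           bitscore = num[3])
  })
  out <- bind_rows(rows)
  if (any(out$full_seq_evalue < 0) || any(out$domain_ievalue < 0)) {
    abort("negative e-value in domtblout")
  }
  if (any(out$seq_start > out$seq_end)) {
    abort("domtblout alignment with start > end")
  }
  out
}

write_domtblout <- function(hits, path, target_len = NULL) {
  # fixture/interchange writer for the per-domain table dialect
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# target name accession tlen query name accession ",
                    "qlen E-value score bias ..."), con, sep = "\n")
  if (nrow(hits) > 0) {
    tl <- target_len %||% (hits$seq_end + 10L)
    for (i in seq_len(nrow(hits))) {
      writeLines(paste(hits$protein_id[i], "-", tl[i], hits$profile_id[i],
                       "-", 200, format(hits$full_seq_evalue[i]),
                       format(hits$bitscore[i]), "0.0", 1, 1,
                       format(hits$domain_ievalue[i]),
                       format(hits$domain_ievalue[i]),
                       format(hits$bitscore[i]), "0.0",
                       1, 200, hits$seq_start[i], hits$seq_end[i],
                       hits$seq_start[i], hits$seq_end[i], "0.90", "-",
                       sep = " "), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Parse tabular similarity-search output (12-column dialect)
#'
#' Reads the standard 12-column tab-separated alignment table
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and annotates every hit with the ABC family of its
#' subject, looked up in the reference database. Hits keep file order.
#'
#' @param path Path to the tabular file.
#' @param reference_db A reference database tibble from
#'   [read_reference_db()].
#' @return A tibble of similarity hits with columns `query_id`,
#'   `subject_id`, `subject_family`, `percent_identity`, `evalue`,
#'   `bitscore`.
#' @export
parse_blast_tab <- function(path, reference_db) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                         col_types = "ccdiiiiiiidd", progress = FALSE)
  if (nrow(tab) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  subject_family = character(), percent_identity = double(),
                  evalue = double(), bitscore = double()))
  }
  fam <- reference_db$family[match(tab$sseqid, reference_db$subject_id)]
  if (anyNA(fam)) {
    missing <- unique(tab$sseqid[is.na(fam)])
    abort(paste0("subject id(s) absent from reference database: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(tab$evalue < 0)) abort("negative e-value in similarity table")
  tibble(query_id = tab$qseqid, subject_id = tab$sseqid,
         subject_family = fam, percent_identity = tab$pident,
         evalue = tab$evalue, bitscore = tab$bitscore)
}

write_blast_tab <- function(hits, path) {
  # writes the 12-column dialect; alignment bookkeeping columns that the
  # classifier never reads are filled with placeholders
  n <- nrow(hits)
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.2f", hits$percent_identity),
    length = if (n) 100L else integer(), mismatch = if (n) 0L else integer(),
    gapopen = if (n) 0L else integer(), qstart = if (n) 1L else integer(),
    qend = if (n) 100L else integer(), sstart = if (n) 1L else integer(),
    send = if (n) 100L else integer(),
    evalue = format(hits$evalue, digits = 3),
    bitscore = sprintf("%.1f", hits$bitscore))
  readr::write_tsv(tab, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a family-labelled ABC reference database
#'
#' The reference database is a FASTA file whose headers follow the dialect
#' `>species|gene_id|family`, with family one of A, BF, BH, C, D, E, F, G,
#' H, I or NONABC. NONABC records are non-ABC proteome background; records
#' labelled I are accepted on input but always excluded by classification.
#'
#' @param path Path to the reference FASTA.
#' @return A tibble with columns `subject_id`, `species`, `family`,
#'   `sequence`.
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) {
    return(tibble(subject_id = character(), species = character(),
                  family = character(), sequence = character()))
  }
  heads <- sub("\\s.*$", "", names(aas))
  parts <- strsplit(heads, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    abort(paste0("reference header(s) not matching 'species|gene_id|family': ",
                 paste(heads[bad][seq_len(min(3, sum(bad)))],
                       collapse = ", ")))
  }
  species <- vapply(parts, `[`, character(1), 1)
  gene <- vapply(parts, `[`, character(1), 2)
  fam <- vapply(parts, `[`, character(1), 3)
  badfam <- !(fam %in% REFDB_FAMILIES)
  if (any(badfam)) {
    abort(paste0("unknown family label(s) in reference headers: ",
                 paste(unique(fam[badfam]), collapse = ", ")))
  }
  tibble(subject_id = gene, species = species, family = fam,
         sequence = toupper(as.character(aas)))
}

#' @rdname read_reference_db
#' @param db Reference database tibble.
#' @export
write_reference_db <- function(db, path) {
  ids <- paste(db$species, db$subject_id, db$family, sep = "|")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(db$sequence, ids)), path)
  invisible(path)
}

#' Read a species metadata table
#'
#' Tab-separated with columns `species_id`, `taxon_order`,
#' `busco_single_copy_pct` (the proteome's BUSCO single-copy completeness,
#' in percent).
#'
#' @param path Path to the TSV.
#' @return A tibble with the three columns, scores validated to lie in
#'   \[0, 100\].
#' @export
read_species_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species_id", "taxon_order", "busco_single_copy_pct")
  if (!all(need %in% names(meta))) {
    abort(paste0("species metadata must have columns: ",
                 paste(need, collapse = ", ")))
  }
  check_busco(meta$busco_single_copy_pct)
  as_tibble(meta[need])
}

check_busco <- function(x) {
  if (any(!is.finite(x) | x < 0 | x > 100)) {
    abort("BUSCO single-copy completeness scores must lie in [0, 100]")
  }
  invisible(x)
}

#' Write classification results
#'
#' Writes two files: `<out_prefix>.abc.tsv` with one row per classified
#' (non-excluded) protein, ordered by species, family, then protein id, and
#' `<out_prefix>.abc.faa` with the sequences of those proteins. Output is
#' byte-deterministic for identical inputs.
#'
#' @param calls A family-call tibble from [assign_family()] /
#'   [scan_species()].
#' @param records The proteome tibble the calls were made on.
#' @param out_prefix Path prefix for the two output files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_results <- function(calls, records, out_prefix) {
  missing <- setdiff(calls$protein_id, records$protein_id)
  if (length(missing) > 0) {
    abort(paste0("calls without matching records: ",
                 paste(missing, collapse = ", ")))
  }
  tab <- calls |>
    filter(.data$family %in% ABC_FAMILIES) |>
    left_join(records, by = "protein_id") |>
    mutate(length = nchar(.data$sequence),
           top_evalue = format(.data$top_evalue, digits = 4)) |>
    select(protein_id = "protein_id", species = "species_id",
           family = "family", length = "length", rule_used = "rule_used",
           top_hit = "top_hit_id", top_evalue = "top_evalue",
           nbd_count = "nbd_count") |>
    arrange(.data$species, .data$family, .data$protein_id)
  tsv_path <- paste0(out_prefix, ".abc.tsv")
  faa_path <- paste0(out_prefix, ".abc.faa")
  readr::write_tsv(tab, tsv_path, progress = FALSE)
  seqs <- records$sequence[match(tab$protein_id, records$protein_id)]
  write_fasta(tibble(protein_id = tab$protein_id, sequence = seqs),
              faa_path)
  invisible(c(tsv_path, faa_path))
}
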