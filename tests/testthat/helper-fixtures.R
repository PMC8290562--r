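# Small shared fixtures, all generated in code at test time.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".faa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a tiny similarity-hit tibble builder for classifier tests
sim_hits <- function(families, evalues = NULL, bitscores = NULL,
                     query = "q1") {
  n <- length(families)
  tibble::tibble(
    query_id = query,
    subject_id = sprintf("s%02d", seq_len(n)),
    subject_family = families,
    percent_identity = 50,
    evalue = evalues %||% 10^(-rev(seq_len(n)) * 10),
    bitscore = bitscores %||% (100 + 10 * rev(seq_len(n))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
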