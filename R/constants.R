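# Fixed alphabets, background composition and family vocabularies.

# Amino-acid order follows the BLOSUM62 row order shipped with Biostrings.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson (1991) background amino-acid frequencies, the
# composition table used by the standard profile-search tools. Frozen here
# so profile construction needs no external data.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441
)

# ABC families as reported in output calls. "B" is only ever an internal
# voting super-label: reference ABC-B hits of either architecture reinforce
# each other and the NBD count then decides full (BF) vs half (BH).
ABC_FAMILIES <- c("A", "BF", "BH", "C", "D", "E", "F", "G", "H")

# Labels allowed in a reference database header. "I" is tolerated on input
# so that the ABC-I exclusion rule is exercisable; it never survives
# classification. NONABC marks proteome background records.
REFDB_FAMILIES <- c(ABC_FAMILIES, "I", "NONABC")

RULE_LEVELS <- c("VOTE_4OF5", "VOTE_TOP3", "EVALUE_GAP", "NONE")

aa_codes <- function(sequence) {
  # integer codes 1..20 in AA_ORDER; X and any other letter -> 0
  m <- match(strsplit(sequence, "", fixed = TRUE)[[1]], AA_ORDER)
  m[is.na(m)] <- 0L
  m
}

codes_to_aa <- function(codes) {
  out <- rep("X", length(codes))
  ok <- codes >= 1 & codes <= 20
  out[ok] <- AA_ORDER[codes[ok]]
  paste(out, collapse = "")
}
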