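---
title: "Methods: ABC transporter annotation and family-size comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABC transporter annotation and family-size comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcfam)
```

This vignette is the package's own account of its methods: the detection
and classification model, the statistics, the choices that were genuinely
open and how we made them, and what the synthetic benchmarks do and do
not demonstrate.

## The annotation model

ABC transporters share one strongly conserved module, the
nucleotide-binding domain (NBD; PFAM PF00005), embedded in much less
conserved transmembrane and linker sequence. The pipeline exploits this
asymmetry twice:

* **Detection** relies only on the NBD. A protein is a *candidate* if an
  NBD profile search finds a match with full-sequence E-value strictly
  below 10. That gate is deliberately loose (an E-value of 10 means ten
  chance hits expected per search): at this stage recall matters,
  because everything that slips through still has to survive family
  assignment. The per-domain independent E-value is parsed separately
  and used only for counting NBDs, with a much stricter default
  (`< 0.01`), since architecture calls (one vs two NBDs) should not rest
  on marginal domain matches. Both values come straight from HMMER3
  `--domtblout` columns when an external search is used.

* **Classification** relies on neighbourhood in sequence space. Ranked
  similarity hits against a reference database of family-labelled ABC
  proteins (plus non-ABC background) vote: 4 of the top 5 agreeing on a
  family wins, else 3 of 3, else a single dominant hit wins only if its
  E-value is at least five orders of magnitude below the runner-up's
  (`e1 ≤ e2 · 1e-5`, boundary inclusive — we read "five orders of
  magnitude" multiplicatively and include the boundary, and we test that
  reading explicitly). The vote is evaluated before the gap rule, and
  the rule that fired is recorded per protein (`rule_used`), so any call
  can be audited after the fact.

Assumptions worth stating: the reference database's family labels are
trusted; hits to it are treated as independent votes (they are not, when
reference species are close relatives); and a candidate with fewer than
five hits can never satisfy the 4-of-5 rule — with exactly four hits only
the top-3 rule can fire. We chose the strict reading rather than
inventing a 4-of-4 variant.

### ABC-B architecture and the exclusion rules

Reference ABC-B records of both architectures vote as one super-label,
because full (BF) and half (BH) transporters are close in NBD space and
should reinforce each other; the candidate's own NBD count then decides:
two or more NBDs → BF, one → BH. NBD counting accepts domains greedily by
ascending independent E-value and rejects intervals overlapping an
accepted one by more than half the shorter interval
(`max_overlap_frac = 0.5`); tandem NBDs in real full transporters are
separated by a whole transmembrane domain, so any tighter setting changes
nothing on clean data and the 0.5 default only guards against split
alignments of a single domain.

Two exclusion rules run after assignment. A winning ABC-I label is
dropped entirely (the family is not annotated in the reference sets this
approach depends on, so calls to it cannot be validated). Classified
proteins shorter than 250 residues are demoted to excluded:
gene-model fragments of real transporters classify perfectly well and
would otherwise inflate family counts. The boundary is strict
("under 250"), and the filter preserves the classification rule in the
output so that filtered fragments remain distinguishable from vote
failures.

At the species level, proteomes with BUSCO single-copy completeness
below 80% are excluded (boundary inclusive at 80.0): family counts from
incomplete gene sets bias comparative statistics downward. BUSCO scores
are caller-supplied metadata; the package does not run BUSCO.

## The built-in search backend

The production path for domain detection is an external HMMER3 search.
The built-in backend exists so that the classification logic — which is
what this package is really about — can be exercised end to end without
external binaries. It is a position-specific score matrix (PSSM) local
aligner, not a profile HMM: no insert/delete states, just per-column
log-odds scores (half-bit units) against the Robinson–Robinson background
composition with additive pseudocount smoothing, aligned by
Smith–Waterman with affine gaps (Gotoh; a gap of length *k* costs
`gap_open + k·gap_extend`, defaults −10/−1 half-bits, matching the usual
protein-search scale where BLOSUM62 is also expressed in half-bits).
Multiple domains are found iteratively: report the best local alignment,
mask its residues, rescan until the score drops below the reporting
threshold (default 25 bits). Because no analytic E-value calibration is
attempted, a Karlin–Altschul-shaped synthetic E-value is attached,
`E = 2^(−bits) · m · n` with *m* the protein length and *n* the profile
length; it is used only for thresholding and ranking within the package,
and the same constants are applied everywhere, so comparisons are
consistent even though absolute values are not calibrated against any
external tool.

The same compiled kernel doubles as the built-in similarity search:
each reference sequence becomes a degenerate PSSM whose row at position
*i* is the BLOSUM62 score row of its residue — which makes profile-vs-
sequence alignment coincide exactly with ordinary pairwise local
alignment. The kernel is verified against an independently written
dynamic-programming oracle in pure R (score agreement to 1e-9 over random
and planted sequences up to 200 aa).

Unknown residues (`X`) score zero everywhere (neutral), and sequences
that are more than half `X` are rejected on input with a warning rather
than silently classified. Coordinates are 1-based inclusive throughout,
the native R convention; interval overlap is computed as
`max(0, min(ends) − max(starts) + 1)`.

## Family-size statistics

Species are grouped by taxonomic order and each family's sizes are
compared with the tie-corrected Kruskal–Wallis statistic on mid-ranks,

$$H = \frac{\frac{12}{N(N+1)}\sum_i R_i^2/n_i - 3(N+1)}
          {1 - \sum_t (t^3-t)/(N^3-N)},$$

with the p-value from the upper tail of the chi-square distribution with
k−1 degrees of freedom. The chi-square approximation is used at every
sample size (no exact small-n tables); with the default minimum of 3
species per order the approximation is rough, which is one reason groups
below that size are dropped with a warning rather than tested.
If every observation is identical the statistic is defined as 0 with
p = 1.

Post-hoc pairwise comparisons use Conover's rank-means form: groups *i*
and *j* differ when

$$|\bar R_i - \bar R_j| >
  t_{1-\alpha'/2,\,N-k}\ \sqrt{S^2\,\frac{N-1-H}{N-k}
  \left(\frac{1}{n_i}+\frac{1}{n_j}\right)},$$

with `S²` the variance of all ranks and, by default,
`α' = α / (k(k−1)/2)` (Bonferroni over pairs; `p_adjust = "none"` gives
the unadjusted LSD-on-ranks variant, since the compact letters reported
alongside published family-size boxplots differ between the two and both
are defensible). Letters come from the insert-and-absorb algorithm over
groups sorted by descending mean rank: start with one column holding all
groups, split a column for each significant pair, absorb subset columns,
then letter the columns. Groups sharing a letter are never a
significantly different pair, and letters are contiguous along the rank
ordering.

When the per-family tests run over a whole matrix (`family_size_tests`),
p-values are additionally Bonferroni-multiplied across the family-level
tests (nine families plus the total), a conservative second level that
can be read off the `p_adjusted` column independently of the raw `p`.

## Quantification helpers

* TPM: `rate_g = count_g/(length_g/1000)`, `TPM_g = rate_g/Σrate · 1e6`.
  Effective gene lengths are caller-supplied; the package never derives
  them from annotation. All-zero samples are an error naming the sample.
* Per-gene z-scores across samples for heatmap display; zero-variance
  genes become all zeros with a warning rather than NaN.
* Schneider–Orelli corrected mortality `100·(T−C)/(100−C)`, clipped at 0
  with a warning when treated mortality falls below control.
* ΔΔCt relative expression `fold = E^(−ΔΔCt)` with `E = 2` by default.
  Dilution-series amplification efficiencies are not folded in
  automatically — pass `efficiency` per gene if you have estimates. The
  choice of housekeeping gene (or a geometric-mean combination) is the
  caller's.

## The synthetic benchmark: what it shows and what it does not

`make_family_archetypes` builds nine family-specific NBD variants
(180 aa) from one random core: Walker A (`GPSGSGKST`), the ABC signature
(`LSGGQRQR`) and Walker B (`ILLLDE`) are held fixed, the remaining
positions are substituted at rate 0.3 per family. That yields roughly
65–75% identity between families and >90% between an archetype and
copies mutated at ≤ 0.1 — close enough that family assignment is decided
by the hit vote, as intended; a larger `family_divergence` pushes
decisions onto the gap rule instead. Reference databases plant five
mutated copies (rate 0.05) per family across four synthetic reference
species; proteomes plant archetype copies in random flanks (≥ 300 aa
total, BF plants with two NBD blocks ≥ 60 aa apart), and decoys are
background sequence except for a fraction built as sub-250-aa fragments
of real plants, specifically to exercise the length filter. The mutation
model is substitutions only, drawn from the background composition — no
indels — so planted domain coordinates stay exact and interval
assertions can be sharp.

The study conditions used by the acceptance checks are 20 seeded runs,
each with a 45-record reference database, 30 planted transporters
covering all nine families (27 at substitution rate 0.1, three at rate
0) and 30 decoys; architecture checks use 20 further runs of three BF
and three BH plants at rate 0.05. These sizes keep a full run within a
few minutes on one CPU while leaving each proportion estimated from 600
planted genes.

What passing these benchmarks shows: the rule logic, thresholds,
boundaries, architecture resolution and provenance bookkeeping are
implemented exactly, and the whole chain is deterministic per seed. What
it does not show: performance on real proteomes. Real ABC families do
not diverge uniformly, real proteins have indels, domain loss and
chimeras, real reference databases have labelling errors, and real
BLAST/HMMER statistics differ from the synthetic E-values. The planted
recovery rates reported by the acceptance script are properties of the
generator's conditions, not estimates of field accuracy.

## Numerical and degenerate-input choices

* Candidate, similarity and domain E-value comparisons are all strict
  (`<`); the gap-rule ratio and the BUSCO gate are inclusive boundaries
  (`≤ e2·1e-5`, `≥ 80`). Each boundary has a dedicated test.
* Ranked hits are deduplicated per subject (best hit kept); ties are
  broken by descending bitscore then lexicographic subject id, making
  every verdict invariant to input order. The "next best hit" of the gap
  rule is therefore always a different subject.
* When the runner-up E-value underflows to zero the gap ratio is
  undefined; the rule then requires the top E-value to be zero as well
  and a bitscore margin of at least 50 bits. Fifty bits is a factor of
  2^50 in likelihood terms, the same spirit as five orders of magnitude
  (≈ 2^17) with a wide safety margin for the uncalibrated synthetic
  scores.
* Profile columns with more than 50% gaps are removed before scoring;
  profiles need at least 10 columns and 2 sequences.
* `H` is clamped at 0 against floating-point negatives; the Conover
  scale factor `(N−1−H)/(N−k)` is clamped at 0 for the degenerate case
  H → N−1 (perfect separation everywhere).
* All generators take explicit integer seeds and are pure functions of
  seed and parameters; batch runs are byte-deterministic.

## Known limitations

* The built-in scanner has no insert/delete states, so long insertions
  inside an NBD fragment its alignment; HMMER remains the production
  path for real data.
* Synthetic E-values are not calibrated; do not compare them with
  E-values from external tools.
* The chi-square omnibus approximation and the Conover critical value
  are both asymptotic; with very small groups the letters are
  indicative, not exact.
* Families are assigned independently per protein; no synteny, no
  phylogeny, no manual curation aids.
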