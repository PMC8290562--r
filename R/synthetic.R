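# Synthetic fixtures with known truth: family archetypes built around the
# conserved NBD core, reference databases, proteomes with planted ABC
# genes and decoys, similarity tables and grouped count fixtures. Every
# generator is a pure function of its seed and parameters.

NBD_LEN <- 180L

# conserved positions shared by all family archetypes: Walker A, the ABC
# signature and Walker B, at roughly canonical offsets
NBD_MOTIFS <- list(
  list(start = 8L, seq = "GPSGSGKST"),   # Walker A / P-loop
  list(start = 85L, seq = "LSGGQRQR"),   # ABC signature
  list(start = 135L, seq = "ILLLDE")     # Walker B
)

random_seq <- function(n) {
  paste(sample(AA_ORDER, n, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

#' Mutate a protein sequence
#'
#' Per-site substitutions at the given rate, substitution targets drawn
#' from the background composition. No indels, so planted domain
#' coordinates stay exact.
#'
#' @param sequence Amino-acid string.
#' @param rate Per-site substitution probability in \[0, 0.5\].
#' @return The mutated sequence.
#' @export
mutate_seq <- function(sequence, rate) {
  if (rate < 0 || rate > 0.5) abort("mutation rate must lie in [0, 0.5]")
  if (rate == 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(AA_ORDER, sum(hit), replace = TRUE,
                         prob = AA_BACKGROUND)
  }
  paste(chars, collapse = "")
}

#' Family NBD archetypes
#'
#' Nine distinguishable NBD sequence variants (one per ABC family), all
#' derived from a single random core so that the conserved motifs (Walker
#' A, ABC signature, Walker B) are shared while the remaining positions
#' diverge (~30% substitutions from the core per family). Deterministic
#' per seed.
#'
#' @param seed Integer seed.
#' @param family_divergence Per-site substitution rate applied to the
#'   shared core outside the motifs, per family. The default keeps
#'   between-family identity high enough that classification is normally
#'   decided by the hit vote; raise it to force decisions onto the
#'   e-value-gap rule.
#' @return A list with `nbd` (named character vector over the nine
#'   families) and `core`.
#' @export
make_family_archetypes <- function(seed, family_divergence = 0.3) {
  withr::with_seed(seed, {
    core <- strsplit(random_seq(NBD_LEN), "", fixed = TRUE)[[1]]
    motif_pos <- unlist(lapply(NBD_MOTIFS, function(m) {
      idx <- m$start:(m$start + nchar(m$seq) - 1L)
      core[idx] <<- strsplit(m$seq, "", fixed = TRUE)[[1]]
      idx
    }))
    variable <- setdiff(seq_len(NBD_LEN), motif_pos)
    nbd <- vapply(ABC_FAMILIES, function(f) {
      v <- core
      hit <- variable[runif(length(variable)) < family_divergence]
      if (length(hit) > 0) {
        v[hit] <- sample(AA_ORDER, length(hit), replace = TRUE,
                         prob = AA_BACKGROUND)
      }
      paste(v, collapse = "")
    }, character(1))
    list(nbd = nbd, core = paste(core, collapse = ""))
  })
}

#' Built-in NBD detection profile
#'
#' PSSM built from the nine family archetype NBD variants (which share a
#' length, so they form a gap-free alignment). The default reporting
#' threshold of 25 bits admits borderline chance matches on purpose: the
#' candidate gate is meant to be permissive, specificity comes from family
#' assignment.
#'
#' @param seed Seed forwarded to [make_family_archetypes()].
#' @param ... Passed to [build_profile()].
#' @return An `abc_profile`.
#' @export
nbd_profile <- function(seed, ...) {
  arch <- make_family_archetypes(seed)
  build_profile(unname(arch$nbd), ...)
}

#' Synthetic family-labelled reference database
#'
#' Mutated copies of each family archetype (substitution rate 0.05)
#' embedded in random flanks, with headers in the
#' `>species|gene_id|family` dialect; ABC-B full (BF) records carry two NBD
#' blocks and half (BH) records one. Decoys are random background
#' sequences labelled NONABC.
#'
#' @param seed Integer seed.
#' @param n_per_family Records per ABC family (>= 3; the voting rules need
#'   at least 3 hits).
#' @param n_decoys Number of NONABC background records.
#' @param ref_rate Per-site substitution rate from the archetype.
#' @return Reference database tibble (`subject_id`, `species`, `family`,
#'   `sequence`).
#' @export
make_reference_db <- function(seed, n_per_family = 5, n_decoys = 10,
                              ref_rate = 0.05) {
  if (n_per_family < 3) abort("n_per_family must be >= 3")
  arch <- make_family_archetypes(seed)
  withr::with_seed(seed + 1L, {
    species <- paste0("refsp", 1:4)
    rows <- list()
    for (f in ABC_FAMILIES) {
      for (i in seq_len(n_per_family)) {
        block <- mutate_seq(arch$nbd[[f]], ref_rate)
        seqn <- if (f == "BF") {
          paste0(random_seq(50), block, random_seq(60),
                 mutate_seq(arch$nbd[[f]], ref_rate), random_seq(50))
        } else {
          paste0(random_seq(50), block, random_seq(50))
        }
        rows[[length(rows) + 1]] <- tibble(
          subject_id = paste0(f, "_ref", i),
          species = species[(i - 1) %% 4 + 1],
          family = f, sequence = seqn)
      }
    }
    for (i in seq_len(n_decoys)) {
      rows[[length(rows) + 1]] <- tibble(
        subject_id = paste0("BG_ref", i),
        species = species[(i - 1) %% 4 + 1],
        family = "NONABC",
        sequence = random_seq(sample(250:450, 1)))
    }
    bind_rows(rows)
  })
}

#' Synthetic proteome with planted ABC genes and decoys
#'
#' Planted genes are archetype copies mutated at the plan's per-site rate
#' and embedded in random flanks (>= 300 aa in total; BF plants carry two
#' NBD blocks separated by a >= 60-aa linker). Decoys are random
#' background sequences, except that a fraction are truncated fragments of
#' planted genes (shorter than 250 aa but still containing a full NBD), to
#' exercise the length filter. The truth table records one row per
#' protein.
#'
#' @param seed Integer seed.
#' @param plan Tibble with columns `family`, `n`, `mutation_rate`.
#' @param n_decoys Number of decoy records.
#' @param decoy_len_range Length range for random decoys.
#' @param fragment_frac Fraction of decoys built as planted-gene fragments
#'   (requires at least one plant).
#' @param species_id Species id attached to all records.
#' @return List with `proteome` (tibble) and `truth` (tibble: `protein_id`,
#'   `true_family` or `"DECOY"`, `nbd_count`, `mutation_rate`).
#' @export
make_proteome <- function(seed, plan, n_decoys = 10,
                          decoy_len_range = c(150, 500),
                          fragment_frac = 0.3, species_id = "synsp1") {
  if (any(plan$mutation_rate < 0 | plan$mutation_rate > 0.5)) {
    abort("mutation rates must lie in [0, 0.5]")
  }
  arch <- make_family_archetypes(seed)
  withr::with_seed(seed + 2L, {
    prot <- list(); truth <- list()
    plant_info <- list()  # for fragment construction
    idx <- 0L
    fam_counter <- setNames(integer(length(ABC_FAMILIES)), ABC_FAMILIES)
    for (r in seq_len(nrow(plan))) {
      f <- plan$family[r]; rate <- plan$mutation_rate[r]
      if (!(f %in% ABC_FAMILIES)) {
        abort(paste0("unknown family in plan: ", f))
      }
      for (i in seq_len(plan$n[r])) {
        idx <- idx + 1L
        fam_counter[[f]] <- fam_counter[[f]] + 1L
        pid <- sprintf("%s_plant_%s_%02d", species_id, f, fam_counter[[f]])
        pre <- random_seq(60)
        block1 <- mutate_seq(arch$nbd[[f]], rate)
        if (f == "BF") {
          linker <- random_seq(60)
          block2 <- mutate_seq(arch$nbd[[f]], rate)
          seqn <- paste0(pre, block1, linker, block2, random_seq(60))
          nbd_n <- 2L
          b1 <- c(61L, 60L + NBD_LEN)
        } else {
          seqn <- paste0(pre, block1, random_seq(60))
          nbd_n <- 1L
          b1 <- c(61L, 60L + NBD_LEN)
        }
        prot[[idx]] <- tibble(protein_id = pid, species_id = species_id,
                              sequence = seqn)
        truth[[idx]] <- tibble(protein_id = pid, true_family = f,
                               nbd_count = nbd_n, mutation_rate = rate)
        plant_info[[idx]] <- list(seq = seqn, block = b1)
      }
    }
    n_frag <- if (length(plant_info) > 0) {
      min(n_decoys, floor(fragment_frac * n_decoys))
    } else 0L
    for (i in seq_len(n_decoys)) {
      idx <- idx + 1L
      pid <- sprintf("%s_decoy_%02d", species_id, i)
      if (i <= n_frag) {
        src <- plant_info[[sample(length(plant_info), 1)]]
        from <- max(1L, src$block[1] - 20L)
        to <- min(nchar(src$seq), from + 219L)  # <= 220 aa, < 250
        seqn <- substr(src$seq, from, to)
      } else {
        seqn <- random_seq(sample(decoy_len_range[1]:decoy_len_range[2], 1))
      }
      prot[[idx]] <- tibble(protein_id = pid, species_id = species_id,
                            sequence = seqn)
      truth[[idx]] <- tibble(protein_id = pid, true_family = "DECOY",
                             nbd_count = 0L, mutation_rate = NA_real_)
    }
    list(proteome = bind_rows(prot), truth = bind_rows(truth))
  })
}

#' Similarity hits for a synthetic proteome
#'
#' Runs the built-in all-vs-all local aligner against the reference
#' database and keeps hits below the e-value cutoff, standing in for an
#' external BLASTP run (same 1e-5 default cutoff).
#'
#' @param proteome Proteome tibble.
#' @param refdb Reference database tibble.
#' @param evalue_cutoff Strict e-value cutoff.
#' @return Similarity-hit tibble.
#' @export
make_similarity_hits <- function(proteome, refdb, evalue_cutoff = 1e-5) {
  similarity_search(proteome, refdb, evalue_cutoff = evalue_cutoff)
}

#' Grouped count fixture for the rank tests
#'
#' Poisson family sizes for `k_groups` groups, with one group's mean
#' optionally shifted upward; the truth (which group, what shift) is
#' attached as attributes.
#'
#' @param seed Integer seed.
#' @param k_groups,n_per_group Number of groups and values per group.
#' @param base_mean Poisson mean of the unshifted groups.
#' @param shifted_group Index of the shifted group (NULL for none).
#' @param shift Added to the shifted group's mean (>= 0).
#' @return Tibble with `group`, `value`; attributes `shifted_group`,
#'   `shift`.
#' @export
make_grouped_counts <- function(seed, k_groups = 4, n_per_group = 10,
                                base_mean = 4, shifted_group = NULL,
                                shift = 0) {
  if (shift < 0) abort("shift must be >= 0")
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(k_groups), function(g) {
      mu <- base_mean + if (!is.null(shifted_group) && g == shifted_group) {
        shift
      } else 0
      tibble(group = sprintf("g%d", g), value = rpois(n_per_group, mu))
    })
    attr(out, "shifted_group") <- shifted_group
    attr(out, "shift") <- shift
    out
  })
}

#' Synthetic species x family count matrix
#'
#' Poisson family sizes per species around field-realistic per-family
#' means, with an optional expansion (one taxonomic order, one family,
#' additive shift) mirroring the kind of lineage-specific expansion the
#' rank tests are meant to detect. BUSCO scores are drawn high (85-99) so
#' all species pass the default gate unless `low_busco` names some.
#'
#' @param seed Integer seed.
#' @param orders Taxonomic orders.
#' @param n_per_order Species per order.
#' @param base_means Named per-family Poisson means.
#' @param shifted_order,shifted_family,shift One expansion to plant.
#' @param low_busco Species indices (per the generated order) given BUSCO
#'   scores below 80.
#' @return An `abc_family_matrix` tibble.
#' @export
make_family_matrix <- function(seed, orders = c("Lepidoptera", "Coleoptera",
                                                "Hemiptera", "Diptera"),
                               n_per_order = 10,
                               base_means = c(A = 8, BF = 4, BH = 6, C = 13,
                                              D = 2, E = 1, F = 3, G = 15,
                                              H = 3),
                               shifted_order = NULL, shifted_family = NULL,
                               shift = 0, low_busco = integer()) {
  withr::with_seed(seed, {
    rows <- list(); i <- 0L
    for (ord in orders) {
      for (s in seq_len(n_per_order)) {
        i <- i + 1L
        counts <- vapply(ABC_FAMILIES, function(f) {
          mu <- base_means[[f]] +
            if (!is.null(shifted_order) && ord == shifted_order &&
                identical(f, shifted_family)) shift else 0
          rpois(1, mu)
        }, numeric(1))
        row <- tibble(species_id = sprintf("%s_sp%02d", ord, s))
        for (f in ABC_FAMILIES) row[[f]] <- as.integer(counts[[f]])
        row$total <- as.integer(sum(counts))
        row$taxon_order <- ord
        row$busco_single_copy_pct <-
          if (i %in% low_busco) round(runif(1, 50, 79), 1) else
            round(runif(1, 85, 99), 1)
        rows[[i]] <- row
      }
    }
    out <- bind_rows(rows)
    class(out) <- c("abc_family_matrix", class(out))
    out
  })
}

#' Synthetic count matrix for the quantification helpers
#'
#' Poisson counts with log-normal-ish per-gene rates and uniform gene
#' lengths, in the tidy (gene, length, samples...) layout [tpm()] expects.
#'
#' @param seed Integer seed.
#' @param n_genes,samples Number of genes and sample names.
#' @return Tibble `gene`, `length`, one column per sample.
#' @export
make_count_matrix <- function(seed, n_genes = 50,
                              samples = c("midgut", "malpighian", "cns")) {
  withr::with_seed(seed, {
    out <- tibble(gene = sprintf("gene%03d", seq_len(n_genes)),
                  length = sample(500:3000, n_genes, replace = TRUE))
    base <- exp(rnorm(n_genes, 3, 1.5))
    for (s in samples) {
      out[[s]] <- rpois(n_genes, base * exp(rnorm(n_genes, 0, 0.5)))
    }
    out
  })
}
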