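# Synthetic-data generators emulating curated neoantigen training sets,
# toy ELISpot plates, and in-silico cfDNA read mixing.

#' Specification for the synthetic training-set generator
#'
#' Defaults encode the composition of curated immunogenicity training
#' sets: a minority positive class, 9-mers dominant among immunogenic
#' peptides (59%, then 10-mers at 28%) with a flatter 9/10-mer split
#' (49%/46%) among non-immunogenic ones, basic residues (K/R) enriched at
#' P1 and acidic residues (E/D) at P2-P4 of immunogenic peptides, a skewed
#' HLA allele pool, and class-conditional Gaussian structured features
#' with seven of eleven features carrying a real class shift.
#'
#' @param n_records Number of records to generate.
#' @param positive_fraction Fraction of immunogenic records (default 0.3).
#' @param length_probs Named list with `positive` and `negative` numeric
#'   vectors over lengths 8-11 (each summing to 1).
#' @param enriched_positions Named list mapping peptide position to
#'   `list(residues =, prob =)` applied to the positive class; `NULL`
#'   disables positional enrichment (the null spec).
#' @param hla_pool Named numeric vector of allele frequencies.
#' @param feature_effects Named numeric vector `F1`..`F11` of mean shifts
#'   (in within-class SD units) added to the positive class.
#' @param n_motif_families Number of immunogenic motif families (default
#'   40). Positive peptides are noisy copies of length-11 family consensus
#'   motifs, emulating the recurrent shared epitopes of curated training
#'   sets; `0` makes positives fully i.i.d.
#' @param family_mutation_rate Per-position substitution probability when
#'   copying a family consensus (default 0.15).
#' @param seed Integer seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_records = 2000,
                           positive_fraction = 0.3,
                           length_probs = NULL,
                           enriched_positions = NULL,
                           hla_pool = NULL,
                           feature_effects = NULL,
                           n_motif_families = 40,
                           family_mutation_rate = 0.15,
                           seed = 1) {
  length_probs <- length_probs %||% list(
    positive = c(`8` = 0.05, `9` = 0.59, `10` = 0.28, `11` = 0.08),
    negative = c(`8` = 0.03, `9` = 0.49, `10` = 0.46, `11` = 0.02)
  )
  stopifnot(abs(sum(length_probs$positive) - 1) < 1e-8,
            abs(sum(length_probs$negative) - 1) < 1e-8,
            positive_fraction > 0, positive_fraction < 1)
  if (is.null(enriched_positions)) {
    enriched_positions <- list(
      `1` = list(residues = c("K", "R"), prob = 0.65),
      `2` = list(residues = c("E", "D"), prob = 0.65),
      `3` = list(residues = c("E", "D"), prob = 0.65),
      `4` = list(residues = c("E", "D"), prob = 0.65)
    )
  } else if (identical(enriched_positions, "none")) {
    enriched_positions <- list()
  }
  hla_pool <- hla_pool %||% c(
    "HLA-A*02:01" = 0.25, "HLA-A*01:01" = 0.12, "HLA-A*03:01" = 0.10,
    "HLA-A*24:02" = 0.10, "HLA-A*11:01" = 0.08, "HLA-B*07:02" = 0.08,
    "HLA-B*08:01" = 0.07, "HLA-B*44:02" = 0.06, "HLA-B*35:01" = 0.05,
    "HLA-C*07:01" = 0.05, "HLA-C*04:01" = 0.04
  )
  feature_effects <- feature_effects %||% c(
    F1 = 1.5, F2 = 0.6, F3 = 1.5, F4 = 1.5, F5 = 0,
    F6 = 0.6, F7 = 0, F8 = 0.6, F9 = 0.6, F10 = 0, F11 = 0
  )
  structure(list(
    n_records = as.integer(n_records),
    positive_fraction = positive_fraction,
    length_probs = length_probs,
    enriched_positions = enriched_positions,
    hla_pool = hla_pool / sum(hla_pool),
    feature_effects = feature_effects,
    n_motif_families = as.integer(n_motif_families),
    family_mutation_rate = family_mutation_rate,
    seed = as.integer(seed)
  ), class = "generator_spec")
}

#' Null generator specification
#'
#' Identical residue, length and feature distributions in both classes:
#' the label carries no signal. Used for type-I-error calibration of the
#' positional chi-square tests.
#'
#' @param n_records,positive_fraction,seed See [generator_spec()].
#' @return A `generator_spec`.
#' @export
null_generator_spec <- function(n_records = 2000, positive_fraction = 0.3,
                                seed = 1) {
  shared_len <- c(`8` = 0.05, `9` = 0.55, `10` = 0.32, `11` = 0.08)
  generator_spec(
    n_records = n_records,
    positive_fraction = positive_fraction,
    length_probs = list(positive = shared_len, negative = shared_len),
    enriched_positions = "none",
    feature_effects = stats::setNames(rep(0, 11), paste0("F", 1:11)),
    n_motif_families = 0,
    seed = seed
  )
}

#' Strong-effect generator specification for parameter recovery
#'
#' A deliberately easy configuration used to sanity-check the whole
#' training stack: positional enrichment probability 0.9, tighter motif
#' families (substitution rate 0.1) and doubled feature shifts. A model
#' pipeline that cannot place planted positives above negatives under this
#' spec is broken; real data is of course far harder (see the vignette).
#'
#' @param n_records,positive_fraction,seed See [generator_spec()].
#' @return A `generator_spec`.
#' @export
strong_effect_spec <- function(n_records = 2000, positive_fraction = 0.3,
                               seed = 1) {
  generator_spec(
    n_records = n_records,
    positive_fraction = positive_fraction,
    enriched_positions = list(
      `1` = list(residues = c("K", "R"), prob = 0.9),
      `2` = list(residues = c("E", "D"), prob = 0.9),
      `3` = list(residues = c("E", "D"), prob = 0.9),
      `4` = list(residues = c("E", "D"), prob = 0.9)
    ),
    feature_effects = c(
      F1 = 2.0, F2 = 0.8, F3 = 2.0, F4 = 2.0, F5 = 0,
      F6 = 0.8, F7 = 0, F8 = 0.8, F9 = 0.8, F10 = 0, F11 = 0
    ),
    family_mutation_rate = 0.1,
    seed = seed
  )
}

# Background residue weights; mildly hydrophobic-leaning (L/V common), as
# in generic proteome-derived peptide pools.
BACKGROUND_AA_WEIGHTS <- c(
  A = 7, C = 2, D = 4, E = 5, F = 4, G = 6, H = 2, I = 5, K = 5, L = 10,
  M = 2, N = 4, P = 5, Q = 4, R = 5, S = 7, T = 5, V = 8, W = 1, Y = 3
)

#' Generate a synthetic labeled peptide-HLA training set
#'
#' Draws records according to a [generator_spec()]: labels, class-specific
#' peptide lengths, positionally enriched residues for the positive class,
#' alleles from the skewed HLA pool, a wild-type peptide differing from the
#' mutant at one residue, and eleven class-conditional Gaussian structured
#' features. Duplicate `(peptide, allele)` pairs are resampled so the
#' output is curation-clean. The spec is attached as a `truth` attribute so
#' parameter-recovery tests can compare estimates against the generating
#' parameters.
#'
#' @param spec A `generator_spec`.
#' @return Tibble of records with columns as in [read_peptide_table()]
#'   plus `F1`..`F11`.
#' @export
generate_training_set <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_records
  n_pos_exp <- n * spec$positive_fraction
  if (n_pos_exp < 1 || (n - n_pos_exp) < 1) {
    abort_neorank("degenerate spec: expected zero records in one class",
                  "neorank_spec_error")
  }
  with_seed(spec$seed, {
    label <- ifelse(stats::runif(n) < spec$positive_fraction,
                    "immunogenic", "non_immunogenic")
    pos <- label == "immunogenic"
    len <- integer(n)
    len[pos] <- sample(8:11, sum(pos), replace = TRUE,
                       prob = spec$length_probs$positive)
    len[!pos] <- sample(8:11, sum(!pos), replace = TRUE,
                        prob = spec$length_probs$negative)
    families <- make_motif_families(spec)
    peptide <- sample_peptides(len, pos, spec, families)
    # resample any duplicate (peptide, allele) pairs
    hla <- sample(names(spec$hla_pool), n, replace = TRUE, prob = spec$hla_pool)
    for (iter in 1:20) {
      dup <- duplicated(paste(peptide, hla, sep = "\r"))
      if (!any(dup)) break
      peptide[dup] <- sample_peptides(len[dup], pos[dup], spec, families)
    }
    wildtype <- mutate_one_residue(peptide)
    feats <- matrix(stats::rnorm(n * 11), n, 11,
                    dimnames = list(NULL, paste0("F", 1:11)))
    shift <- spec$feature_effects[paste0("F", 1:11)]
    feats[pos, ] <- sweep(feats[pos, , drop = FALSE], 2, shift, "+")
    out <- tibble::tibble(
      record_id = make_record_ids(n, "syn"),
      mutant_peptide = peptide,
      wildtype_peptide = wildtype,
      hla_allele = hla,
      label = label,
      source = "synthetic_generator"
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(feats))
    attr(out, "truth") <- spec
    out
  })
}

# Length-11 consensus motifs for the positive class, drawn with the
# positional enrichment applied at consensus level.
make_motif_families <- function(spec) {
  if (spec$n_motif_families < 1) return(NULL)
  bg <- BACKGROUND_AA_WEIGHTS / sum(BACKGROUND_AA_WEIGHTS)
  ch <- matrix("", spec$n_motif_families, 11)
  for (p in 1:11) {
    ch[, p] <- sample(names(bg), spec$n_motif_families, replace = TRUE, prob = bg)
    enr <- spec$enriched_positions[[as.character(p)]]
    if (!is.null(enr)) {
      hit <- stats::runif(spec$n_motif_families) < enr$prob
      if (any(hit)) {
        ch[hit, p] <- sample(enr$residues, sum(hit), replace = TRUE)
      }
    }
  }
  ch
}

sample_peptides <- function(len, pos, spec, families = NULL) {
  n <- length(len)
  max_len <- max(len)
  bg <- BACKGROUND_AA_WEIGHTS / sum(BACKGROUND_AA_WEIGHTS)
  ch <- matrix("", n, max_len)
  # i.i.d. background draw, positionally enriched for positives
  for (p in seq_len(max_len)) {
    ch[, p] <- sample(names(bg), n, replace = TRUE, prob = bg)
    enr <- spec$enriched_positions[[as.character(p)]]
    if (!is.null(enr) && any(pos)) {
      hit <- pos & stats::runif(n) < enr$prob
      if (any(hit)) {
        ch[hit, p] <- sample(enr$residues, sum(hit), replace = TRUE)
      }
    }
  }
  # positives as noisy copies of family consensus motifs (prefix of the
  # length-11 consensus, per-position substitutions kept from the
  # background draw above)
  if (!is.null(families) && any(pos)) {
    fam <- sample.int(nrow(families), n, replace = TRUE)
    keep_consensus <- matrix(stats::runif(n * max_len) >= spec$family_mutation_rate,
                             n, max_len)
    cons <- families[fam, seq_len(max_len), drop = FALSE]
    sel <- pos & keep_consensus
    ch[sel] <- cons[sel]
  }
  vapply(seq_len(n), function(i) paste(ch[i, seq_len(len[i])], collapse = ""),
         character(1))
}

mutate_one_residue <- function(peptides) {
  vapply(peptides, function(pp) {
    L <- nchar(pp)
    p <- sample.int(L, 1)
    cur <- substr(pp, p, p)
    repl <- sample(setdiff(AA_ALPHABET, cur), 1)
    paste0(substr(pp, 1, p - 1), repl, substr(pp, p + 1, L))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate synthetic ELISpot plate counts
#'
#' Plants negative / weak / strong responses with Poisson replicate noise
#' around well-separated means so the planted class is recovered by
#' [classify_elispot()] with high probability at default noise.
#'
#' @param n_peptides Number of peptides.
#' @param response_mix Named fractions of planted `strong` and `weak`
#'   responses (remainder negative).
#' @param background_mean Background spots per well (default 10).
#' @param n_replicates Replicate wells per peptide (default 3).
#' @param seed Integer seed.
#' @return Tibble with `peptide_id`, replicate columns `rep1..repk`,
#'   `background_mean` and the planted class in `planted`.
#' @export
generate_elispot_counts <- function(n_peptides,
                                    response_mix = c(strong = 0.10, weak = 0.48),
                                    background_mean = 10, n_replicates = 3,
                                    seed = 1) {
  stopifnot(sum(response_mix) <= 1)
  with_seed(seed, {
    planted <- sample(c("strong", "weak", "negative"), n_peptides, replace = TRUE,
                      prob = c(response_mix["strong"], response_mix["weak"],
                               1 - sum(response_mix)))
    lambda <- background_mean + c(strong = 120, weak = 35, negative = 2)[planted]
    reps <- matrix(stats::rpois(n_peptides * n_replicates, rep(lambda, n_replicates)),
                   nrow = n_peptides)
    colnames(reps) <- paste0("rep", seq_len(n_replicates))
    dplyr::bind_cols(
      tibble::tibble(peptide_id = make_record_ids(n_peptides, "pep")),
      tibble::as_tibble(reps),
      tibble::tibble(background_mean = background_mean, planted = planted)
    )
  })
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed 4-line-record FASTQ file.
#' @return Tibble (`id`, `sequence`, `quality`).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    abort_neorank("FASTQ file length is not a multiple of 4 lines",
                  "neorank_io_error")
  }
  idx <- seq(1, length(lines), by = 4)
  tibble::tibble(
    id = sub("^@", "", lines[idx]),
    sequence = lines[idx + 1],
    quality = lines[idx + 3]
  )
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads Tibble (`id`, `sequence`, `quality`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a toy read set from a random reference
#'
#' Generates `n_reads` error-free reads of fixed length from a random
#' reference sequence (uniform base composition), with constant high base
#' qualities. A stand-in for real sequencing data at toy scale.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (default 100).
#' @param reference_length Reference length in bp (default 10000).
#' @param prefix Read-ID prefix.
#' @param seed Integer seed.
#' @return Tibble of reads as in [read_fastq()].
#' @export
simulate_read_set <- function(n_reads, read_length = 100,
                              reference_length = 10000,
                              prefix = "read", seed = 1) {
  with_seed(seed, {
    reference <- paste(sample(c("A", "C", "G", "T"), reference_length,
                              replace = TRUE), collapse = "")
    starts <- sample.int(reference_length - read_length + 1, n_reads,
                         replace = TRUE)
    tibble::tibble(
      id = sprintf("%s_%06d", prefix, seq_len(n_reads)),
      sequence = substring(reference, starts, starts + read_length - 1),
      quality = strrep("I", read_length)
    )
  })
}

#' Mix tumor and normal read sets in silico
#'
#' Emulates a cfDNA sample of given tumor fraction by sampling
#' `floor(tumor_fraction * n_total)` reads without replacement from the
#' tumor read set and the complement from the normal set, then shuffling
#' with the seed. A manifest records the exact counts so every output read
#' traces to exactly one input stream.
#'
#' @param tumor_reads,normal_reads Read tibbles (see [read_fastq()]) or
#'   paths to FASTQ files.
#' @param tumor_fraction Tumor fraction in (0, 1], default 0.15.
#' @param n_total Total reads in the mixture (default: as many as the
#'   pools allow at the requested fraction).
#' @param seed Integer seed.
#' @return List with `reads` (shuffled tibble with a `source_stream`
#'   column) and `manifest` (tibble of per-stream counts).
#' @export
insilico_mix <- function(tumor_reads, normal_reads, tumor_fraction = 0.15,
                         n_total = NULL, seed = 1) {
  if (is.character(tumor_reads)) tumor_reads <- read_fastq(tumor_reads)
  if (is.character(normal_reads)) normal_reads <- read_fastq(normal_reads)
  stopifnot(tumor_fraction > 0, tumor_fraction <= 1)
  if (nrow(tumor_reads) == 0 || nrow(normal_reads) == 0) {
    abort_neorank("both read streams must be non-empty", "neorank_input_error")
  }
  if (is.null(n_total)) {
    n_total <- min(floor(nrow(tumor_reads) / tumor_fraction),
                   if (tumor_fraction < 1) {
                     floor(nrow(normal_reads) / (1 - tumor_fraction))
                   } else {
                     Inf
                   })
  }
  n_tumor <- floor(tumor_fraction * n_total)
  n_normal <- n_total - n_tumor
  if (n_tumor > nrow(tumor_reads) || n_normal > nrow(normal_reads)) {
    abort_neorank(
      sprintf("requested %d tumor / %d normal reads but only %d / %d available",
              n_tumor, n_normal, nrow(tumor_reads), nrow(normal_reads)),
      "neorank_depth_error"
    )
  }
  with_seed(seed, {
    tsel <- tumor_reads[sample.int(nrow(tumor_reads), n_tumor), , drop = FALSE]
    nsel <- normal_reads[sample.int(nrow(normal_reads), n_normal), , drop = FALSE]
    tsel$source_stream <- rep("tumor", nrow(tsel))
    nsel$source_stream <- rep("normal", nrow(nsel))
    mixed <- dplyr::bind_rows(tsel, nsel)
    mixed <- mixed[sample.int(nrow(mixed)), , drop = FALSE]
    manifest <- tibble::tibble(
      stream = c("tumor", "normal"),
      n_reads = c(n_tumor, n_normal),
      available = c(nrow(tumor_reads), nrow(normal_reads)),
      fraction = c(n_tumor, n_normal) / n_total
    )
    list(reads = mixed, manifest = manifest)
  })
}
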