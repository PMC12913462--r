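# Reading, writing and curating peptide-HLA record tables.

FEATURE_COLUMNS <- paste0("F", 1:11)

MANDATORY_COLUMNS <- c("mutant_peptide", "hla_allele", "label")

#' Read a peptide-HLA table
#'
#' Reads a delimited table of labeled peptide-HLA pairs into a tibble with
#' one row per record. Mandatory columns are `mutant_peptide`, `hla_allele`
#' and `label`; optional columns are `record_id`, `wildtype_peptide`,
#' `hla_pseudosequence`, `source` and the structured feature columns
#' `F1`..`F11`. Missing optional columns are left absent; row order is
#' preserved.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A tibble with one row per record and a `record_id` column
#'   (generated from row numbers when the file has none).
#' @export
read_peptide_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_neorank(paste0("file not found: ", path), "neorank_io_error")
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  dat <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(dat))
  if (length(missing_cols) > 0) {
    abort_neorank(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "neorank_schema_error"
    )
  }
  feat_cols <- intersect(FEATURE_COLUMNS, names(dat))
  for (fc in feat_cols) {
    raw <- dat[[fc]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort_neorank(
        sprintf("unparseable value '%s' in feature column %s at row %d",
                raw[bad[1]], fc, bad[1]),
        "neorank_value_error"
      )
    }
    parsed[!is.na(raw) & raw == ""] <- NA_real_
    dat[[fc]] <- parsed
  }
  if (!"record_id" %in% names(dat)) {
    dat$record_id <- make_record_ids(nrow(dat))
  }
  tibble::as_tibble(dat) |>
    dplyr::relocate("record_id")
}

#' Write a peptide-HLA table
#'
#' @param data Tibble of records as returned by [read_peptide_table()].
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(data, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(data, path, progress = FALSE)
  invisible(path)
}

#' Normalize an HLA class I/II allele name
#'
#' Canonicalizes common spellings of HLA allele names to the form
#' `HLA-<locus>*<group>:<protein>` with two-digit-minimum fields, e.g.
#' `"A0101"`, `"a*1:1"` and `"HLA-A01:01"` all become `"HLA-A*01:01"`.
#' The function is idempotent and vectorized.
#'
#' @param raw Character vector of allele spellings.
#' @return Character vector of canonical allele names.
#' @export
#' @examples
#' normalize_hla(c("HLA-A*01:01", "A0101", "b4402"))
normalize_hla <- function(raw) {
  vapply(raw, normalize_hla_one, character(1), USE.NAMES = FALSE)
}

normalize_hla_one <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    abort_neorank("empty HLA allele name", "neorank_normalization_error",
                  raw = raw)
  }
  x <- toupper(gsub("[[:space:]]", "", raw))
  x <- sub("^HLA-?", "", x)
  m <- regmatches(x, regexec("^(DRB[0-9]|DQA1|DQB1|DPA1|DPB1|[A-GE])\\*?([0-9:]+)$", x))[[1]]
  if (length(m) == 0) {
    abort_neorank(paste0("cannot parse HLA allele name: '", raw, "'"),
                  "neorank_normalization_error", raw = raw)
  }
  locus <- m[2]
  digits <- m[3]
  if (grepl(":", digits)) {
    fields <- strsplit(digits, ":", fixed = TRUE)[[1]]
    if (length(fields) < 2 || any(!nzchar(fields))) {
      abort_neorank(paste0("cannot parse HLA allele fields: '", raw, "'"),
                    "neorank_normalization_error", raw = raw)
    }
  } else {
    # Undelimited digit runs: last two digits are the protein field.
    if (nchar(digits) < 3) {
      abort_neorank(paste0("cannot parse HLA allele fields: '", raw, "'"),
                    "neorank_normalization_error", raw = raw)
    }
    fields <- c(substr(digits, 1, nchar(digits) - 2),
                substr(digits, nchar(digits) - 1, nchar(digits)))
  }
  fields <- vapply(fields[1:2], function(f) {
    if (nchar(f) < 2) paste0(strrep("0", 2 - nchar(f)), f) else f
  }, character(1))
  sprintf("HLA-%s*%s:%s", locus, fields[1], fields[2])
}

#' Curate a peptide-HLA dataset
#'
#' Applies the standard inclusion filters used when assembling
#' immunogenicity training sets: peptides must be `min_length`-`max_length`
#' residues (defaults 8-11), drawn from the 20-letter amino-acid alphabet,
#' and records must carry a peptide, an HLA allele and a label. Duplicate
#' `(mutant_peptide, canonical hla_allele)` pairs are collapsed to their
#' first occurrence; label conflicts among duplicates are counted in the
#' report. Relative order is preserved and a per-rule removal report is
#' attached (see [curation_report()]).
#'
#' @param data Tibble of records (see [read_peptide_table()]).
#' @param min_length,max_length Inclusive peptide length bounds.
#' @return The curated tibble, with HLA names canonicalized and a
#'   `curation_report` attribute.
#' @export
curate <- function(data, min_length = 8, max_length = 11) {
  data <- tibble::as_tibble(data)
  if (!"record_id" %in% names(data)) data$record_id <- make_record_ids(nrow(data))
  n0 <- nrow(data)

  peptide <- toupper(as.character(data$mutant_peptide %||% rep(NA_character_, n0)))
  allele <- as.character(data$hla_allele %||% rep(NA_character_, n0))
  label <- as.character(data$label %||% rep(NA_character_, n0))

  incomplete <- is.na(peptide) | !nzchar(peptide) | is.na(allele) |
    !nzchar(allele) | is.na(label) | !nzchar(label)
  alphabet_bad <- !incomplete & !is_aa_string(peptide)
  len <- nchar(peptide)
  length_bad <- !incomplete & !alphabet_bad & (len < min_length | len > max_length)

  keep <- !(incomplete | alphabet_bad | length_bad)
  out <- data[keep, , drop = FALSE]
  out$mutant_peptide <- peptide[keep]
  out$hla_allele <- normalize_hla(allele[keep])
  if ("wildtype_peptide" %in% names(out)) {
    out$wildtype_peptide <- toupper(out$wildtype_peptide)
  }

  key <- paste(out$mutant_peptide, out$hla_allele, sep = "\r")
  dup <- duplicated(key)
  conflicts <- 0L
  if (any(dup)) {
    first_label <- out$label[match(key, key)]
    conflicts <- sum(dup & out$label != first_label)
  }
  out <- out[!dup, , drop = FALSE]

  report <- tibble::tibble(
    rule = c("incomplete", "invalid_alphabet", "length_out_of_bounds",
             "duplicate_pair", "label_conflict_among_duplicates"),
    count = c(sum(incomplete), sum(alphabet_bad), sum(length_bad),
              sum(dup), conflicts)
  )
  attr(out, "curation_report") <- report
  attr(out, "length_bounds") <- c(min_length, max_length)
  out
}

#' Retrieve the curation report
#'
#' @param data A tibble returned by [curate()].
#' @return Tibble with columns `rule` and `count`.
#' @export
curation_report <- function(data) {
  rep <- attr(data, "curation_report")
  if (is.null(rep)) {
    abort_neorank("no curation report attached; was this dataset curated?",
                  "neorank_state_error")
  }
  rep
}

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file. Sequences are uppercased; IDs are the
#'   first whitespace-delimited token of each header. Duplicate IDs are an
#'   error.
#' @return Named character vector mapping protein ID to sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort_neorank(
      paste0("duplicate FASTA IDs: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "neorank_io_error"
    )
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Read an annotated missense-variant table
#'
#' Reads a TSV of protein-level missense variants with columns
#' `protein_id`, `position` (1-based protein coordinate), `ref_aa`,
#' `alt_aa` and optionally `gene` and `expression`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of variant records.
#' @export
read_variant_table <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    ref_aa = readr::col_character(),
    alt_aa = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  required <- c("protein_id", "position", "ref_aa", "alt_aa")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0) {
    abort_neorank(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "neorank_schema_error"
    )
  }
  validate_variants(dat)
  tibble::as_tibble(dat)
}

validate_variants <- function(dat) {
  bad <- which(dat$ref_aa == dat$alt_aa)
  if (length(bad) > 0) {
    abort_neorank(sprintf("ref_aa equals alt_aa at row %d", bad[1]),
                  "neorank_value_error")
  }
  if (any(dat$position < 1)) {
    abort_neorank("variant positions must be >= 1 (1-based protein coordinates)",
                  "neorank_value_error")
  }
  invisible(dat)
}

#' Read missense variants from a VCF with a protein-consequence tag
#'
#' Minimal plumbing for VCFs whose INFO field carries an annotated protein
#' consequence of the form `<protein_id>:p.<ref><pos><alt>` under the tag
#' named by `csq_tag`. Records without a parseable missense consequence are
#' skipped.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param csq_tag INFO key holding the protein consequence (default `"PCSQ"`).
#' @return Tibble of variant records as in [read_variant_table()].
#' @export
read_variants_vcf <- function(path, csq_tag = "PCSQ") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_neorank("the vcfR package is required to read VCF files",
                  "neorank_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  info <- vcfR::extract.info(v, element = csq_tag)
  m <- regmatches(info, regexec("^([^:]+):p\\.([A-Y])([0-9]+)([A-Y])$", info))
  keep <- vapply(m, length, integer(1)) == 5
  rows <- m[keep]
  tibble::tibble(
    protein_id = vapply(rows, `[[`, character(1), 2),
    position = as.integer(vapply(rows, `[[`, character(1), 4)),
    ref_aa = vapply(rows, `[[`, character(1), 3),
    alt_aa = vapply(rows, `[[`, character(1), 5),
    gene = NA_character_
  ) |> validate_variants()
}
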