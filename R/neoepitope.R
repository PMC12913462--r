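# Mutant-peptide enumeration from missense variants and the
# immunogenicity feature registry.

#' Enumerate mutant 8-11-mer peptides over missense variants
#'
#' For each variant and each requested length L, every window of length L
#' that lies fully inside the protein and covers the variant position is
#' emitted with the reference residue replaced by the alternate. For a
#' variant at interior distance >= L - 1 from both protein ends there are
#' exactly L windows of length L, so the default lengths give
#' 8 + 9 + 10 + 11 = 38 candidates. Identical peptide strings arising from
#' different windows of the same variant are collapsed, retaining the
#' provenance of every contributing window.
#'
#' @param variants Tibble of variant records (`protein_id`, `position`,
#'   `ref_aa`, `alt_aa`, optional `gene`), see [read_variant_table()].
#' @param proteins Named character vector of protein sequences, see
#'   [read_fasta()].
#' @param lengths Integer set of peptide lengths, default `8:11`.
#' @return Tibble of candidates: `peptide`, `protein_id`, `gene`,
#'   `variant_position`, `ref_aa`, `alt_aa`, `length`, `window_start`
#'   (1-based protein coordinate; semicolon-joined when windows collapse)
#'   and `mutant_position_in_peptide` (for the first contributing window).
#' @export
enumerate_mutant_peptides <- function(variants, proteins, lengths = 8:11) {
  if (!all(lengths %in% 8:11)) {
    abort_neorank("lengths must be a subset of 8:11", "neorank_value_error")
  }
  variants <- tibble::as_tibble(variants)
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$protein_id %in% names(proteins)) {
      abort_neorank(paste0("protein not found in FASTA: ", v$protein_id),
                    "neorank_coordinate_error")
    }
    prot <- proteins[[v$protein_id]]
    plen <- nchar(prot)
    pos <- v$position
    if (pos < 1 || pos > plen) {
      abort_neorank(sprintf("variant position %d outside protein %s (length %d)",
                            pos, v$protein_id, plen),
                    "neorank_coordinate_error")
    }
    found <- substr(prot, pos, pos)
    if (found != v$ref_aa) {
      abort_neorank(
        sprintf("reference mismatch at %s position %d: expected %s, found %s",
                v$protein_id, pos, v$ref_aa, found),
        "neorank_consistency_error"
      )
    }
    mutated <- paste0(substr(prot, 1, pos - 1), v$alt_aa,
                      substr(prot, pos + 1, plen))
    cand <- list()
    for (L in sort(lengths)) {
      lo <- max(1, pos - L + 1)
      hi <- min(pos, plen - L + 1)
      starts <- if (hi >= lo) seq(lo, hi) else integer(0)
      for (s in starts) {
        cand[[length(cand) + 1]] <- tibble::tibble(
          peptide = substr(mutated, s, s + L - 1),
          protein_id = v$protein_id,
          gene = if ("gene" %in% names(v)) v$gene else NA_character_,
          variant_position = pos,
          ref_aa = v$ref_aa, alt_aa = v$alt_aa,
          length = L,
          window_start = as.character(s),
          mutant_position_in_peptide = pos - s + 1L
        )
      }
    }
    cand <- dplyr::bind_rows(cand)
    if (nrow(cand) > 0) {
      cand <- cand |>
        dplyr::group_by(.data$peptide) |>
        dplyr::summarise(
          dplyr::across(c("protein_id", "gene", "variant_position",
                          "ref_aa", "alt_aa", "length",
                          "mutant_position_in_peptide"), dplyr::first),
          window_start = paste(.data$window_start, collapse = ";"),
          .groups = "drop"
        )
    }
    rows[[i]] <- cand
  }
  dplyr::bind_rows(rows)
}

#' The immunogenicity feature registry
#'
#' Eleven structured features grouped into three mechanistic categories.
#' Features tied to external antigen-processing predictors (TAP transport
#' efficiency, proteasomal/CTL processing score, peptide-HLA binding
#' affinity and stability, expression) are declared `external_column` and
#' are ingested via a join; the remaining features are documented local
#' proxies computed from the peptide sequence itself. The model layer
#' treats all eleven identically, so external scores can replace or extend
#' the proxies without interface changes.
#'
#' @return Tibble (`feature`, `name`, `category`, `provenance`, `description`).
#' @export
feature_registry <- function() {
  tibble::tribble(
    ~feature, ~name, ~category, ~provenance, ~description,
    "F1", "binding_affinity", "antigen_presentation", "external_column",
    "Predicted peptide-HLA binding affinity (external predictor).",
    "F2", "binding_stability", "antigen_presentation", "external_column",
    "Predicted peptide-HLA complex stability (external predictor).",
    "F3", "tap_efficiency", "antigen_processing", "external_column",
    "TAP transport efficiency (external predictor).",
    "F4", "ctl_processing", "antigen_processing", "external_column",
    "Combined CTL antigen-processing score, e.g. NetCTLpan (external predictor).",
    "F5", "expression", "antigen_processing", "external_column",
    "Source-gene expression level (external quantification).",
    "F6", "tcr_contact_hydrophobicity", "tcr_recognition", "local_proxy",
    "Mean Kyte-Doolittle hydropathy over TCR-contact positions 4..L-1.",
    "F7", "peptide_hydrophobicity", "tcr_recognition", "local_proxy",
    "Mean Kyte-Doolittle hydropathy over the full peptide.",
    "F8", "p1_basic", "tcr_recognition", "local_proxy",
    "Indicator of a basic residue (K/R) at position P1.",
    "F9", "acidic_p2_p4", "tcr_recognition", "local_proxy",
    "Fraction of acidic residues (E/D) at positions P2-P4.",
    "F10", "aromaticity", "tcr_recognition", "local_proxy",
    "Fraction of aromatic residues (F/W/Y) in the peptide.",
    "F11", "wt_dissimilarity", "tcr_recognition", "local_proxy",
    "Hydropathy distance between mutant and wild-type peptide (needs wildtype_peptide)."
  )
}

local_feature_value <- function(feature_name, peptide, wildtype = NA_character_) {
  kd <- kyte_doolittle()
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  switch(feature_name,
    tcr_contact_hydrophobicity = {
      idx <- 4:(L - 1)
      mean(kd[chars[idx]])
    },
    peptide_hydrophobicity = mean(kd[chars]),
    p1_basic = as.numeric(chars[1] %in% c("K", "R")),
    acidic_p2_p4 = mean(chars[2:4] %in% c("E", "D")),
    aromaticity = mean(chars %in% c("F", "W", "Y")),
    wt_dissimilarity = {
      if (is.na(wildtype) || nchar(wildtype) != L) return(NA_real_)
      wchars <- strsplit(wildtype, "")[[1]]
      mean(abs(kd[chars] - kd[wchars]))
    },
    abort_neorank(paste0("unknown local feature: ", feature_name),
                  "neorank_value_error")
  )
}

#' Assemble the 11-slot feature vector for candidate peptides
#'
#' Fills the locally computable proxy features from the peptide sequence
#' and joins externally supplied columns for the features the registry
#' declares external. Missing declared-external columns raise an error by
#' default: silent imputation would hide upstream failures.
#'
#' @param candidates Tibble with at least `peptide` (8-11-mers) and
#'   `hla_allele` columns; an optional `wildtype_peptide` column feeds the
#'   dissimilarity proxy.
#' @param external Optional tibble of external feature columns keyed by
#'   `(peptide, hla_allele)`; columns named as in
#'   `feature_registry()$name` (or `F1`..`F11`).
#' @param allow_missing_external If `TRUE`, absent external features become
#'   `NA` instead of an error (the completeness flag stays `FALSE`).
#' @return The input tibble with columns `F1`..`F11` appended and a logical
#'   `features_complete` column.
#' @export
assemble_features <- function(candidates, external = NULL,
                              allow_missing_external = FALSE) {
  reg <- feature_registry()
  candidates <- tibble::as_tibble(candidates)
  n <- nrow(candidates)
  wt <- if ("wildtype_peptide" %in% names(candidates)) {
    candidates$wildtype_peptide
  } else {
    rep(NA_character_, n)
  }
  out <- candidates
  ext_features <- reg$feature[reg$provenance == "external_column"]
  if (is.null(external) && !allow_missing_external) {
    abort_neorank(
      paste0("external feature columns required but not supplied: ",
             paste(reg$name[reg$provenance == "external_column"], collapse = ", ")),
      "neorank_missing_feature_error"
    )
  }
  ext_tbl <- NULL
  if (!is.null(external)) {
    external <- tibble::as_tibble(external)
    # accept either registry names or F-codes
    for (i in seq_len(nrow(reg))) {
      if (reg$name[i] %in% names(external) && !(reg$feature[i] %in% names(external))) {
        names(external)[names(external) == reg$name[i]] <- reg$feature[i]
      }
    }
    missing_ext <- setdiff(ext_features, names(external))
    if (length(missing_ext) > 0 && !allow_missing_external) {
      abort_neorank(
        paste0("missing declared-external feature column(s): ",
               paste(reg$name[match(missing_ext, reg$feature)], collapse = ", ")),
        "neorank_missing_feature_error"
      )
    }
    ext_tbl <- external
  }
  for (i in seq_len(nrow(reg))) {
    fcode <- reg$feature[i]
    if (reg$provenance[i] == "local_proxy") {
      out[[fcode]] <- vapply(seq_len(n), function(r) {
        local_feature_value(reg$name[i], candidates$peptide[r], wt[r])
      }, numeric(1))
    } else {
      out[[fcode]] <- rep(NA_real_, n)
    }
  }
  if (!is.null(ext_tbl)) {
    keys_in <- paste(out$peptide, normalize_hla(out$hla_allele), sep = "\r")
    keys_ext <- paste(ext_tbl$peptide, normalize_hla(ext_tbl$hla_allele), sep = "\r")
    hit <- match(keys_in, keys_ext)
    for (fcode in intersect(ext_features, names(ext_tbl))) {
      out[[fcode]] <- ext_tbl[[fcode]][hit]
    }
  }
  fmat <- as.matrix(out[, reg$feature])
  out$features_complete <- rowSums(is.na(fmat)) == 0
  out
}
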