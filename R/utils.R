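# Shared constants and internal helpers.

#' The 20 standard amino acids, alphabetical one-letter codes
#' @keywords internal
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of hydropathy values for the 20 standard amino
#' acids (positive = hydrophobic).
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' kyte_doolittle()[["I"]]
kyte_doolittle <- function() {
  c(
    A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
  )
}

LABEL_LEVELS <- c("immunogenic", "non_immunogenic", "unknown")

abort_neorank <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "neorank_error"), ...)
}

# Evaluate `expr` under a temporary RNG state so package functions are
# seeded without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_aa_string <- function(x) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

# Stable per-record identifiers when a table has none.
make_record_ids <- function(n, prefix = "rec") {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}
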