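# Sequence encoders: k-mer tokenization, TF-IDF, one-hot, and contextual
# embeddings via a pluggable embedder interface.

#' Tokenize merged peptide-HLA strings into overlapping k-mers
#'
#' Each record's mutant peptide and its HLA representation are merged with
#' an explicit separator character and sliced into all stride-1 windows of
#' length `k`. The separator is outside the amino-acid alphabet, so k-mers
#' spanning the peptide/HLA boundary stay distinct tokens rather than
#' chimeric amino-acid words. For a merged string of length L the token
#' count is L - k + 1.
#'
#' @param data Tibble of curated records with `record_id`, `mutant_peptide`
#'   and `hla_allele` (plus `hla_pseudosequence` when that representation is
#'   requested).
#' @param k Window length (>= 1).
#' @param hla_repr `"allele_name"` (default; the full allele name carries
#'   supertype/subtype information) or `"pseudosequence"`.
#' @param separator Single merge character, default `"|"`.
#' @return A `kmer_tokens` object: tibble with `record_id` and a `tokens`
#'   list-column, carrying `k` and `separator` attributes.
#' @export
tokenize_records <- function(data, k, hla_repr = c("allele_name", "pseudosequence"),
                             separator = "|") {
  hla_repr <- match.arg(hla_repr)
  stopifnot(k >= 1, nchar(separator) == 1)
  if (separator %in% AA_ALPHABET) {
    abort_neorank("separator must lie outside the amino-acid alphabet",
                  "neorank_value_error")
  }
  hla_part <- if (hla_repr == "allele_name") {
    data$hla_allele
  } else {
    if (!"hla_pseudosequence" %in% names(data) ||
        anyNA(data$hla_pseudosequence)) {
      abort_neorank("hla_pseudosequence column required for pseudosequence representation",
                    "neorank_value_error")
    }
    data$hla_pseudosequence
  }
  merged <- paste0(data$mutant_peptide, separator, hla_part)
  tokens <- lapply(merged, slice_kmers, k = k)
  out <- tibble::tibble(record_id = data$record_id, tokens = tokens)
  attr(out, "k") <- as.integer(k)
  attr(out, "separator") <- separator
  attr(out, "role") <- attr(data, "role")
  class(out) <- c("kmer_tokens", class(out))
  out
}

#' Slice one string into its stride-1 k-mers
#'
#' @param x A single string of length >= `k`.
#' @param k Window length.
#' @return Character vector of the L - k + 1 windows.
#' @export
#' @examples
#' slice_kmers("SIINFEKL", 6)
slice_kmers <- function(x, k) {
  L <- nchar(x)
  if (L < k) {
    abort_neorank(sprintf("merged string of length %d is shorter than k = %d", L, k),
                  "neorank_tokenization_error")
  }
  starts <- seq_len(L - k + 1)
  substring(x, starts, starts + k - 1)
}

#' Fit a TF-IDF model on a token corpus
#'
#' The vocabulary is every distinct token in the corpus; inverse document
#' frequency uses the smoothed form `ln((1 + N) / (1 + df)) + 1`, where `N`
#' is the corpus size and `df` the number of documents containing the token.
#'
#' @param corpus A `kmer_tokens` object (or list of character vectors).
#' @param norm Row normalization applied at transform time: `"l2"`
#'   (default) or `"none"`.
#' @return A `tfidf_model` object.
#' @export
fit_tfidf <- function(corpus, norm = c("l2", "none")) {
  norm <- match.arg(norm)
  docs <- if (is.data.frame(corpus)) corpus$tokens else corpus
  if (length(docs) == 0) {
    abort_neorank("cannot fit TF-IDF on an empty corpus", "neorank_fit_error")
  }
  n_docs <- length(docs)
  df_counts <- table(unlist(lapply(docs, unique), use.names = FALSE))
  vocab <- sort(names(df_counts))
  df <- as.numeric(df_counts[vocab])
  idf <- log((1 + n_docs) / (1 + df)) + 1
  names(idf) <- vocab
  structure(
    list(vocabulary = stats::setNames(seq_along(vocab), vocab),
         idf = idf, norm = norm, n_docs = n_docs),
    class = "tfidf_model"
  )
}

#' Transform a token corpus with a fitted TF-IDF model
#'
#' Cell values are raw term count times idf, followed by row-wise l2
#' normalization when the model was fitted with `norm = "l2"` (zero rows
#' are left at zero). Out-of-vocabulary tokens are ignored.
#'
#' @param model A `tfidf_model`.
#' @param docs A `kmer_tokens` object (or list of character vectors).
#' @return An encoded matrix (records x vocabulary) with `record_id`
#'   rownames when available.
#' @export
transform_tfidf <- function(model, docs) {
  if (!inherits(model, "tfidf_model")) {
    abort_neorank("model is not a fitted tfidf_model", "neorank_state_error")
  }
  ids <- if (is.data.frame(docs)) docs$record_id else NULL
  role <- attr(docs, "role")
  token_lists <- if (is.data.frame(docs)) docs$tokens else docs
  V <- length(model$vocabulary)
  mat <- matrix(0, nrow = length(token_lists), ncol = V,
                dimnames = list(ids, names(model$vocabulary)))
  for (i in seq_along(token_lists)) {
    counts <- table(token_lists[[i]])
    hit <- intersect(names(counts), names(model$vocabulary))
    if (length(hit) > 0) {
      j <- model$vocabulary[hit]
      mat[i, j] <- as.numeric(counts[hit]) * model$idf[hit]
    }
  }
  if (model$norm == "l2") {
    nrm <- sqrt(rowSums(mat^2))
    nz <- nrm > 0
    mat[nz, ] <- mat[nz, , drop = FALSE] / nrm[nz]
  }
  new_encoded_matrix(mat, encoder_tag = "tfidf", role = role)
}

new_encoded_matrix <- function(mat, encoder_tag, role = NULL, synthetic = NULL) {
  stopifnot(is.matrix(mat))
  if (any(!is.finite(mat))) {
    abort_neorank("encoded matrix contains non-finite entries", "neorank_value_error")
  }
  attr(mat, "encoder_tag") <- encoder_tag
  attr(mat, "role") <- role
  attr(mat, "synthetic") <- synthetic %||% rep(FALSE, nrow(mat))
  class(mat) <- c("encoded_matrix", class(mat))
  mat
}

#' One-hot encode an amino-acid sequence
#'
#' @param seq A single sequence string.
#' @param alphabet Ordered symbol list; default the 20 standard residues.
#' @return An L x length(alphabet) binary matrix; each row sums to 1.
#' @export
#' @examples
#' one_hot("ACD")
one_hot <- function(seq, alphabet = AA_ALPHABET) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    abort_neorank(sprintf("unknown symbol '%s' at position %d", chars[p], p),
                  "neorank_encoding_error")
  }
  mat <- matrix(0, nrow = length(chars), ncol = length(alphabet),
                dimnames = list(NULL, alphabet))
  mat[cbind(seq_along(chars), idx)] <- 1
  mat
}

#' Deterministic hash-seeded contextual embedder
#'
#' A contextual-embedder implementation whose per-token vectors are pure
#' functions of the token string, mimicking how a subword-tokenizer
#' language model embeds text: each token is decomposed into its character
#' 1- to 3-grams and the token vector is the mean of the sub-piece vectors,
#' so tokens sharing substrings receive similar embeddings while distinct
#' tokens stay distinct. Each sub-piece vector comes from a polynomial
#' rolling hash seeding a linear congruential generator whose uniforms are
#' mapped through the normal quantile function. Identical tokens always
#' receive identical vectors and no global RNG state is touched, so the
#' determinism contract of the embedder interface holds bitwise. Intended
#' as the offline default; a pre-trained transformer checkpoint can be
#' wrapped with [custom_embedder()] instead.
#'
#' @param dimension Embedding dimension (default 64).
#' @param max_ngram Longest character n-gram used in the decomposition
#'   (default 3).
#' @return A `contextual_embedder` object.
#' @export
hash_embedder <- function(dimension = 64, max_ngram = 3) {
  stopifnot(dimension >= 1, max_ngram >= 1)
  cache <- new.env(parent = emptyenv())
  piece_vec <- function(piece) {
    v <- cache[[piece]]
    if (is.null(v)) {
      v <- hash_token_vector(piece, dimension)
      cache[[piece]] <- v
    }
    v
  }
  embed_fn <- function(tokens) {
    out <- matrix(0, nrow = length(tokens), ncol = dimension)
    for (i in seq_along(tokens)) {
      tk <- tokens[i]
      L <- nchar(tk)
      pieces <- character(0)
      for (g in seq_len(min(max_ngram, L))) {
        pieces <- c(pieces, substring(tk, 1:(L - g + 1), g:L))
      }
      acc <- numeric(dimension)
      for (pc in pieces) acc <- acc + piece_vec(pc)
      out[i, ] <- acc / length(pieces)
    }
    out
  }
  structure(list(name = "hash-ngram-stub", dimension = as.integer(dimension),
                 embed_fn = embed_fn),
            class = "contextual_embedder")
}

# 31-bit LCG stream seeded by a polynomial hash of the token.
hash_token_vector <- function(token, dimension) {
  codes <- utf8ToInt(token)
  h <- 7
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  x <- h
  u <- numeric(dimension)
  for (j in seq_len(dimension)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    u[j] <- (x + 0.5) / 2147483648
  }
  stats::qnorm(u) / sqrt(dimension)
}

#' Wrap an arbitrary token-embedding function as a contextual embedder
#'
#' @param name Embedder name.
#' @param dimension Output dimension.
#' @param embed_fn Function mapping a character vector of tokens to an
#'   `n_tokens x dimension` numeric matrix; must be deterministic.
#' @return A `contextual_embedder` object.
#' @export
custom_embedder <- function(name, dimension, embed_fn) {
  structure(list(name = name, dimension = as.integer(dimension),
                 embed_fn = embed_fn),
            class = "contextual_embedder")
}

#' Embed tokenized records with a contextual embedder
#'
#' @param tokens A `kmer_tokens` object.
#' @param embedder A `contextual_embedder`.
#' @param pooling `"none"` returns the token-level matrices (for the
#'   convolutional submodel); `"mean"` and `"cls"` return one row per record
#'   (mean over tokens, or the first token's vector).
#' @param max_tokens Length budget; longer token sequences are truncated
#'   with a warning, never silently.
#' @return For `pooling = "none"`, a `token_embeddings` object (list of
#'   matrices plus record IDs); otherwise an encoded matrix with one row
#'   per record.
#' @export
embed_records <- function(tokens, embedder, pooling = c("mean", "cls", "none"),
                          max_tokens = 512) {
  pooling <- match.arg(pooling)
  if (!inherits(embedder, "contextual_embedder")) {
    abort_neorank("embedder must be a contextual_embedder", "neorank_state_error")
  }
  token_lists <- tokens$tokens
  n_trunc <- 0L
  mats <- lapply(token_lists, function(tk) {
    if (length(tk) > max_tokens) {
      n_trunc <<- n_trunc + 1L
      tk <- tk[seq_len(max_tokens)]
    }
    embedder$embed_fn(tk)
  })
  if (n_trunc > 0) {
    warning(sprintf("%d token sequence(s) exceeded the %d-token budget and were truncated",
                    n_trunc, max_tokens))
  }
  role <- attr(tokens, "role")
  if (pooling == "none") {
    out <- structure(
      list(matrices = mats, record_ids = tokens$record_id,
           dimension = embedder$dimension, embedder = embedder$name),
      class = "token_embeddings"
    )
    attr(out, "role") <- role
    attr(out, "synthetic") <- rep(FALSE, length(mats))
    return(out)
  }
  pooled <- t(vapply(mats, function(m) {
    if (pooling == "mean") colMeans(m) else m[1, ]
  }, numeric(embedder$dimension)))
  rownames(pooled) <- tokens$record_id
  new_encoded_matrix(pooled, encoder_tag = paste0("embed_", pooling), role = role)
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("TF-IDF model: %d tokens, %d documents, norm = %s\n",
              length(x$vocabulary), x$n_docs, x$norm))
  invisible(x)
}

#' @export
print.contextual_embedder <- function(x, ...) {
  cat(sprintf("Contextual embedder '%s', dimension %d\n", x$name, x$dimension))
  invisible(x)
}

# Pad token-level embeddings to a common token count (zero rows) and
# return an n x (T_max * dim) flat matrix plus the layout, the fixed-size
# design representation the convolutional submodel trains on.
flatten_token_embeddings <- function(emb, t_max = NULL) {
  d <- emb$dimension
  lens <- vapply(emb$matrices, nrow, integer(1))
  t_max <- t_max %||% max(lens)
  if (any(lens > t_max)) {
    abort_neorank("token count exceeds the fixed layout; refit with larger t_max",
                  "neorank_shape_error")
  }
  flat <- matrix(0, nrow = length(emb$matrices), ncol = t_max * d)
  for (i in seq_along(emb$matrices)) {
    m <- emb$matrices[[i]]
    padded <- matrix(0, nrow = t_max, ncol = d)
    padded[seq_len(nrow(m)), ] <- m
    flat[i, ] <- as.numeric(t(padded)) # row-major: token blocks of length d
  }
  rownames(flat) <- emb$record_ids
  out <- new_encoded_matrix(flat, encoder_tag = "token_embed_flat",
                            role = attr(emb, "role"))
  attr(out, "t_max") <- as.integer(t_max)
  attr(out, "embed_dim") <- as.integer(d)
  out
}
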