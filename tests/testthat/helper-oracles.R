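# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate correctness.

# --- TF-IDF oracle ---------------------------------------------------------

oracle_tfidf <- function(docs, norm = "l2") {
  vocab <- sort(unique(unlist(docs)))
  n <- length(docs)
  idf <- numeric(length(vocab))
  for (j in seq_along(vocab)) {
    df <- 0
    for (d in docs) if (vocab[j] %in% d) df <- df + 1
    idf[j] <- log((1 + n) / (1 + df)) + 1
  }
  mat <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    for (j in seq_along(vocab)) {
      cnt <- sum(docs[[i]] == vocab[j])
      mat[i, j] <- cnt * idf[j]
    }
    if (norm == "l2") {
      nrm <- sqrt(sum(mat[i, ]^2))
      if (nrm > 0) mat[i, ] <- mat[i, ] / nrm
    }
  }
  list(vocab = vocab, idf = stats::setNames(idf, vocab), matrix = mat)
}

random_token_corpus <- function(n_docs, alphabet = c("AA", "AB", "BA", "BB", "CC", "CA")) {
  lapply(seq_len(n_docs), function(i) {
    sample(alphabet, sample(2:8, 1), replace = TRUE)
  })
}

# --- AUC oracle ------------------------------------------------------------

oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# --- rank-fusion oracle ----------------------------------------------------

oracle_fuse <- function(rankings, top_n) {
  ids <- sort(rankings[[1]]$record_id)
  get_rank <- function(rl, id) rl$rank[rl$record_id == id]
  get_score <- function(rl, id) rl$score[rl$record_id == id]

  support <- integer(length(ids))
  mean_rank <- numeric(length(ids))
  best_norm <- numeric(length(ids))
  mins <- sapply(rankings, function(rl) min(rl$score))
  maxs <- sapply(rankings, function(rl) max(rl$score))
  for (i in seq_along(ids)) {
    rs <- sapply(rankings, get_rank, id = ids[i])
    support[i] <- sum(rs <= top_n)
    mean_rank[i] <- mean(rs)
    normed <- sapply(seq_along(rankings), function(m) {
      s <- get_score(rankings[[m]], ids[i])
      if (maxs[m] == mins[m]) 0.5 else (s - mins[m]) / (maxs[m] - mins[m])
    })
    best_norm[i] <- max(normed)
  }
  cons <- which(support >= 2)
  rest <- which(support < 2)
  cons <- cons[order(-support[cons], mean_rank[cons], ids[cons])]
  rest <- rest[order(-best_norm[rest], ids[rest])]
  ids[c(cons, rest)]
}

random_ranked_list <- function(ids, tag) {
  scores <- round(stats::runif(length(ids)), 3) # rounding provokes ties
  ord <- order(-scores, ids)
  out <- tibble::tibble(record_id = ids[ord], score = scores[ord],
                        rank = seq_along(ids))
  attr(out, "model_tag") <- tag
  class(out) <- c("ranked_list", class(out))
  out
}

# --- mutant-window oracle --------------------------------------------------

oracle_windows <- function(protein, pos, alt, lengths) {
  out <- character(0)
  mutated <- paste0(substr(protein, 1, pos - 1), alt,
                    substr(protein, pos + 1, nchar(protein)))
  for (L in lengths) {
    for (s in seq_len(max(0, nchar(protein) - L + 1))) {
      e <- s + L - 1
      if (s <= pos && pos <= e) {
        out <- c(out, substr(mutated, s, e))
      }
    }
  }
  out
}

# --- fixtures --------------------------------------------------------------

toy_peptide_table <- function() {
  tibble::tibble(
    record_id = paste0("r", 1:3),
    mutant_peptide = c("SIINFEKL", "KEDEALYFV", "RLEDTWGQV"),
    wildtype_peptide = c("SIINFEKI", "KEDEALYFA", "RLEDTWGQA"),
    hla_allele = c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02"),
    label = c("non_immunogenic", "immunogenic", "immunogenic"),
    source = "toy"
  )
}

random_peptide <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), L, replace = TRUE),
        collapse = "")
}

# Small labeled dataset with a separable feature signal, for fast training
# tests.
small_training_data <- function(n = 120, seed = 42) {
  spec <- generator_spec(n_records = n, seed = seed)
  curate(generate_training_set(spec))
}
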