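# k-mer slicing, TF-IDF, one-hot and the contextual embedder.

test_that("k-mer slicing enumerates all stride-1 windows", {
  expect_equal(slice_kmers("SIINFEKL", 6), c("SIINFE", "IINFEK", "INFEKL"))
  expect_equal(length(slice_kmers(strrep("A", 16), 16)), 1)
  expect_error(slice_kmers("SHORT", 6), class = "neorank_tokenization_error")

  # token-count law over random strings
  set.seed(3)
  for (rep in 1:25) {
    L <- sample(4:30, 1)
    k <- sample(seq_len(L), 1)
    toks <- slice_kmers(random_peptide(L), k)
    expect_length(toks, L - k + 1)
    expect_true(all(nchar(toks) == k))
  }
})

test_that("merged tokenization keeps boundary k-mers distinct via the separator", {
  tab <- toy_peptide_table()
  tok <- tokenize_records(tab, k = 4)
  merged_len <- nchar(tab$mutant_peptide) + 1 + nchar(tab$hla_allele)
  expect_equal(vapply(tok$tokens, length, integer(1)), merged_len - 4 + 1)
  expect_true(any(grepl("\\|", tok$tokens[[1]])))
  # a merged string of length 25 gives 22 windows of length 4
  tab25 <- tibble::tibble(record_id = "x", mutant_peptide = random_peptide(13),
                          hla_allele = "HLA-A*02:01", label = "unknown")
  expect_length(tokenize_records(tab25, k = 4)$tokens[[1]], 22)
})

test_that("smoothed idf collapses to 1 for ubiquitous and single-document tokens", {
  single <- fit_tfidf(list(c("AA", "AB", "AA")))
  expect_true(all(abs(single$idf - 1) < 1e-12))

  corpus <- list(c("AA", "AB"), c("AA", "CC"), c("AA", "BB"))
  m <- fit_tfidf(corpus)
  expect_equal(unname(m$idf["AA"]), 1)           # in every document
  expect_gt(unname(m$idf["BB"]), 1)              # in one of three

  expect_error(fit_tfidf(list()), class = "neorank_fit_error")
})

test_that("TF-IDF fit and transform match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:50) {
    docs <- random_token_corpus(sample(2:8, 1))
    model <- fit_tfidf(docs)
    got <- transform_tfidf(model, docs)
    ora <- oracle_tfidf(docs)
    expect_equal(names(model$vocabulary), ora$vocab)
    expect_lt(max(abs(model$idf[ora$vocab] - ora$idf)), 1e-10)
    expect_lt(max(abs(unclass(got)[, ora$vocab] - ora$matrix)), 1e-10)
  }
})

test_that("out-of-vocabulary documents become zero rows; duplicates encode identically", {
  model <- fit_tfidf(list(c("AA", "AB"), c("AA", "CC")))
  out <- transform_tfidf(model, list(c("ZZ", "ZY"), c("AA", "AB"), c("AA", "AB")))
  expect_true(all(unclass(out)[1, ] == 0))
  expect_equal(unclass(out)[2, ], unclass(out)[3, ])
})

test_that("one-hot encoding is exactly invertible", {
  m <- one_hot("AA")
  expect_equal(dim(m), c(2, 20))
  expect_true(all(rowSums(m) == 1))
  expect_equal(sum(one_hot("AC") != one_hot("AA")), 2)

  set.seed(5)
  for (rep in 1:10) {
    pep <- random_peptide(9)
    m <- one_hot(pep)
    expect_equal(paste(colnames(m)[apply(m, 1, which.max)], collapse = ""), pep)
  }
  expect_error(one_hot("AXB", alphabet = c("A", "B")),
               class = "neorank_encoding_error", regexp = "position 2")
})

test_that("the hash embedder is deterministic and separates distinct tokens", {
  emb <- hash_embedder(32)
  toks <- c("AABB", "ABAB", "BABA", "CCDD", "A")
  m1 <- emb$embed_fn(toks)
  m2 <- emb$embed_fn(toks)
  expect_identical(m1, m2)
  d <- as.matrix(dist(m1))
  diag(d) <- Inf
  expect_gt(min(d), 1e-8)
})

test_that("similar tokens embed closer than unrelated tokens", {
  # subword-style composition: one substitution moves the vector less than
  # a full replacement
  emb <- hash_embedder(64)
  m <- emb$embed_fn(c("KEDE", "KEDD", "VLLW"))
  d_sim <- sqrt(sum((m[1, ] - m[2, ])^2))
  d_far <- sqrt(sum((m[1, ] - m[3, ])^2))
  expect_lt(d_sim, d_far)
})

test_that("pooled embeddings follow the pooling contract", {
  tab <- toy_peptide_table()
  tok <- tokenize_records(tab, k = 2)
  emb <- hash_embedder(16)

  none <- embed_records(tok, emb, pooling = "none")
  expect_length(none$matrices, 3)
  expect_equal(ncol(none$matrices[[1]]), 16)

  mean_pooled <- embed_records(tok, emb, pooling = "mean")
  expect_equal(unclass(mean_pooled)[1, ], colMeans(none$matrices[[1]]))
  cls <- embed_records(tok, emb, pooling = "cls")
  expect_equal(unclass(cls)[1, ], none$matrices[[1]][1, ])

  # mean pooling of a single-token sequence is that token's embedding
  one_tok <- tibble::tibble(record_id = "x", tokens = list("SI"))
  attr(one_tok, "k") <- 2L
  pooled <- embed_records(one_tok, emb, pooling = "mean")
  expect_equal(unclass(pooled)[1, ], emb$embed_fn("SI")[1, ])
})

test_that("token sequences over the length budget are truncated loudly", {
  tab <- toy_peptide_table()
  tok <- tokenize_records(tab, k = 2)
  emb <- hash_embedder(8)
  expect_warning(out <- embed_records(tok, emb, pooling = "none", max_tokens = 5),
                 regexp = "truncated")
  expect_true(all(vapply(out$matrices, nrow, integer(1)) <= 5))
})

test_that("encoders are pure: same records and config give identical matrices", {
  tab <- small_training_data(60)
  tok <- tokenize_records(tab, k = 6)
  m <- fit_tfidf(tok)
  expect_identical(unclass(transform_tfidf(m, tok)),
                   unclass(transform_tfidf(m, tok)))
  emb <- hash_embedder(16)
  tok2 <- tokenize_records(tab, k = 4)
  a <- flatten_token_embeddings(embed_records(tok2, emb, pooling = "none"))
  b <- flatten_token_embeddings(embed_records(tok2, emb, pooling = "none"))
  expect_identical(unclass(a), unclass(b))
})
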