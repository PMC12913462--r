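# Architectures, training behavior and scoring of the three submodels.

test_that("parameter counts match the closed form", {
  net <- build_submodel("fcnn_tfidf", input_dim = 100)
  expect_equal(n_params(net$arch), (100 * 64 + 64) + (64 * 2 + 2)) # 6594

  cnn <- build_submodel("cnn_embed", embed_dim = 16, t_max = 20)
  expect_equal(n_params(cnn$arch),
               sum(sapply(c(3, 4, 5), function(w) w * 16 * 120 + 120)) +
                 (360 * 2 + 2))

  fe <- build_submodel("fcnn_embed", input_dim = 64 + 11)
  expect_equal(fe$arch$input_dim, 75)
})

test_that("architectures match the published layer plans", {
  fc <- build_submodel("fcnn_tfidf", input_dim = 50)
  kinds <- vapply(fc$arch$layers, `[[`, character(1), "kind")
  expect_equal(kinds, c("dense", "relu", "dropout", "dense"))
  expect_equal(fc$arch$layers[[1]]$to, 64L)
  expect_equal(fc$arch$layers[[3]]$p, 0.2)
  expect_equal(fc$arch$layers[[4]]$to, 2L)

  cn <- build_submodel("cnn_embed", embed_dim = 8, t_max = 15)
  kinds <- vapply(cn$arch$layers, `[[`, character(1), "kind")
  expect_equal(kinds, c("conv1d", "conv1d", "conv1d", "concat", "dropout", "dense"))
  widths <- vapply(cn$arch$layers[1:3], `[[`, integer(1), "width")
  expect_equal(widths, c(3L, 4L, 5L))
  expect_true(all(vapply(cn$arch$layers[1:3], `[[`, integer(1), "filters") == 120L))
  expect_true(all(vapply(cn$arch$layers[1:3], `[[`, character(1), "activation") == "relu"))
  expect_true(all(vapply(cn$arch$layers[1:3], `[[`, character(1), "pooling") == "global_max"))
  expect_equal(cn$arch$layers[[4]]$to, 360L)
  expect_equal(cn$arch$layers[[5]]$p, 0.1)

  fe <- build_submodel("fcnn_embed", input_dim = 75)
  expect_equal(fe$arch$hidden_size, 53L)
  expect_equal(fe$arch$dropout, 0.5)
})

test_that("training hyperparameters default to the published settings", {
  cfgs <- lapply(c("fcnn_tfidf", "cnn_embed", "fcnn_embed"), submodel_config)
  expect_equal(vapply(cfgs, `[[`, integer(1), "epochs"), c(45L, 19L, 31L))
  expect_true(all(vapply(cfgs, `[[`, integer(1), "batch_size") == 32L))
  expect_true(all(vapply(cfgs, `[[`, numeric(1), "learning_rate") == 1e-4))
  expect_true(all(vapply(cfgs, `[[`, character(1), "optimizer") == "adam"))
  expect_equal(vapply(cfgs, `[[`, integer(1), "k"), c(6L, 4L, 2L))
})

test_that("build errors name the offending dimension", {
  expect_error(build_submodel("fcnn_tfidf"), class = "neorank_build_error")
  expect_error(build_submodel("cnn_embed", embed_dim = 8),
               class = "neorank_build_error")
  expect_error(build_submodel("cnn_embed", embed_dim = 8, t_max = 2),
               class = "neorank_build_error", regexp = "t_max")
})

test_that("training reduces loss on separable data and is seed-reproducible", {
  set.seed(21)
  n <- 200
  x <- rbind(matrix(rnorm(100 * 5, mean = 1.5), 100, 5),
             matrix(rnorm(100 * 5, mean = -1.5), 100, 5))
  labels <- rep(c("immunogenic", "non_immunogenic"), each = 100)
  cfg <- submodel_config("fcnn_tfidf")
  cfg$epochs <- 8L
  net <- build_submodel("fcnn_tfidf", input_dim = 5, config = cfg)
  m1 <- train_submodel(net, x, labels, seed = 3)
  hist <- tidy(m1)
  expect_equal(nrow(hist), 8)
  expect_lt(hist$train_loss[8], hist$train_loss[1])

  m2 <- train_submodel(net, x, labels, seed = 3)
  expect_equal(tidy(m1)$train_loss, tidy(m2)$train_loss, tolerance = 1e-6)
  expect_lt(abs(tidy(m1)$train_loss[1] - tidy(m2)$train_loss[1]), 1e-6)
})

test_that("each architecture can drive training loss near zero on 32 memorizable records", {
  set.seed(33)
  n <- 32
  x <- matrix(rnorm(n * 6), n, 6)
  labels <- rep(c("immunogenic", "non_immunogenic"), each = 16)

  cfg <- submodel_config("fcnn_tfidf")
  cfg$epochs <- 300L
  cfg$learning_rate <- 1e-2
  cfg$dropout <- 0
  net <- build_submodel("fcnn_tfidf", input_dim = 6, config = cfg)
  net$arch$dropout <- 0
  m <- train_submodel(net, x, labels, seed = 1)
  expect_lt(tidy(m)$train_loss[300], 0.05)

  # conv net on token-level embeddings of random peptides
  tab <- tibble::tibble(record_id = sprintf("r%02d", 1:n),
                        mutant_peptide = vapply(rep(9, n), random_peptide, character(1)),
                        hla_allele = "HLA-A*02:01", label = labels)
  emb <- hash_embedder(16)
  xt <- flatten_token_embeddings(embed_records(tokenize_records(tab, 4), emb, "none"))
  cfg2 <- submodel_config("cnn_embed")
  cfg2$epochs <- 150L
  cfg2$learning_rate <- 1e-2
  net2 <- build_submodel("cnn_embed", embed_dim = 16, t_max = attr(xt, "t_max"),
                         config = cfg2)
  net2$arch$dropout <- 0
  m2 <- train_submodel(net2, xt, labels, seed = 1)
  expect_lt(tidy(m2)$train_loss[150], 0.05)
})

test_that("scores are probabilities with deterministic ID tie-breaks", {
  set.seed(8)
  x <- matrix(rnorm(40 * 5), 40, 5)
  rownames(x) <- sprintf("r%02d", 1:40)
  labels <- rep(c("immunogenic", "non_immunogenic"), each = 20)
  cfg <- submodel_config("fcnn_tfidf"); cfg$epochs <- 3L
  m <- train_submodel(build_submodel("fcnn_tfidf", input_dim = 5, config = cfg),
                      x, labels, seed = 1)
  rl <- predict_scores(m, x)
  expect_true(all(rl$score >= 0 & rl$score <= 1))
  expect_equal(rl$rank, seq_len(40))
  expect_true(all(diff(rl$score) <= 0))

  # duplicated input row scores identically
  x2 <- x[c(1, 1), , drop = FALSE]
  rownames(x2) <- c("a", "b")
  rl2 <- predict_scores(m, x2)
  expect_equal(rl2$score[1], rl2$score[2])
  expect_equal(rl2$record_id, c("a", "b")) # tie broken lexicographically

  expect_error(predict_scores(m, x[, 1:3]), class = "neorank_shape_error")
})

test_that("ranking order is invariant under strictly monotone score transforms", {
  set.seed(44)
  for (rep in 1:20) {
    ids <- sprintf("r%02d", 1:15)
    scores <- runif(15)
    base <- new_ranked_list(ids, scores, "m")
    f <- sample(list(function(s) 2 * s + 1, function(s) exp(s),
                     function(s) s^3 + s, function(s) atan(s)), 1)[[1]]
    trans <- new_ranked_list(ids, f(scores), "m")
    expect_equal(base$record_id, trans$record_id)
  }
})

test_that("glance summarizes a trained submodel", {
  set.seed(1)
  x <- matrix(rnorm(20 * 4), 20, 4)
  labels <- rep(c("immunogenic", "non_immunogenic"), each = 10)
  cfg <- submodel_config("fcnn_embed"); cfg$epochs <- 2L
  m <- train_submodel(build_submodel("fcnn_embed", input_dim = 4, config = cfg),
                      x, labels, seed = 2)
  g <- glance(m)
  expect_equal(g$epochs, 2)
  expect_equal(g$n_params, (4 * 53 + 53) + (53 * 2 + 2))
})

test_that("training refuses divergence-free preconditions violations", {
  cfg <- submodel_config("fcnn_tfidf"); cfg$epochs <- 1L
  net <- build_submodel("fcnn_tfidf", input_dim = 3, config = cfg)
  expect_error(train_submodel(net, matrix(0, 0, 3), character(0)),
               class = "neorank_data_error")
})
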