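# End-to-end training and prediction: encoders + preprocessing + the three
# submodels + rank-level fusion.

#' Train the three-submodel immunogenicity ensemble
#'
#' Splits a curated dataset 60/20/20 (stratified by label), builds each
#' submodel's design matrix with its own encoder pipeline (TF-IDF on
#' 6-mers; token-level contextual embeddings of 4-mers; mean-pooled 2-mer
#' embeddings concatenated with the 11 z-scored structured features),
#' rebalances the training partition with SMOTE per design matrix, and
#' trains the three networks with their standard hyperparameters. The
#' TF-IDF vocabulary and the feature scaler are fitted on the training
#' partition only; SMOTE-synthetic rows are flagged and never leave the
#' training fold.
#'
#' @param data Curated tibble with `record_id`, `mutant_peptide`,
#'   `hla_allele`, `label` and feature columns `F1`..`F11`.
#' @param embedder A `contextual_embedder` (default [hash_embedder()]).
#' @param seed Integer master seed; submodel seeds derive from it.
#' @param use_smote Rebalance training folds with SMOTE (default `TRUE`).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param fractions Split fractions (default 0.6/0.2/0.2).
#' @param epochs Optional named list overriding per-submodel epoch counts
#'   (for quick experiments; defaults follow [submodel_config()]).
#' @return A `neorank_ensemble` object.
#' @export
train_immunogenicity_models <- function(data, embedder = hash_embedder(64),
                                        seed = 1, use_smote = TRUE, smote_k = 5,
                                        fractions = c(train = 0.6, validation = 0.2,
                                                      test = 0.2),
                                        epochs = NULL) {
  if (!all(paste0("F", 1:11) %in% names(data))) {
    abort_neorank("data must carry feature columns F1..F11 (see assemble_features)",
                  "neorank_schema_error")
  }
  parts <- split_dataset(data, fractions = fractions, seed = seed)

  # shared encoder state, fitted on the training partition
  tok6_train <- tokenize_records(parts$train, k = 6)
  tfidf <- fit_tfidf(tok6_train)
  t_max <- max(vapply(tokenize_records(data, k = 4)$tokens, length, integer(1)))
  feat_cols <- paste0("F", 1:11)
  feat_train <- as.matrix(parts$train[, feat_cols])
  attr(feat_train, "role") <- "train"
  scaler <- fit_scaler(feat_train)

  state <- list(tfidf = tfidf, t_max = t_max, embedder = embedder,
                scaler = scaler, feat_cols = feat_cols)

  submodels <- list()
  for (mi in seq_along(SUBMODEL_NAMES)) {
    name <- SUBMODEL_NAMES[mi]
    config <- submodel_config(name)
    if (!is.null(epochs[[name]])) config$epochs <- as.integer(epochs[[name]])
    x_train <- encode_for_submodel(state, parts$train, name)
    x_val <- encode_for_submodel(state, parts$validation, name)
    y_train <- parts$train$label
    if (use_smote) {
      sm <- smote(x_train, y_train, k_neighbors = smote_k,
                  seed = seed * 100 + mi)
      x_train <- sm$x
      y_train <- sm$labels
    }
    net <- if (name == "cnn_embed") {
      build_submodel(name, embed_dim = embedder$dimension, t_max = t_max,
                     config = config)
    } else {
      build_submodel(name, input_dim = ncol(x_train), config = config)
    }
    submodels[[name]] <- train_submodel(net, x_train, y_train,
                                        x_val = x_val,
                                        labels_val = parts$validation$label,
                                        seed = seed * 10 + mi)
  }
  structure(list(submodels = submodels, state = state, split = parts,
                 seed = seed, use_smote = use_smote),
            class = "neorank_ensemble")
}

# Build the design matrix a named submodel consumes, using fitted encoder
# state (never refitted here).
encode_for_submodel <- function(state, data, name) {
  role <- attr(data, "role")
  if (name == "fcnn_tfidf") {
    tok <- tokenize_records(data, k = 6)
    transform_tfidf(state$tfidf, tok)
  } else if (name == "cnn_embed") {
    tok <- tokenize_records(data, k = 4)
    emb <- embed_records(tok, state$embedder, pooling = "none")
    flatten_token_embeddings(emb, t_max = state$t_max)
  } else if (name == "fcnn_embed") {
    tok <- tokenize_records(data, k = 2)
    pooled <- embed_records(tok, state$embedder, pooling = "mean")
    feats <- as.matrix(data[, state$feat_cols])
    scaled <- apply_scaler(state$scaler, feats)
    out <- cbind(unclass(pooled), unclass(scaled))
    rownames(out) <- data$record_id
    new_encoded_matrix(out, encoder_tag = "embed_mean_plus_features",
                       role = role)
  } else {
    abort_neorank(paste0("unknown submodel: ", name), "neorank_build_error")
  }
}

#' Score new records with every submodel of a trained ensemble
#'
#' @param object A `neorank_ensemble`.
#' @param data Curated tibble of records (with `F1`..`F11`).
#' @param ... Unused.
#' @return Named list of `ranked_list` tibbles, one per submodel.
#' @export
predict.neorank_ensemble <- function(object, data, ...) {
  lapply(object$submodels, function(m) {
    x <- encode_for_submodel(object$state, data, m$name)
    predict_scores(m, x, record_ids = data$record_id)
  })
}

#' Rank candidates with the fused consensus ensemble
#'
#' @param ensemble A trained `neorank_ensemble`.
#' @param data Curated tibble of candidate records.
#' @param top_n Per-model top-list size for the consensus rule (default 50).
#' @return A `consensus_ranking` tibble.
#' @export
rank_candidates <- function(ensemble, data, top_n = 50) {
  fuse_rankings(predict(ensemble, data), top_n = top_n)
}

#' Evaluate a trained ensemble on held-out records
#'
#' Computes each submodel's ROC AUC and Top-N capture on the given records
#' plus the fused consensus ranking's Top-N capture.
#'
#' @param ensemble A trained `neorank_ensemble`.
#' @param data Held-out curated tibble with labels (defaults to the test
#'   partition stored in the ensemble).
#' @param n_values Top-N prefix sizes (default `c(10, 20, 50)`).
#' @param top_n Consensus top-list size (default 50).
#' @return List with `auc` (named numeric), `topn` (tibble with per-model
#'   and fused capture), and the fused `ranking`.
#' @export
evaluate_ensemble <- function(ensemble, data = NULL, n_values = c(10, 20, 50),
                              top_n = 50) {
  data <- data %||% ensemble$split$test
  truth <- stats::setNames(data$label, data$record_id)
  ranked <- predict(ensemble, data)
  auc <- vapply(ranked, function(rl) {
    roc_auc(rl$score, truth[rl$record_id])
  }, numeric(1))
  fused <- fuse_rankings(ranked, top_n = top_n)
  topn <- dplyr::bind_rows(
    purrr::imap_dfr(ranked, function(rl, nm) {
      dplyr::mutate(top_n_capture(rl, truth, n_values), model = nm)
    }),
    dplyr::mutate(top_n_capture(fused, truth, n_values), model = "ensemble")
  )
  list(auc = auc, topn = topn, ranking = fused)
}

#' @export
print.neorank_ensemble <- function(x, ...) {
  cat(sprintf("Immunogenicity ensemble: %s (seed %d)\n",
              paste(names(x$submodels), collapse = " + "), x$seed))
  cat(sprintf("Partitions: %d train / %d validation / %d test\n",
              nrow(x$split$train), nrow(x$split$validation), nrow(x$split$test)))
  invisible(x)
}
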