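# The three immunogenicity submodels and their training wiring.
#
# Each submodel pairs one encoder pipeline with one network:
#   fcnn_tfidf : merged peptide|HLA strings, 6-mer slicing, TF-IDF (l2),
#                dense net hidden 64, dropout 0.2, 45 epochs
#   cnn_embed  : 4-mer slicing, token-level contextual embeddings,
#                parallel conv widths 3/4/5 x 120 filters, dropout 0.1,
#                19 epochs
#   fcnn_embed : 2-mer slicing, mean-pooled contextual embeddings
#                concatenated with the 11 z-scored structured features,
#                dense net hidden 53, dropout 0.5, 31 epochs
# All train with Adam (lr 1e-4), batch size 32, two-class cross-entropy.

SUBMODEL_NAMES <- c("fcnn_tfidf", "cnn_embed", "fcnn_embed")

#' Default configuration of a named submodel
#'
#' @param name One of `"fcnn_tfidf"`, `"cnn_embed"`, `"fcnn_embed"`.
#' @return List of encoder and training settings.
#' @export
submodel_config <- function(name = SUBMODEL_NAMES) {
  name <- match.arg(name)
  switch(name,
    fcnn_tfidf = list(name = name, k = 6L, encoder = "tfidf",
                      hidden_size = 64L, dropout = 0.2,
                      batch_size = 32L, epochs = 45L, learning_rate = 1e-4,
                      optimizer = "adam"),
    cnn_embed = list(name = name, k = 4L, encoder = "token_embedding",
                     kernel_widths = c(3L, 4L, 5L), filters = 120L,
                     dropout = 0.1,
                     batch_size = 32L, epochs = 19L, learning_rate = 1e-4,
                     optimizer = "adam"),
    fcnn_embed = list(name = name, k = 2L, encoder = "pooled_embedding_plus_features",
                      hidden_size = 53L, dropout = 0.5,
                      batch_size = 32L, epochs = 31L, learning_rate = 1e-4,
                      optimizer = "adam")
  )
}

#' Build an untrained submodel for given input shapes
#'
#' @param name Submodel name (see [submodel_config()]).
#' @param input_dim Input dimension for the dense submodels.
#' @param embed_dim,t_max Embedding dimension and fixed token count for the
#'   convolutional submodel.
#' @param config Optional configuration override from [submodel_config()].
#' @return An object of class `neorank_net` holding the architecture and
#'   configuration; parameters are initialized at training time.
#' @export
build_submodel <- function(name = SUBMODEL_NAMES, input_dim = NULL,
                           embed_dim = NULL, t_max = NULL, config = NULL) {
  name <- match.arg(name)
  config <- config %||% submodel_config(name)
  if (name == "cnn_embed") {
    if (is.null(embed_dim) || is.null(t_max)) {
      abort_neorank("cnn_embed requires embed_dim and t_max", "neorank_build_error")
    }
    if (t_max < max(config$kernel_widths)) {
      abort_neorank(sprintf("t_max (%d) is smaller than the widest kernel (%d)",
                            t_max, max(config$kernel_widths)),
                    "neorank_build_error")
    }
    arch <- new_cnn_arch(embed_dim, t_max, config$kernel_widths,
                         config$filters, config$dropout)
  } else {
    if (is.null(input_dim) || input_dim < 1) {
      abort_neorank(sprintf("%s requires a positive input_dim", name),
                    "neorank_build_error")
    }
    arch <- new_fcnn_arch(input_dim, config$hidden_size, config$dropout)
  }
  structure(list(name = name, arch = arch, config = config),
            class = "neorank_net")
}

#' Train a submodel
#'
#' Runs exactly `config$epochs` epochs of mini-batch Adam on the two-class
#' cross-entropy. Validation data, when given, is used for monitoring only
#' (no early stopping). Rows flagged as SMOTE-synthetic are allowed in
#' training input; validation input must not contain any.
#'
#' @param net An untrained `neorank_net` from [build_submodel()].
#' @param x Training design matrix.
#' @param labels Training labels (`"immunogenic"` / `"non_immunogenic"`).
#' @param x_val,labels_val Optional validation design matrix and labels.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; fixed seed gives a reproducible loss history.
#' @return A `neorank_submodel` with fitted parameters and an epoch-wise
#'   loss history.
#' @export
train_submodel <- function(net, x, labels, x_val = NULL, labels_val = NULL,
                           seed = 1) {
  if (!inherits(net, "neorank_net")) {
    abort_neorank("net must come from build_submodel()", "neorank_state_error")
  }
  syn_val <- attr(x_val, "synthetic")
  if (!is.null(syn_val) && any(syn_val)) {
    abort_neorank("validation data contains SMOTE-synthetic rows",
                  "neorank_leakage_error")
  }
  if (ncol(x) != expected_input_cols(net$arch)) {
    abort_neorank(sprintf("design matrix has %d columns; architecture expects %d",
                          ncol(x), expected_input_cols(net$arch)),
                  "neorank_shape_error")
  }
  y01 <- labels_to01(labels)
  yv <- if (!is.null(labels_val)) labels_to01(labels_val) else NULL
  fit <- train_network(net$arch, unclass(x), y01,
                       x_val = if (is.null(x_val)) NULL else unclass(x_val),
                       y_val = yv,
                       batch_size = net$config$batch_size,
                       epochs = net$config$epochs,
                       lr = net$config$learning_rate,
                       seed = seed)
  structure(list(name = net$name, arch = net$arch, config = net$config,
                 params = fit$params, history = fit$history, seed = seed),
            class = "neorank_submodel")
}

expected_input_cols <- function(arch) {
  if (arch$type == "fcnn") arch$input_dim else arch$t_max * arch$embed_dim
}

labels_to01 <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("immunogenic", "non_immunogenic"))
  if (length(bad) > 0) {
    abort_neorank(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
                  "neorank_value_error")
  }
  as.integer(labels == "immunogenic")
}

#' Predict immunogenicity scores and rank candidates
#'
#' Scores are the softmax probability of the immunogenic class, so they lie
#' in `[0, 1]` and are deterministic for a trained model. The returned
#' ranking is descending by score with a lexicographic record-ID tie-break.
#' Rows flagged as SMOTE-synthetic are refused: synthetic samples exist for
#' training folds only and must never be evaluated.
#'
#' @param model A trained `neorank_submodel`.
#' @param x Design matrix encoded with the model's own encoder pipeline,
#'   with record IDs as rownames (or supplied via `record_ids`).
#' @param record_ids Optional record identifiers aligned to rows.
#' @return A `ranked_list` tibble (`record_id`, `score`, `rank`) with a
#'   `model_tag` attribute.
#' @export
predict_scores <- function(model, x, record_ids = NULL) {
  if (!inherits(model, "neorank_submodel")) {
    abort_neorank("model is not a trained submodel", "neorank_state_error")
  }
  syn <- attr(x, "synthetic")
  if (!is.null(syn) && any(syn)) {
    abort_neorank("refusing to score SMOTE-synthetic rows", "neorank_leakage_error")
  }
  if (ncol(x) != expected_input_cols(model$arch)) {
    abort_neorank(sprintf("design matrix has %d columns; model expects %d",
                          ncol(x), expected_input_cols(model$arch)),
                  "neorank_shape_error")
  }
  ids <- record_ids %||% rownames(x)
  if (is.null(ids)) ids <- make_record_ids(nrow(x))
  logits <- net_forward_logits(model$arch, model$params, unclass(x))
  score <- softmax_rows(logits)[, 2]
  new_ranked_list(ids, score, model$name)
}

#' Construct a ranked list from scores
#'
#' Orders records by descending score with a lexicographic record-ID
#' tie-break and assigns ranks 1..n. Useful for building `ranked_list`
#' objects from externally computed score tables before [fuse_rankings()].
#'
#' @param ids Record identifiers.
#' @param scores Numeric scores aligned to `ids`.
#' @param model_tag Label for the scoring model.
#' @return A `ranked_list` tibble.
#' @export
new_ranked_list <- function(ids, scores, model_tag) {
  scores <- unname(scores)
  ord <- order(-scores, ids)
  out <- tibble::tibble(record_id = ids[ord], score = scores[ord],
                        rank = seq_along(ids))
  attr(out, "model_tag") <- model_tag
  class(out) <- c("ranked_list", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained submodel's loss history
#'
#' @param x A `neorank_submodel`.
#' @param ... Unused.
#' @return Tibble (`epoch`, `train_loss`, `val_loss`).
#' @method tidy neorank_submodel
#' @export
tidy.neorank_submodel <- function(x, ...) {
  x$history
}

#' One-row summary of a trained submodel
#'
#' @param x A `neorank_submodel`.
#' @param ... Unused.
#' @return One-row tibble with the architecture and final losses.
#' @method glance neorank_submodel
#' @export
glance.neorank_submodel <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_params = n_params(x),
    epochs = nrow(x$history),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    final_val_loss = x$history$val_loss[nrow(x$history)],
    seed = x$seed
  )
}

#' @export
print.neorank_submodel <- function(x, ...) {
  cat(sprintf("Trained submodel '%s' (%d parameters, %d epochs)\n",
              x$name, n_params(x), nrow(x$history)))
  invisible(x)
}

#' @export
print.neorank_net <- function(x, ...) {
  cat(sprintf("Untrained submodel '%s' (%d parameters when initialized)\n",
              x$name, n_params(x$arch)))
  invisible(x)
}
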