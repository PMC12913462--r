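# Feature scaling, SMOTE rebalancing and dataset splitting.

#' Fit a z-score scaler on a training design matrix
#'
#' Column means and standard deviations (population convention, divisor n)
#' are estimated on the training matrix only, so that transforming the
#' fitting data yields per-column mean 0 and standard deviation 1 for
#' non-constant columns. Fitting on a matrix tagged with a non-training
#' role is an error: held-out statistics must never leak into the scaler.
#'
#' @param train_matrix Numeric matrix (typically an `encoded_matrix` carrying
#'   a `role` attribute).
#' @return A `zscore_scaler` object.
#' @export
fit_scaler <- function(train_matrix) {
  role <- attr(train_matrix, "role")
  if (!is.null(role) && !identical(role, "train")) {
    abort_neorank(
      sprintf("scaler must be fitted on the training partition, not '%s'", role),
      "neorank_role_error"
    )
  }
  m <- colMeans(train_matrix)
  s <- sqrt(colMeans(sweep(unclass(train_matrix), 2, m)^2))
  structure(list(means = m, stds = s, fitted_on = role %||% "untagged",
                 n_fit = nrow(train_matrix)),
            class = "zscore_scaler")
}

#' Apply a fitted z-score scaler
#'
#' @param scaler A `zscore_scaler` from [fit_scaler()].
#' @param matrix Numeric matrix with the same columns as the fitting data.
#' @return The transformed matrix; constant columns (std 0) map to 0 with a
#'   warning.
#' @export
apply_scaler <- function(scaler, matrix) {
  if (!inherits(scaler, "zscore_scaler")) {
    abort_neorank("scaler has not been fitted", "neorank_state_error")
  }
  if (ncol(matrix) != length(scaler$means)) {
    abort_neorank(sprintf("matrix has %d columns but scaler was fitted on %d",
                          ncol(matrix), length(scaler$means)),
                  "neorank_shape_error")
  }
  s <- scaler$stds
  const <- s == 0
  if (any(const)) {
    warning(sprintf("%d constant column(s) mapped to 0", sum(const)))
    s[const] <- 1
  }
  out <- sweep(sweep(unclass(matrix), 2, scaler$means), 2, s, "/")
  out[, const] <- 0
  keep_attrs <- c("encoder_tag", "role", "synthetic", "t_max", "embed_dim")
  for (a in keep_attrs) attr(out, a) <- attr(matrix, a)
  class(out) <- class(matrix)
  out
}

#' Rebalance a training matrix with SMOTE
#'
#' Synthetic minority over-sampling: each synthetic row is
#' `x + u * (x_nn - x)` for a minority point `x`, one of its `k_neighbors`
#' nearest minority neighbors `x_nn` (Euclidean), and `u ~ Uniform(0, 1)`.
#' Originals are unchanged; synthetic rows are flagged so they can never
#' leak into evaluation (scoring a flagged row is an error downstream).
#' Only training-tagged input may be rebalanced.
#'
#' @param train_matrix Numeric design matrix (rows = records).
#' @param labels Factor or character vector of two classes, aligned to rows.
#' @param k_neighbors Number of nearest minority neighbors (default 5;
#'   must be smaller than the minority class size).
#' @param target_ratio Desired minority/majority ratio in (0, 1]; 1 (the
#'   default) balances the classes fully.
#' @param seed Integer seed for neighbor choice and interpolation.
#' @return A list with `x` (augmented matrix), `labels`, and `synthetic`
#'   (logical flag per row; also attached to `x` as an attribute).
#' @export
smote <- function(train_matrix, labels, k_neighbors = 5, target_ratio = 1,
                  seed = 1) {
  role <- attr(train_matrix, "role")
  if (!is.null(role) && !identical(role, "train")) {
    abort_neorank("SMOTE may only be applied to the training partition",
                  "neorank_role_error")
  }
  labels <- as.character(labels)
  tab <- sort(table(labels))
  if (length(tab) != 2) {
    abort_neorank("SMOTE requires exactly two classes in the labels",
                  "neorank_class_error")
  }
  minority <- names(tab)[1]
  n_min <- tab[[1]]
  n_maj <- tab[[2]]
  if (k_neighbors >= n_min) {
    abort_neorank(sprintf("k_neighbors (%d) must be smaller than the minority class size (%d)",
                          k_neighbors, n_min),
                  "neorank_config_error")
  }
  stopifnot(target_ratio > 0, target_ratio <= 1)
  n_target <- floor(target_ratio * n_maj)
  n_new <- max(0L, n_target - n_min)
  x <- unclass(train_matrix)
  if (n_new == 0) {
    return(list(x = train_matrix, labels = labels,
                synthetic = rep(FALSE, nrow(x))))
  }
  min_idx <- which(labels == minority)
  xm <- x[min_idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(xm))^2
  diag(d2) <- Inf
  ords <- apply(d2, 1, function(row) order(row)[seq_len(k_neighbors)])
  nn <- if (k_neighbors == 1) matrix(ords, ncol = 1) else t(ords)
  synth <- with_seed(seed, {
    base_pick <- sample(rep_len(seq_len(n_min), n_new))
    nb_pick <- nn[cbind(base_pick, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    xm[base_pick, , drop = FALSE] +
      u * (xm[nb_pick, , drop = FALSE] - xm[base_pick, , drop = FALSE])
  })
  rownames(synth) <- sprintf("synthetic%05d", seq_len(n_new))
  x_aug <- rbind(x, synth)
  flags <- c(rep(FALSE, nrow(x)), rep(TRUE, n_new))
  out <- x_aug
  for (a in c("encoder_tag", "t_max", "embed_dim")) {
    attr(out, a) <- attr(train_matrix, a)
  }
  attr(out, "role") <- role
  attr(out, "synthetic") <- flags
  class(out) <- class(train_matrix)
  list(x = out, labels = c(labels, rep(minority, n_new)), synthetic = flags)
}

#' Split a dataset into train / validation / test partitions
#'
#' Partitions are disjoint, their union is the input, and sizes match the
#' requested fractions within rounding. Splits are stratified by label by
#' default so that class proportions are preserved within one record per
#' partition.
#'
#' @param data Curated tibble of records with a `label` column.
#' @param fractions Named numeric of train/validation/test fractions summing
#'   to 1 (default `c(train = 0.6, validation = 0.2, test = 0.2)`).
#' @param stratify Stratify by label (default `TRUE`).
#' @param seed Integer seed.
#' @return Named list of three tibbles (`train`, `validation`, `test`), each
#'   tagged with a `role` attribute, plus a `manifest` tibble
#'   (`record_id`, `partition`).
#' @export
split_dataset <- function(data, fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                          stratify = TRUE, seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0),
            all(c("train", "validation", "test") %in% names(fractions)))
  n <- nrow(data)
  part <- character(n)
  # Rounding can over/undershoot by one record; the training slot absorbs it.
  if (stratify) {
    for (lv in unique(data$label)) {
      idx <- which(data$label == lv)
      shuffled <- with_seed(seed + match(lv, sort(unique(data$label))), sample(idx))
      sizes <- round(length(idx) * fractions[c("train", "validation", "test")])
      sizes["train"] <- length(idx) - sizes["validation"] - sizes["test"]
      part[shuffled] <- rep(c("train", "validation", "test"), sizes)
    }
  } else {
    shuffled <- with_seed(seed, sample(seq_len(n)))
    sizes <- round(n * fractions[c("train", "validation", "test")])
    sizes["train"] <- n - sizes["validation"] - sizes["test"]
    part[shuffled] <- rep(c("train", "validation", "test"), sizes)
  }
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(p) {
                  d <- data[part == p, , drop = FALSE]
                  attr(d, "role") <- p
                  d
                })
  out$manifest <- tibble::tibble(record_id = data$record_id, partition = part)
  out
}

#' Assign k-fold cross-validation folds
#'
#' @param data Curated tibble with `record_id` and `label`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratify Stratify folds by label (default `TRUE`).
#' @return Tibble (`record_id`, `fold`) with folds 1..k.
#' @export
kfold_assign <- function(data, k = 5, seed = 1, stratify = TRUE) {
  stopifnot(k >= 2)
  n <- nrow(data)
  fold <- integer(n)
  if (stratify) {
    for (lv in unique(data$label)) {
      idx <- which(data$label == lv)
      if (length(idx) < k) {
        abort_neorank(sprintf("class '%s' has %d records, fewer than %d folds",
                              lv, length(idx), k),
                      "neorank_stratification_error")
      }
      shuffled <- with_seed(seed + match(lv, sort(unique(data$label))), sample(idx))
      fold[shuffled] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    shuffled <- with_seed(seed, sample(seq_len(n)))
    fold[shuffled] <- rep_len(seq_len(k), n)
  }
  tibble::tibble(record_id = data$record_id, fold = fold)
}
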