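# Evaluation metrics, dataset characterization statistics and ELISpot
# response classification.

#' Top-N capture of truly immunogenic candidates
#'
#' Counts how many truly immunogenic records fall within the first `n`
#' positions of a ranking, for each requested `n`.
#'
#' @param ranking A `ranked_list` or `consensus_ranking` tibble (any tibble
#'   with `record_id` ordered by rank works).
#' @param truth Named character vector (or tibble with `record_id`,
#'   `label`) mapping every ranked record to its label.
#' @param n_values Prefix sizes, default `c(10, 20, 50)`.
#' @return A `topn_report` tibble (`n`, `captured`).
#' @export
top_n_capture <- function(ranking, truth, n_values = c(10, 20, 50)) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth$label), truth$record_id)
  }
  ids <- ranking$record_id
  missing_ids <- setdiff(ids, names(truth))
  if (length(missing_ids) > 0) {
    abort_neorank(paste0("record(s) missing from truth: ",
                         paste(utils::head(missing_ids, 5), collapse = ", ")),
                  "neorank_coverage_error")
  }
  pos <- truth[ids] == "immunogenic"
  captured <- vapply(n_values, function(n) sum(pos[seq_len(min(n, length(pos)))]),
                     numeric(1))
  out <- tibble::tibble(n = as.integer(n_values), captured = as.integer(captured))
  class(out) <- c("topn_report", class(out))
  out
}

#' Plot a Top-N capture report
#'
#' @param object A `topn_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topn_report
#' @export
autoplot.topn_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$n), y = .data$captured)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "top N", y = "immunogenic peptides captured") +
    ggplot2::theme_minimal()
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney U) formulation with ties counted
#' one half, so the value is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Labels; `"immunogenic"`/`"non_immunogenic"`, a factor, or
#'   0/1 with 1 the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else labels_to01(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort_neorank("AUC is undefined with a single class", "neorank_metric_error")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Characterize a labeled peptide dataset
#'
#' Compares immunogenic versus non-immunogenic peptides: a chi-square test
#' on the peptide length contingency table, per-position chi-square tests
#' of residue frequencies (residues whose expected count falls below
#' `min_expected` in any cell are pooled into an `"other"` category before
#' testing), and per-position residue frequency tables normalized to sum
#' to one per position and class.
#'
#' @param data Curated tibble with `mutant_peptide` and `label`.
#' @param min_expected Pooling threshold for sparse cells (default 5).
#' @param p_adjust Multiple-testing correction for the positional p-values
#'   (`"none"` by default; any method of [stats::p.adjust()]).
#' @return A list of class `dataset_characterization`: `length_test`
#'   (one-row tibble), `positional_tests` (tibble per position) and
#'   `residue_frequencies` (long tibble).
#' @export
characterize_dataset <- function(data, min_expected = 5, p_adjust = "none") {
  dat <- dplyr::filter(data, .data$label %in% c("immunogenic", "non_immunogenic"))
  if (length(unique(dat$label)) < 2) {
    abort_neorank("both classes must be present", "neorank_class_error")
  }
  len <- nchar(dat$mutant_peptide)
  tab_len <- table(factor(len, levels = sort(unique(len))), dat$label)
  lt <- suppressWarnings(stats::chisq.test(tab_len, correct = FALSE))
  length_test <- tibble::tibble(statistic = unname(lt$statistic),
                                df = unname(lt$parameter),
                                p_value = lt$p.value)

  max_len <- max(len)
  pos_rows <- vector("list", max_len)
  freq_rows <- vector("list", max_len)
  for (p in seq_len(max_len)) {
    sel <- len >= p
    residues <- substr(dat$mutant_peptide[sel], p, p)
    labs <- dat$label[sel]
    tab <- table(residues, labs)
    freq <- prop.table(tab, margin = 2)
    freq_rows[[p]] <- tibble::as_tibble(as.data.frame(freq)) |>
      stats::setNames(c("residue", "label", "frequency")) |>
      dplyr::mutate(position = p, .before = 1)
    test <- positional_chisq(tab, min_expected)
    pos_rows[[p]] <- tibble::tibble(
      position = p, n_peptides = sum(sel),
      n_categories = test$n_categories,
      statistic = test$statistic, df = test$df, p_value = test$p_value
    )
  }
  positional_tests <- dplyr::bind_rows(pos_rows)
  positional_tests$p_value <- stats::p.adjust(positional_tests$p_value,
                                              method = p_adjust)
  structure(list(length_test = length_test,
                 positional_tests = positional_tests,
                 residue_frequencies = dplyr::bind_rows(freq_rows)),
            class = "dataset_characterization")
}

# Chi-square on a residues x class table with sparse-residue pooling.
positional_chisq <- function(tab, min_expected = 5) {
  tab <- as.matrix(tab)
  if (nrow(tab) >= 2) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sparse <- apply(expected, 1, min) < min_expected
    if (any(sparse) && sum(sparse) > 1) {
      pooled <- colSums(tab[sparse, , drop = FALSE])
      tab <- rbind(tab[!sparse, , drop = FALSE], other = pooled)
    }
  }
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                n_categories = nrow(tab)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, n_categories = nrow(tab))
}

#' @export
print.dataset_characterization <- function(x, ...) {
  cat(sprintf("Length distribution chi-square: X2 = %.3f, p = %.3g\n",
              x$length_test$statistic, x$length_test$p_value))
  sig <- sum(x$positional_tests$p_value < 0.05, na.rm = TRUE)
  cat(sprintf("Positional tests: %d of %d positions significant at 0.05\n",
              sig, nrow(x$positional_tests)))
  invisible(x)
}

#' Statistical screen of structured immunogenicity features
#'
#' For a feature matrix and binary labels: pairwise Spearman correlations,
#' per-feature Shapiro-Wilk normality tests, per-feature Mann-Whitney U
#' tests between classes, and a random-forest relative importance ranking
#' (importances normalized to sum to one). Constant features yield `NA`
#' correlations, reported as missing rather than silently zero.
#'
#' @param features Numeric matrix or data frame of features (rows = records).
#' @param labels Class labels aligned to rows.
#' @param n_trees Random-forest size (default 500).
#' @param seed Seed for the forest.
#' @return A list of class `feature_stats_report`: `spearman` (matrix),
#'   `tests` (tibble with `shapiro_p`, `mannwhitney_p`), `importance`
#'   (tibble sorted by decreasing importance).
#' @export
feature_stats <- function(features, labels, n_trees = 500, seed = 1) {
  fm <- as.matrix(features)
  y <- factor(labels_to01(labels), levels = c(0, 1))
  if (min(table(y)) < 3) {
    abort_neorank("need at least 3 records per class", "neorank_class_error")
  }
  spearman <- suppressWarnings(stats::cor(fm, method = "spearman"))
  tests <- purrr::map_dfr(seq_len(ncol(fm)), function(j) {
    v <- fm[, j]
    sh <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    mw <- tryCatch(
      suppressWarnings(stats::wilcox.test(v[y == 1], v[y == 0])$p.value),
      error = function(e) NA_real_
    )
    tibble::tibble(feature = colnames(fm)[j] %||% paste0("V", j),
                   shapiro_p = sh, mannwhitney_p = mw)
  })
  rf <- with_seed(seed, randomForest::randomForest(x = fm, y = y, ntree = n_trees))
  imp <- randomForest::importance(rf)[, 1]
  imp <- imp / sum(imp)
  importance <- tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  structure(list(spearman = spearman, tests = tests, importance = importance,
                 n_trees = n_trees, seed = seed),
            class = "feature_stats_report")
}

#' @export
print.feature_stats_report <- function(x, ...) {
  cat(sprintf("Feature screen over %d features (%d-tree forest)\n",
              nrow(x$tests), x$n_trees))
  cat("Top features by importance:\n")
  print(utils::head(x$importance, 3))
  invisible(x)
}

#' ELISpot response thresholds
#'
#' Background-subtracted mean spot counts of at least `weak_min` are
#' positive; counts of at least `strong_min` are strong positives (strong
#' takes precedence at the shared boundary, so weak = \[weak_min,
#' strong_min)).
#'
#' @param weak_min Minimum spots for a weak positive (default 8).
#' @param strong_min Minimum spots for a strong positive (default 81).
#' @return An `elispot_thresholds` object.
#' @export
elispot_thresholds <- function(weak_min = 8, strong_min = 81) {
  stopifnot(weak_min > 0, strong_min > weak_min)
  structure(list(weak_min = weak_min, strong_min = strong_min),
            class = "elispot_thresholds")
}

#' Classify ELISpot responses
#'
#' Per peptide: replicate outliers are removed (default rule: the
#' Iglewicz-Hoaglin modified z-score, dropping replicates with
#' `0.6745 |x - median| / MAD > outlier_cut` when at least three
#' replicates are available; a mean-based 2-SD rule cannot fire at typical
#' replicate counts because a lone outlier inflates the standard deviation
#' it is judged against), the remaining replicates are averaged, the
#' background mean is subtracted and the result floored at zero, and the
#' adjusted count is thresholded into negative / weak / strong.
#'
#' @param data Tibble with `peptide_id`, one or more replicate columns
#'   (names starting `"rep"`), and `background_mean`.
#' @param thresholds An [elispot_thresholds()] object.
#' @param outlier_cut Modified z-score cut (default 3.5); `Inf` disables
#'   outlier removal.
#' @return An `elispot_result` tibble (`peptide_id`, `n_replicates_used`,
#'   `adjusted_count`, `response`) carrying a `summary` attribute with
#'   weak/strong/total positive percentages (see [elispot_summary()]).
#' @export
classify_elispot <- function(data, thresholds = elispot_thresholds(),
                             outlier_cut = 3.5) {
  rep_cols <- grep("^rep", names(data), value = TRUE)
  if (length(rep_cols) == 0) {
    abort_neorank("no replicate columns (names starting with 'rep') found",
                  "neorank_schema_error")
  }
  if (!"background_mean" %in% names(data)) {
    abort_neorank("background_mean column required", "neorank_schema_error")
  }
  reps <- as.matrix(data[, rep_cols])
  if (any(reps < 0, na.rm = TRUE)) {
    abort_neorank("negative replicate spot counts are not allowed",
                  "neorank_value_error")
  }
  out <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    counts <- reps[i, ]
    counts <- counts[!is.na(counts)]
    if (length(counts) == 0) {
      abort_neorank(sprintf("peptide %s has no replicates", data$peptide_id[i]),
                    "neorank_value_error")
    }
    if (length(counts) >= 3 && is.finite(outlier_cut)) {
      med <- stats::median(counts)
      mad0 <- stats::median(abs(counts - med))
      scale <- if (mad0 > 0) mad0 else mean(abs(counts - med))
      if (scale > 0) {
        keep <- 0.6745 * abs(counts - med) / scale <= outlier_cut
        counts <- counts[keep]
      }
    }
    adjusted <- max(0, mean(counts) - data$background_mean[i])
    response <- if (adjusted >= thresholds$strong_min) {
      "strong"
    } else if (adjusted >= thresholds$weak_min) {
      "weak"
    } else {
      "negative"
    }
    tibble::tibble(peptide_id = data$peptide_id[i],
                   n_replicates_used = length(counts),
                   adjusted_count = adjusted,
                   response = response)
  })
  n <- nrow(out)
  n_weak <- sum(out$response == "weak")
  n_strong <- sum(out$response == "strong")
  attr(out, "summary") <- tibble::tibble(
    n_peptides = n, n_weak = n_weak, n_strong = n_strong,
    weak_rate_pct = 100 * n_weak / n,
    strong_rate_pct = 100 * n_strong / n,
    positive_rate_pct = 100 * (n_weak + n_strong) / n
  )
  attr(out, "thresholds") <- thresholds
  class(out) <- c("elispot_result", class(out))
  out
}

#' Summary rates of an ELISpot classification
#'
#' @param result An `elispot_result` from [classify_elispot()].
#' @return One-row tibble of counts and weak/strong/total positive
#'   percentages.
#' @export
elispot_summary <- function(result) {
  s <- attr(result, "summary")
  if (is.null(s)) {
    abort_neorank("not a classified ELISpot result", "neorank_state_error")
  }
  s
}

#' Plot background-subtracted ELISpot responses
#'
#' @param object An `elispot_result`.
#' @param ... Unused.
#' @return A ggplot object with the weak and strong thresholds marked.
#' @method autoplot elispot_result
#' @export
autoplot.elispot_result <- function(object, ...) {
  th <- attr(object, "thresholds")
  dat <- dplyr::arrange(object, dplyr::desc(.data$adjusted_count))
  dat$peptide_id <- factor(dat$peptide_id, levels = dat$peptide_id)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$peptide_id,
                                    y = .data$adjusted_count,
                                    fill = .data$response)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = th$weak_min, linetype = "dashed",
                        colour = "#d6604d") +
    ggplot2::geom_hline(yintercept = th$strong_min, linetype = "dashed",
                        colour = "#1b7837") +
    ggplot2::labs(x = NULL, y = "background-subtracted spots") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
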