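# Rank-level late-fusion consensus over submodel rankings.

#' Fuse submodel rankings into a consensus ordering
#'
#' Implements the rank-level late-fusion rule: the top `top_n` candidates
#' of each submodel are selected, and candidates appearing in at least two
#' of those top lists are consensus candidates, prioritized at the head of
#' the fused ranking. Within the consensus block the order is support count
#' (descending), then mean per-model rank (ascending), then record ID. The
#' remaining candidates follow in descending order of their best
#' (per-model min-max normalized) score, record-ID tie-break. Scores from
#' different submodels live on different scales, hence the normalization;
#' set `remainder_score = "raw"` to rank the remainder by raw scores
#' instead.
#'
#' @param rankings List of 2-3 `ranked_list` tibbles over the same
#'   candidate set (see [predict_scores()]).
#' @param top_n Per-model top-list size (default 50).
#' @param remainder_score `"max_minmax"` (default) or `"raw"`.
#' @return A `consensus_ranking` tibble with columns `rank`, `record_id`,
#'   `consensus`, `support`, `mean_rank` and `fused_score`.
#' @export
fuse_rankings <- function(rankings, top_n = 50,
                          remainder_score = c("max_minmax", "raw")) {
  remainder_score <- match.arg(remainder_score)
  stopifnot(top_n >= 1)
  if (!is.list(rankings) || length(rankings) < 2 || length(rankings) > 3) {
    abort_neorank("rankings must be a list of 2-3 ranked lists", "neorank_input_error")
  }
  for (rl in rankings) {
    if (anyDuplicated(rl$record_id)) {
      abort_neorank("duplicate record IDs within a ranked list", "neorank_input_error")
    }
  }
  ids0 <- sort(rankings[[1]]$record_id)
  for (rl in rankings[-1]) {
    if (!identical(sort(rl$record_id), ids0)) {
      diff <- union(setdiff(rl$record_id, ids0), setdiff(ids0, rl$record_id))
      abort_neorank(paste0("candidate sets differ between ranked lists: ",
                           paste(utils::head(diff, 10), collapse = ", ")),
                    "neorank_input_error")
    }
  }

  n_models <- length(rankings)
  ranks <- vapply(rankings, function(rl) rl$rank[match(ids0, rl$record_id)],
                  numeric(length(ids0)))
  scores <- vapply(rankings, function(rl) rl$score[match(ids0, rl$record_id)],
                   numeric(length(ids0)))
  if (length(ids0) == 1) {
    ranks <- matrix(ranks, 1); scores <- matrix(scores, 1)
  }

  in_top <- ranks <= top_n
  support <- rowSums(in_top)
  consensus <- support >= 2
  mean_rank <- rowMeans(ranks)

  norm_scores <- apply(scores, 2, function(s) {
    rng <- max(s) - min(s)
    if (rng == 0) rep(0.5, length(s)) else (s - min(s)) / rng
  })
  if (length(ids0) == 1) norm_scores <- matrix(norm_scores, 1)
  best_score <- if (remainder_score == "max_minmax") {
    apply(norm_scores, 1, max)
  } else {
    apply(scores, 1, max)
  }

  cons_idx <- which(consensus)
  cons_ord <- cons_idx[order(-support[cons_idx], mean_rank[cons_idx], ids0[cons_idx])]
  rest_idx <- which(!consensus)
  rest_ord <- rest_idx[order(-best_score[rest_idx], ids0[rest_idx])]
  ord <- c(cons_ord, rest_ord)

  out <- tibble::tibble(
    rank = seq_along(ord),
    record_id = ids0[ord],
    consensus = consensus[ord],
    support = as.integer(support[ord]),
    mean_rank = mean_rank[ord],
    fused_score = best_score[ord]
  )
  per_model <- as.data.frame(ranks[ord, , drop = FALSE])
  tags <- vapply(seq_len(n_models), function(i) {
    attr(rankings[[i]], "model_tag") %||% paste0("model", i)
  }, character(1))
  names(per_model) <- paste0("rank_", tags)
  out <- dplyr::bind_cols(out, tibble::as_tibble(per_model))
  attr(out, "top_n") <- as.integer(top_n)
  attr(out, "model_tags") <- tags
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Plot a consensus ranking
#'
#' Bar chart of fused rank versus per-model support, highlighting the
#' consensus block.
#'
#' @param object A `consensus_ranking`.
#' @param max_rank Truncate the display at this rank (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_ranking
#' @export
autoplot.consensus_ranking <- function(object, max_rank = 50, ...) {
  dat <- dplyr::filter(object, .data$rank <= max_rank)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$support,
                                    fill = .data$consensus)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "grey60")) +
    ggplot2::labs(x = "fused rank", y = "models supporting (top-n)",
                  fill = "consensus") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
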