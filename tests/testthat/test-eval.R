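# Metrics, characterization statistics and ELISpot classification.

test_that("top-N capture counts positives in ranking prefixes", {
  ids <- sprintf("p%02d", 1:30)
  truth <- stats::setNames(rep(c("immunogenic", "non_immunogenic"), c(5, 25)), ids)
  rl <- new_ranked_list(ids, seq(30, 1), "m") # positives ranked first
  rep <- top_n_capture(rl, truth)
  expect_equal(rep$captured[rep$n == 10], 5)

  # brute-force prefix recount on random rankings, plus monotonicity
  set.seed(41)
  for (i in 1:100) {
    scores <- runif(30)
    rl <- new_ranked_list(ids, scores, "m")
    rep <- top_n_capture(rl, truth, n_values = c(5, 10, 20))
    manual <- vapply(c(5, 10, 20), function(n) {
      sum(truth[rl$record_id[1:n]] == "immunogenic")
    }, numeric(1))
    expect_equal(rep$captured, as.integer(manual))
    expect_true(all(diff(rep$captured) >= 0))
  }

  expect_error(top_n_capture(rl, truth[-1]), class = "neorank_coverage_error")
})

test_that("AUC matches the pairwise oracle and known endpoints", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_error(roc_auc(1:5, rep(1, 5)), class = "neorank_metric_error")

  set.seed(43)
  for (rep in 1:50) {
    n <- sample(6:25, 1)
    scores <- sample(1:10, n, replace = TRUE) / 10 # provoke ties
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(roc_auc(scores, y), oracle_auc(scores, y))
  }

  # labels independent of scores: AUC concentrates at 1/2
  set.seed(47)
  scores <- rnorm(10000)
  y <- rbinom(10000, 1, 0.3)
  expect_lt(abs(roc_auc(scores, y) - 0.5), 0.02)

  # invariance under monotone transforms
  set.seed(49)
  s <- rnorm(100); y <- rbinom(100, 1, 0.4)
  expect_equal(roc_auc(s, y), roc_auc(exp(s), y))
})

test_that("AUC agrees with an established implementation", {
  set.seed(51)
  s <- rnorm(200)
  y <- rbinom(200, 1, 0.35)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("identical class distributions give a zero length chi-square", {
  peps <- vapply(rep(c(8, 9, 10, 11), 5), random_peptide, character(1))
  dat <- tibble::tibble(
    mutant_peptide = c(peps, peps),
    label = rep(c("immunogenic", "non_immunogenic"), each = 20)
  )
  ch <- characterize_dataset(dat)
  expect_equal(ch$length_test$statistic, 0)
  expect_equal(ch$length_test$p_value, 1)
  # positional tests also see identical residue tables
  expect_true(all(ch$positional_tests$statistic < 1e-10, na.rm = TRUE))
})

test_that("the 2x2 chi-square matches the closed form", {
  # 2 length levels x 2 classes
  dat <- tibble::tibble(
    mutant_peptide = vapply(c(rep(9, 30), rep(10, 10), rep(9, 20), rep(10, 40)),
                            random_peptide, character(1)),
    label = rep(c("immunogenic", "non_immunogenic"), c(40, 60))
  )
  ch <- characterize_dataset(dat)
  tab <- table(nchar(dat$mutant_peptide), dat$label)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  manual <- sum((tab - expected)^2 / expected)
  expect_equal(ch$length_test$statistic, manual)
  expect_equal(ch$length_test$df, 1)
})

test_that("planted acidic enrichment at P2-P4 is detected across seeds", {
  for (seed in 1:3) {
    dat <- generate_training_set(generator_spec(n_records = 1000, seed = seed))
    ch <- characterize_dataset(dat)
    p <- ch$positional_tests$p_value
    expect_true(all(p[2:4] < 0.05))
  }
})

test_that("residue frequencies are normalized per position and class", {
  dat <- generate_training_set(generator_spec(n_records = 300, seed = 9))
  ch <- characterize_dataset(dat)
  sums <- ch$residue_frequencies |>
    dplyr::group_by(.data$position, .data$label) |>
    dplyr::summarise(s = sum(.data$frequency), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("feature screens report correlations, tests and forest importance", {
  set.seed(53)
  n <- 60
  f1 <- rnorm(n)
  labels <- rep(c("immunogenic", "non_immunogenic"), each = n / 2)
  feats <- cbind(
    signal = c(rnorm(n / 2, 2), rnorm(n / 2, 0)),
    f1 = f1,
    f1_monotone = exp(f1),           # rank-identical copy
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  fs <- feature_stats(feats, labels, n_trees = 200, seed = 2)
  expect_equal(fs$spearman["f1", "f1_monotone"], 1)
  expect_equal(diag(fs$spearman), rep(1, 5), ignore_attr = TRUE)
  expect_true(isSymmetric(fs$spearman))
  expect_equal(fs$importance$feature[1], "signal")
  expect_equal(sum(fs$importance$importance), 1)
  expect_lt(fs$tests$mannwhitney_p[1], 0.01)

  # planted single discriminative feature recovers top importance, 3 seeds
  for (seed in 4:6) {
    withr::with_seed(seed, {
      feats2 <- cbind(planted = c(rnorm(30, 2.5), rnorm(30, 0)),
                      matrix(rnorm(60 * 4), 60, 4,
                             dimnames = list(NULL, paste0("n", 1:4))))
    })
    fs2 <- feature_stats(feats2, labels, n_trees = 200, seed = seed)
    expect_equal(fs2$importance$feature[1], "planted")
  }

  # constant features yield missing, not zero, correlations
  feats3 <- cbind(const = rep(1, n), x = rnorm(n), y = rnorm(n))
  fs3 <- feature_stats(feats3, labels, n_trees = 50, seed = 1)
  expect_true(is.na(fs3$spearman["const", "x"]))
})

test_that("ELISpot thresholds classify boundary counts as specified", {
  dat <- tibble::tibble(
    peptide_id = c("a", "b", "c"),
    rep1 = c(91, 18, 17.9), rep2 = c(91, 18, 17.9),
    background_mean = 10
  )
  res <- classify_elispot(dat, outlier_cut = Inf)
  expect_equal(res$adjusted_count, c(81, 8, 7.9))
  expect_equal(res$response, c("strong", "weak", "negative"))
  # responses partition the peptides
  expect_true(all(table(res$peptide_id) == 1))
})

test_that("ELISpot summary reproduces the positive-rate arithmetic", {
  n_weak <- 24; n_strong <- 5; n_neg <- 21
  dat <- tibble::tibble(
    peptide_id = sprintf("p%02d", 1:50),
    rep1 = c(rep(40, n_weak), rep(150, n_strong), rep(3, n_neg)),
    rep2 = c(rep(40, n_weak), rep(150, n_strong), rep(3, n_neg)),
    background_mean = 5
  )
  s <- elispot_summary(classify_elispot(dat))
  expect_equal(s$positive_rate_pct, 58)
  expect_equal(s$weak_rate_pct, 48)
  expect_equal(s$strong_rate_pct, 10)
})

test_that("replicate outliers are dropped and adjusted counts floored at zero", {
  dat <- tibble::tibble(peptide_id = "a", rep1 = 20, rep2 = 22, rep3 = 21,
                        rep4 = 500, background_mean = 30)
  res <- classify_elispot(dat)
  expect_equal(res$n_replicates_used, 3)
  expect_equal(res$adjusted_count, 0) # mean 21 - background 30, floored
  expect_equal(res$response, "negative")

  dat_bad <- tibble::tibble(peptide_id = "a", rep1 = -3, background_mean = 0)
  expect_error(classify_elispot(dat_bad), class = "neorank_value_error")
})
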