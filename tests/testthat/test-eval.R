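test_that("compute_metrics matches direct arithmetic on hand cases", {
  m <- compute_metrics(confusion_counts(TP = 50, FP = 10, TN = 90, FN = 10))
  expect_equal(m[["SE"]], 50 / 60)
  expect_equal(m[["SP"]], 0.9)
  expect_equal(m[["ACC"]], 0.875)
  expect_equal(m[["MCC"]], (50 * 90 - 10 * 10) / sqrt(60 * 60 * 100 * 100))
  expect_equal(m[["Precision"]], 50 / 60)
  expect_equal(m[["F_measure"]], 2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6))

  sym <- compute_metrics(confusion_counts(TP = 20, FP = 30, TN = 30, FN = 20))
  expect_equal(as.numeric(sym[c("SE", "SP", "ACC", "MCC")]), c(0.5, 0.5, 0.5, 0))

  perfect <- compute_metrics(confusion_counts(TP = 10, FP = 0, TN = 15, FN = 0))
  expect_equal(as.numeric(perfect[c("ACC", "MCC", "F_measure")]), c(1, 1, 1))
})

test_that("compute_metrics flags zero denominators and rejects empty tables", {
  m <- compute_metrics(confusion_counts(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_equal(m[["SE"]], 0)
  expect_true(all(c("SE", "Precision", "MCC") %in% attr(m, "flagged")))
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "all counts")
})

test_that("compute_metrics agrees with the exact oracle on 1000 random tables", {
  withr::with_seed(30, tables <- matrix(sample(0:40, 4000, replace = TRUE), ncol = 4))
  for (i in seq_len(nrow(tables))) {
    tb <- tables[i, ]
    if (sum(tb) == 0) next
    got <- compute_metrics(confusion_counts(tb[1], tb[2], tb[3], tb[4]))
    want <- oracle_metrics(tb[1], tb[2], tb[3], tb[4])
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-14)
  }
})

test_that("roc_curve: analytic limits and Mann-Whitney equivalence", {
  truth <- rep(c(1, 0), each = 10)
  perfect <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  expect_equal(roc_curve(perfect, truth)$auc, 1)
  expect_equal(roc_curve(rep(0.5, 20), truth)$auc, 0.5)
  withr::with_seed(31, {
    scores <- round(runif(50), 2)  # rounded to force ties
    y <- rbinom(50, 1, 0.4)
  })
  r <- roc_curve(scores, y)
  expect_equal(r$auc, oracle_auc(scores, y), tolerance = 1e-12)
  expect_true(all(diff(r$roc$TPR) >= 0))
  expect_true(all(diff(r$roc$FPR) >= 0))
  expect_true(all(r$roc$FPR >= 0 & r$roc$TPR <= 1))
  expect_error(roc_curve(scores, rep(1, 50)), "both classes")
})

test_that("MCC is centred on zero under label permutation", {
  withr::with_seed(32, {
    pred <- rbinom(200, 1, 0.4)
    truth <- rbinom(200, 1, 0.3)
    mccs <- replicate(200, {
      yp <- sample(truth)
      m <- compute_metrics(confusion_counts(
        TP = sum(yp == 1 & pred == 1), FP = sum(yp == 0 & pred == 1),
        TN = sum(yp == 0 & pred == 0), FN = sum(yp == 1 & pred == 0)))
      m[["MCC"]]
    })
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("balance_dataset undersamples the majority class deterministically", {
  withr::with_seed(33, {
    pos <- setNames(replicate(15, rand_seq(50)), paste0("p", 1:15))
    neg <- setNames(replicate(40, rand_seq(50)), paste0("n", 1:40))
  })
  ds <- labeled_dataset(pos, neg)
  b1 <- balance_dataset(ds, seed = 7)
  expect_equal(sum(b1$labels == 1), sum(b1$labels == 0))
  expect_equal(sum(b1$labels == 1), 15)
  b2 <- balance_dataset(ds, seed = 7)
  expect_identical(b1$sequences, b2$sequences)
  bal <- labeled_dataset(pos, setNames(replicate(15, rand_seq(50)), paste0("m", 1:15)))
  expect_setequal(names(balance_dataset(bal, seed = 1)$sequences),
                  names(bal$sequences))
})

test_that("stratified folds preserve the class ratio within one example", {
  y <- c(rep(1L, 33), rep(0L, 77))
  folds <- amyforest:::stratified_folds(y, 10L, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  per_fold_pos <- tapply(y, folds, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  per_fold_n <- tabulate(folds)
  expect_lte(diff(range(per_fold_n)), 2)
})

test_that("stratified_split gives the stated partition sizes", {
  y <- rep(c(1L, 0L), each = 50)
  tr <- stratified_split(y, 0.8, seed = 5)
  expect_equal(sum(tr), 80)
  expect_equal(sum(y[!tr] == 1), 10)
  expect_equal(sum(y[!tr] == 0), 10)
})

small_ds <- function(seed = 40, n_pos = 15, n_neg = 25) {
  generate_dataset(generator_spec(n_pos = n_pos, n_neg = n_neg, len_min = 50,
                                  len_max = 80, enrichment = 5, seed = seed))
}

fast_clf <- function() clf_random_forest(n_trees = 60L)

test_that("kfold_cv pools counts to the dataset size and is seed-reproducible", {
  ds <- small_ds()
  r1 <- kfold_cv(ds, encoder = "188d", classifier = fast_clf(), K = 5L, seed = 2)
  counts <- r1$aggregate$counts
  expect_equal(counts$TP + counts$FP + counts$TN + counts$FN, 40)
  expect_equal(sum(r1$per_fold[, c("TP", "FP", "TN", "FN")]), 40)
  expect_equal(nrow(r1$per_fold), 5)
  r2 <- kfold_cv(ds, encoder = "188d", classifier = fast_clf(), K = 5L, seed = 2)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$aggregate$metrics, r2$aggregate$metrics)
  expect_equal(r1$mean_error, mean(1 - r1$per_fold$ACC))
})

test_that("kfold_cv guards its preconditions", {
  ds <- small_ds()
  expect_error(kfold_cv(ds, K = 1L))
  expect_error(kfold_cv(ds, K = 1000L), "exceeds dataset size")
  tiny <- small_ds(n_pos = 3, n_neg = 20)
  expect_warning(
    kfold_cv(tiny, encoder = "188d", classifier = fast_clf(), K = 5L, seed = 1),
    "fewer than K")
})

test_that("leave-one-out: K = n gives singleton test folds", {
  ds <- small_ds(n_pos = 6, n_neg = 8, seed = 41)
  n <- length(ds$labels)
  suppressWarnings(
    r <- kfold_cv(ds, encoder = "188d", classifier = clf_nearest_neighbors(3L),
                  K = n, seed = 1))
  expect_equal(nrow(r$per_fold), n)
  expect_true(all(rowSums(r$per_fold[, c("TP", "FP", "TN", "FN")]) == 1))
})

test_that("external_split_eval evaluates only the held-out 20%", {
  ds <- small_ds(n_pos = 20, n_neg = 30, seed = 42)
  r <- external_split_eval(ds, encoder = "188d", classifier = fast_clf(),
                           train_fraction = 0.8, seed = 3)
  counts <- r$aggregate$counts
  expect_equal(counts$TP + counts$FP + counts$TN + counts$FN, 4 + 6)
  expect_equal(sum(r$train_index), 16 + 24)
  r2 <- external_split_eval(ds, encoder = "188d", classifier = fast_clf(),
                            train_fraction = 0.8, seed = 3)
  expect_identical(r$aggregate$metrics, r2$aggregate$metrics)
})

test_that("classifier_bench runs paired folds and survives failing rows", {
  ds <- small_ds(seed = 43)
  broken <- list(name = "Broken",
                 fit = function(X, y) stop("boom"),
                 prob = function(m, X) NULL)
  res <- classifier_bench(ds, encoder = "188d",
                          classifiers = list(fast_clf(), fast_clf(),
                                             clf_naive_bayes(), broken),
                          K = 4L, seed = 9)
  expect_equal(nrow(res$table), 4)
  expect_true(res$table$failed[res$table$classifier == "Broken"])
  rf_rows <- res$table[res$table$classifier == "RandomForest", ]
  expect_equal(nrow(rf_rows), 2)  # identical specs -> identical rows
  expect_equal(rf_rows$ACC[1], rf_rows$ACC[2])
  expect_equal(rf_rows$AUC[1], rf_rows$AUC[2])
})

test_that("eval reports serialize to JSON and TSV", {
  ds <- small_ds(seed = 44)
  r <- kfold_cv(ds, encoder = "188d", classifier = fast_clf(), K = 4L, seed = 2)
  dir <- withr::local_tempdir()
  j <- file.path(dir, "report.json")
  write_eval_report(r, j, "json")
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$aggregate$ACC, r$aggregate$metrics[["ACC"]])
  tsv <- file.path(dir, "roc.tsv")
  write_eval_report(r, tsv, "roc_tsv")
  roc <- read.delim(tsv)
  expect_identical(names(roc), c("FPR", "TPR"))
})
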