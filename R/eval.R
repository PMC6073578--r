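# Evaluation protocol: confusion-count metrics (SE, SP, ACC, MCC, Precision,
# Recall, F-measure), ROC/AUC, stratified k-fold cross-validation, 80/20
# external validation, balanced undersampling, and a paired classifier
# benchmark.

#' Confusion counts
#'
#' @param TP,FP,TN,FN nonnegative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_counts")
}

confusion_from_predictions <- function(truth, pred) {
  confusion_counts(TP = sum(truth == 1L & pred == 1L),
                   FP = sum(truth == 0L & pred == 1L),
                   TN = sum(truth == 0L & pred == 0L),
                   FN = sum(truth == 1L & pred == 0L))
}

#' Classification metrics from confusion counts
#'
#' SE = TP/(TP+FN); SP = TN/(TN+FP); ACC = (TP+TN)/total;
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN));
#' Precision = TP/(TP+FP); Recall = SE; F = 2 P R / (P + R).
#' A zero denominator makes the affected metric 0 and is recorded in the
#' `flagged` attribute (this keeps report tables NaN-free; a well-populated
#' two-class evaluation never hits this case).
#'
#' @param counts a [confusion_counts()] (or list with TP/FP/TN/FN).
#' @return Named numeric vector (SE, SP, ACC, MCC, Precision, Recall,
#'   F_measure) with attribute `flagged` naming zero-denominator metrics.
#' @examples
#' compute_metrics(confusion_counts(TP = 50, FP = 10, TN = 90, FN = 10))
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  total <- TP + FP + TN + FN
  if (total == 0) stop("compute_metrics: all counts are zero")
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else num / den
  }
  SE <- safe(TP, TP + FN, "SE")
  SP <- safe(TN, TN + FP, "SP")
  ACC <- (TP + TN) / total
  MCC <- safe(TP * TN - FP * FN,
              sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)), "MCC")
  Precision <- safe(TP, TP + FP, "Precision")
  Recall <- SE
  F_measure <- safe(2 * Precision * Recall, Precision + Recall, "F_measure")
  structure(c(SE = SE, SP = SP, ACC = ACC, MCC = MCC, Precision = Precision,
              Recall = Recall, F_measure = F_measure),
            flagged = flagged)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (each threshold predicts positive
#' at score >= t), yielding a staircase from (0, 0) to (1, 1); AUC by the
#' trapezoidal rule, which equals the normalized Mann-Whitney U statistic
#' with ties counted half.
#'
#' @param scores numeric positive-class scores.
#' @param truth 0/1 labels aligned with `scores`; both classes required.
#' @return List with `roc` (data.frame FPR, TPR) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2L) {
    stop("roc_curve: both classes must be present")
  }
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # cumulative counts at each unique-score threshold
  is_last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(t)[is_last]
  fp <- cumsum(1L - t)[is_last]
  roc <- data.frame(FPR = c(0, fp / nn), TPR = c(0, tp / np))
  auc <- sum(diff(roc$FPR) * (head(roc$TPR, -1) + roc$TPR[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Balance a dataset by undersampling the majority class
#'
#' Randomly (seeded) discards majority-class sequences until both classes
#' have the minority-class size. Already-balanced input is returned unchanged
#' up to ordering.
#'
#' @param dataset a [labeled_dataset()].
#' @param seed integer seed for the selection.
#' @return A balanced [labeled_dataset()].
#' @export
balance_dataset <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  y <- dataset$labels
  if (length(unique(y)) < 2L) stop("balance_dataset: two classes required")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  n_keep <- min(n1, n0)
  keep <- with_local_seed(seed, {
    i1 <- sample(which(y == 1L), n_keep)
    i0 <- sample(which(y == 0L), n_keep)
    sort(c(i1, i0))
  })
  structure(list(sequences = dataset$sequences[keep], labels = y[keep],
                 name = paste0(dataset$name, "_balanced")),
            class = "labeled_dataset")
}

# stratified fold assignment: shuffle within class, deal round-robin with a
# running offset across classes; keeps the class ratio within one example per
# fold and leaves no fold empty while K <= n (so K = n is leave-one-out)
stratified_folds <- function(y, K, seed) {
  folds <- integer(length(y))
  with_local_seed(seed, {
    start <- 0L
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- ((start + seq_along(idx) - 1L) %% K) + 1L
      start <- start + length(idx)
    }
  })
  folds
}

eval_report <- function(per_fold_counts, scores, truth, fold_of = NULL) {
  agg <- confusion_counts(
    TP = sum(vapply(per_fold_counts, `[[`, numeric(1), "TP")),
    FP = sum(vapply(per_fold_counts, `[[`, numeric(1), "FP")),
    TN = sum(vapply(per_fold_counts, `[[`, numeric(1), "TN")),
    FN = sum(vapply(per_fold_counts, `[[`, numeric(1), "FN")))
  per_fold <- do.call(rbind, lapply(seq_along(per_fold_counts), function(i) {
    cc <- per_fold_counts[[i]]
    m <- suppressWarnings(compute_metrics(cc))
    data.frame(fold = i, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               t(as.matrix(m))[1, , drop = FALSE], row.names = NULL)
  }))
  r <- roc_curve(scores, truth)
  structure(list(per_fold = per_fold,
                 aggregate = list(counts = agg, metrics = compute_metrics(agg)),
                 fold_mean = colMeans(per_fold[, c("SE", "SP", "ACC", "MCC",
                                                   "Precision", "Recall",
                                                   "F_measure"), drop = FALSE]),
                 mean_error = mean(1 - per_fold$ACC),
                 roc = r$roc, auc = r$auc,
                 scores = scores, truth = truth, fold_of = fold_of),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$aggregate$metrics
  cat(sprintf(paste0("<eval_report> %d examples, %d fold(s)\n",
                     "  pooled: ACC %.4f  MCC %.4f  SE %.4f  SP %.4f  F %.4f  AUC %.4f\n"),
              length(x$truth), nrow(x$per_fold),
              m["ACC"], m["MCC"], m["SE"], m["SP"], m["F_measure"], x$auc))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into K stratified folds; for each fold, trains on
#' the other K - 1 and evaluates on it. Reports per-fold confusion counts and
#' metrics, metrics on the pooled counts, fold-averaged metrics, the mean
#' cross-validation error E, and the ROC/AUC of the pooled out-of-fold
#' scores. A fixed seed makes the whole report bit-reproducible.
#'
#' @param dataset a [labeled_dataset()].
#' @param encoder encoder name or function (see [make_encoder()]).
#' @param classifier a classifier spec (default [clf_random_forest()]).
#' @param K number of folds (default 10); `K = n` gives leave-one-out.
#' @param seed integer seed driving fold assignment and training.
#' @return An `eval_report`.
#' @export
kfold_cv <- function(dataset, encoder = "188d+pse",
                     classifier = clf_random_forest(), K = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), K >= 2L)
  y <- dataset$labels
  if (K > length(y)) stop("kfold_cv: K exceeds dataset size")
  if (min(table(y)) < K) {
    warning("kfold_cv: a class has fewer than K members; some folds will ",
            "miss it (consider a smaller K)")
  }
  X <- encode_dataset(dataset, encoder)
  folds <- stratified_folds(y, K, seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", K)
  with_local_seed(seed + 1L, {
    for (k in seq_len(K)) {
      tr <- folds != k
      model <- classifier$fit(X[tr, , drop = FALSE], y[tr])
      p <- classifier$prob(model, X[!tr, , drop = FALSE])
      scores[!tr] <- p
      per_fold[[k]] <- confusion_from_predictions(y[!tr], as.integer(p >= 0.5))
    }
  })
  eval_report(per_fold, scores, y, fold_of = folds)
}

#' Stratified train/test split indices
#'
#' @param y 0/1 labels.
#' @param train_fraction fraction per class assigned to training
#'   (`floor(train_fraction * n_class)`).
#' @param seed integer seed.
#' @return Logical vector, TRUE = training example.
#' @export
stratified_split <- function(y, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  tr <- logical(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n_tr <- floor(train_fraction * length(idx))
      tr[idx[seq_len(n_tr)]] <- TRUE
    }
  })
  tr
}

#' External (held-out) validation with a stratified 80/20 split
#'
#' Trains once on the training fraction and evaluates on the held-out
#' remainder; metrics are computed on the held-out examples only. The split
#' indices are returned for reproducibility.
#'
#' @inheritParams kfold_cv
#' @param train_fraction fraction used for model development (default 0.8).
#' @return An `eval_report` with an extra `$train_index` logical vector.
#' @export
external_split_eval <- function(dataset, encoder = "188d+pse",
                                classifier = clf_random_forest(),
                                train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  y <- dataset$labels
  tr <- stratified_split(y, train_fraction, seed)
  if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
    stop("external_split_eval: both classes must appear in both partitions")
  }
  X <- encode_dataset(dataset, encoder)
  report <- with_local_seed(seed + 1L, {
    model <- classifier$fit(X[tr, , drop = FALSE], y[tr])
    p <- classifier$prob(model, X[!tr, , drop = FALSE])
    cc <- confusion_from_predictions(y[!tr], as.integer(p >= 0.5))
    eval_report(list(cc), p, y[!tr])
  })
  report$train_index <- tr
  report
}

#' Benchmark several classifiers over identical folds
#'
#' Runs [kfold_cv()] for each classifier spec with the same seed (hence the
#' same stratified folds: a paired comparison) and tabulates pooled metrics.
#' A classifier that errors is reported as a failed row and the run
#' continues.
#'
#' @inheritParams kfold_cv
#' @param classifiers list of classifier specs.
#' @return List with `table` (one row per classifier: ACC, MCC, SE, SP,
#'   F_measure, AUC, failed) and `reports` (named list of `eval_report`s).
#' @export
classifier_bench <- function(dataset, encoder = "188d+pse", classifiers,
                             K = 10L, seed = 1L) {
  X_cache <- encode_dataset(dataset, encoder)  # encode once, shared by all rows
  rows <- list()
  reports <- list()
  for (spec in classifiers) {
    res <- tryCatch(
      kfold_cv(dataset, encoder = X_cache, classifier = spec,
               K = K, seed = seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(classifier = spec$name, ACC = NA,
                                              MCC = NA, SE = NA, SP = NA,
                                              F_measure = NA, AUC = NA,
                                              failed = TRUE)
    } else {
      m <- res$aggregate$metrics
      rows[[length(rows) + 1L]] <- data.frame(classifier = spec$name,
                                              ACC = m[["ACC"]], MCC = m[["MCC"]],
                                              SE = m[["SE"]], SP = m[["SP"]],
                                              F_measure = m[["F_measure"]],
                                              AUC = res$auc, failed = FALSE)
      reports[[length(reports) + 1L]] <- res
      names(reports)[length(reports)] <- spec$name
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}

#' Serialize an evaluation report
#'
#' Writes the pooled metrics + per-fold table as JSON, or per-fold metrics /
#' ROC points as TSV.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @param what one of `"json"` (full report), `"metrics_tsv"` (per-fold
#'   table), `"roc_tsv"` (ROC points).
#' @export
write_eval_report <- function(report, path, what = c("json", "metrics_tsv", "roc_tsv")) {
  what <- match.arg(what)
  if (what == "json") {
    out <- list(aggregate = c(as.list(report$aggregate$counts)[c("TP", "FP", "TN", "FN")],
                              as.list(report$aggregate$metrics)),
                fold_mean = as.list(report$fold_mean),
                mean_error = report$mean_error,
                auc = report$auc,
                per_fold = report$per_fold)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else if (what == "metrics_tsv") {
    write.table(report$per_fold, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write.table(report$roc, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
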