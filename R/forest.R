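# Random-forest classifier and pluggable comparison classifiers. The forest
# follows the standard recipe: draw n bootstrap samples, grow a CART tree
# choosing each split from k of the q features, repeat for m trees, predict
# by majority vote (the vote fraction doubles as the class-probability score).

#' Train a random forest
#'
#' @param X numeric feature matrix (rows = examples).
#' @param y integer/numeric labels in \{0, 1\}; both classes must be present.
#' @param n_trees number of trees m (default 500).
#' @param mtry features sampled per split k (default `floor(sqrt(ncol(X)))`).
#' @param sample_size bootstrap sample size n (default `nrow(X)`).
#' @param min_node minimum node size to attempt a split from (default 1:
#'   grow to purity).
#' @param bootstrap draw bootstrap samples (default TRUE); FALSE trains every
#'   tree on the full sample (used for the single decision tree).
#' @param seed optional integer; when given, training is wrapped in a local
#'   RNG scope so results are bit-reproducible without touching the caller's
#'   RNG state. When NULL the current RNG stream is used (so an outer
#'   `set.seed()` also makes training deterministic).
#' @return Object of class `rf_model` with `$trees`, `$mtry`, `$n_trees`,
#'   `$feature_names`.
#' @export
rf_train <- function(X, y, n_trees = 500L, mtry = NULL, sample_size = NULL,
                     min_node = 1L, bootstrap = TRUE, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)), n_trees >= 1L)
  if (length(unique(y)) < 2L) {
    stop("rf_train: both classes must be present in y")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- min(as.integer(mtry), ncol(X))
  if (is.null(sample_size)) sample_size <- nrow(X)
  run <- function() {
    rf_train_cpp(X, y, as.integer(n_trees), mtry, as.integer(sample_size),
                 as.integer(min_node), isTRUE(bootstrap))
  }
  trees <- if (is.null(seed)) run() else with_local_seed(seed, run())
  structure(list(trees = trees, mtry = mtry, n_trees = n_trees,
                 feature_names = colnames(X)),
            class = "rf_model")
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Predict with a random forest
#'
#' @param object an `rf_model`.
#' @param newdata numeric matrix with the training columns.
#' @param type `"prob"` for the positive-class vote fraction, `"class"` for
#'   the majority-vote label (threshold 0.5).
#' @param ... unused.
#' @export
predict.rf_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  p <- rf_predict_cpp(object$trees, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry = %d, %d features\n",
              x$n_trees, x$mtry, length(x$feature_names)))
  invisible(x)
}

# ---- pluggable comparison classifiers -------------------------------------
# A classifier spec is list(name, fit(X, y) -> model, prob(model, X) -> score)
# so the benchmarking harness can run any of them over identical folds.

#' Classifier specification constructors
#'
#' Each returns a spec usable by [kfold_cv()], [external_split_eval()] and
#' [classifier_bench()]: a list with `name`, `fit(X, y)` and
#' `prob(model, X)` (positive-class score). Available:
#' `clf_random_forest()` (the package forest), `clf_decision_tree()` (a single
#' unbagged CART grown on all features), `clf_naive_bayes()` (Gaussian),
#' `clf_nearest_neighbors()` (k-NN on Euclidean distance, vote fraction
#' score) and `clf_logistic()` (ridge-regularized logistic regression via
#' glmnet).
#'
#' @param n_trees,mtry,sample_size,min_node forwarded to [rf_train()].
#' @return A classifier spec list.
#' @export
clf_random_forest <- function(n_trees = 500L, mtry = NULL, sample_size = NULL,
                              min_node = 1L) {
  list(name = "RandomForest",
       fit = function(X, y) rf_train(X, y, n_trees = n_trees, mtry = mtry,
                                     sample_size = sample_size, min_node = min_node),
       prob = function(model, X) predict(model, X, type = "prob"))
}

#' @rdname clf_random_forest
#' @export
clf_decision_tree <- function(min_node = 1L) {
  list(name = "DecisionTree",
       fit = function(X, y) rf_train(X, y, n_trees = 1L, mtry = ncol(X),
                                     bootstrap = FALSE, min_node = min_node),
       prob = function(model, X) predict(model, X, type = "prob"))
}

#' @rdname clf_random_forest
#' @export
clf_naive_bayes <- function() {
  eps <- 1e-9
  list(
    name = "NaiveBayes",
    fit = function(X, y) {
      X <- as.matrix(X)
      fit_class <- function(cl) {
        Xc <- X[y == cl, , drop = FALSE]
        list(mu = colMeans(Xc),
             var = apply(Xc, 2L, function(v) max(stats::var(v), eps)),
             prior = nrow(Xc) / nrow(X))
      }
      list(c0 = fit_class(0L), c1 = fit_class(1L))
    },
    prob = function(model, X) {
      X <- as.matrix(X)
      loglik <- function(cl) {
        ll <- rep(log(cl$prior), nrow(X))
        for (j in seq_len(ncol(X))) {
          ll <- ll + stats::dnorm(X[, j], cl$mu[j], sqrt(cl$var[j]), log = TRUE)
        }
        ll
      }
      l0 <- loglik(model$c0)
      l1 <- loglik(model$c1)
      1 / (1 + exp(pmin(700, pmax(-700, l0 - l1))))
    })
}

#' @rdname clf_random_forest
#' @param k number of neighbors (default 5).
#' @export
clf_nearest_neighbors <- function(k = 5L) {
  list(
    name = "NearestNeighbors",
    fit = function(X, y) list(X = as.matrix(X), y = as.integer(y), k = k),
    prob = function(model, X) {
      X <- as.matrix(X)
      tr <- model$X
      tr_sq <- rowSums(tr^2)
      apply(X, 1L, function(row) {
        d2 <- tr_sq - 2 * drop(tr %*% row) + sum(row^2)
        nb <- order(d2)[seq_len(min(model$k, length(d2)))]
        mean(model$y[nb])
      })
    })
}

#' @rdname clf_random_forest
#' @param lambda ridge penalty (default 1e-3).
#' @export
clf_logistic <- function(lambda = 1e-3) {
  list(
    name = "LogisticRegression",
    fit = function(X, y) {
      glmnet::glmnet(as.matrix(X), as.factor(y), family = "binomial",
                     alpha = 0, lambda = lambda)
    },
    prob = function(model, X) {
      drop(predict(model, as.matrix(X), type = "response"))
    })
}

#' Save / load a trained model
#'
#' Serializes a trained classifier together with the encoder name that
#' produced its features, under a versioned wrapper so stale files are
#' rejected on load.
#'
#' @param model a trained model (e.g. `rf_model`).
#' @param path file path (RDS).
#' @param encoder encoder name recorded for prediction-time encoding.
#' @export
save_model <- function(model, path, encoder = "188d+pse") {
  saveRDS(list(format = "amyforest-model", version = 1L,
               encoder = encoder, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: list with `$model` and `$encoder`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "amyforest-model")) {
    stop("load_model: '", path, "' is not a saved model")
  }
  if (!identical(obj$version, 1L)) {
    stop("load_model: unsupported model version ", obj$version)
  }
  obj[c("model", "encoder")]
}
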