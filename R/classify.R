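#' Build a binary miRNA-presence feature matrix
#'
#' Rows are documents (positive corpus first, then negative), columns are
#' normalized miRNA core names, and a cell is 1 iff the core is in that
#' document's deduplicated miRNA set — so mention multiplicity within a
#' document never inflates a feature. Documents without any mention keep an
#' all-zero row.
#'
#' @param tagged_pos,tagged_neg tagged corpora ([tag_corpus()]); the
#'   positive corpus receives label 1.
#' @param vocabulary optional fixed set of core names; defaults to the
#'   sorted union of cores observed in the two corpora.
#' @return list of class `feature_matrix` with `x` (0/1 matrix), `labels`
#'   (integer vector) and `pmid`.
#' @export
build_feature_matrix <- function(tagged_pos, tagged_neg, vocabulary = NULL) {
  sets <- c(tagged_pos$mirna_set, tagged_neg$mirna_set)
  if (is.null(vocabulary)) vocabulary <- sort(unique(unlist(sets)))
  if (length(vocabulary) == 0) stop("empty feature vocabulary")
  x <- matrix(vapply(sets, function(s) as.integer(vocabulary %in% s),
                     integer(length(vocabulary))),
              ncol = length(vocabulary), byrow = TRUE,
              dimnames = list(NULL, vocabulary))
  labels <- c(rep(1L, nrow(tagged_pos)), rep(0L, nrow(tagged_neg)))
  n_empty <- sum(rowSums(x) == 0)
  if (n_empty > 0)
    message(n_empty, " document(s) with no miRNA mention kept as all-zero rows")
  structure(list(x = x, labels = labels,
                 pmid = c(tagged_pos$pmid, tagged_neg$pmid)),
            class = "feature_matrix")
}

#' Balance two corpora by down-sampling the larger class
#'
#' The larger corpus is down-sampled uniformly without replacement to the
#' size of the smaller, so the pair holds an equal number of documents per
#' class. Deterministic for a given seed.
#'
#' @param pos,neg corpora (either may be the larger).
#' @param seed RNG seed.
#' @return list with elements `pos` and `neg` of equal row count.
#' @export
balance_classes <- function(pos, neg, seed = 1) {
  if (nrow(pos) == 0 || nrow(neg) == 0) stop("both classes must be non-empty")
  n <- min(nrow(pos), nrow(neg))
  set.seed(seed)
  if (nrow(pos) > n) pos <- pos[sort(sample.int(nrow(pos), n)), , drop = FALSE]
  if (nrow(neg) > n) neg <- neg[sort(sample.int(nrow(neg), n)), , drop = FALSE]
  list(pos = as_mirlit_corpus(pos), neg = as_mirlit_corpus(neg))
}

#' Holdout split configuration
#'
#' @param test_fraction fraction of rows held out for testing (default 0.3).
#' @param seed RNG seed.
#' @param stratified preserve class proportions in the split (default TRUE).
#' @return list of class `split_config`.
#' @export
split_config <- function(test_fraction = 0.3, seed = 1, stratified = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_config")
}

#' Single train/test holdout split
#'
#' Under stratification the test fraction is rounded within each class, so
#' a balanced input yields a balanced test set (within 1 per class). Train
#' and test are disjoint and their union is the full matrix.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param config a [split_config()].
#' @return list with `train` and `test` feature matrices and the integer
#'   `test_idx`.
#' @export
holdout_split <- function(fm, config = split_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "split_config"))
  n <- nrow(fm$x)
  set.seed(config$seed)
  if (config$stratified) {
    test_idx <- integer()
    for (cl in sort(unique(fm$labels))) {
      idx <- which(fm$labels == cl)
      if (length(idx) < 2) stop("need >= 2 rows per class for stratification")
      k <- round(config$test_fraction * length(idx))
      test_idx <- c(test_idx, sample(idx, k))
    }
    test_idx <- sort(test_idx)
  } else {
    test_idx <- sort(sample.int(n, round(config$test_fraction * n)))
  }
  subset_fm <- function(idx) {
    structure(list(x = fm$x[idx, , drop = FALSE], labels = fm$labels[idx],
                   pmid = fm$pmid[idx]), class = "feature_matrix")
  }
  list(train = subset_fm(setdiff(seq_len(n), test_idx)),
       test = subset_fm(test_idx), test_idx = test_idx)
}

#' Classifier configuration
#'
#' Four model families are supported: `"NB"` (categorical naive Bayes on
#' the binary features, Laplace smoothing 1), `"DT"` (CART decision tree,
#' grown without minimum-split restrictions as is usual for this kind of
#' sparse binary feature space),
#' `"RF"` (random forest, 500 trees), and `"SVM"` (support vector machine;
#' defaults `cost = 10`, `gamma = "scale"` i.e. 1 / (n_features * var(x)),
#' `kernel = "sigmoid"`).
#'
#' @param model one of "NB", "DT", "RF", "SVM".
#' @param seed RNG seed used when fitting.
#' @param ... hyperparameter overrides (`cost`, `gamma`, `kernel` for SVM;
#'   `ntree` for RF; passed through otherwise).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(model = c("SVM", "NB", "DT", "RF"), seed = 1, ...) {
  model <- match.arg(toupper(model[1]), c("SVM", "NB", "DT", "RF"))
  hp <- list(...)
  if (model == "SVM") {
    hp$cost <- hp$cost %||% 10
    hp$gamma <- hp$gamma %||% "scale"
    hp$kernel <- hp$kernel %||% "sigmoid"
  }
  if (model == "RF") hp$ntree <- hp$ntree %||% 500
  structure(list(model = model, seed = as.integer(seed), hyperparameters = hp),
            class = "classifier_config")
}

gamma_scale <- function(x) {
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v == 0) 1 / ncol(x) else 1 / (ncol(x) * v)
}

#' Fit one classifier
#'
#' @param config a [classifier_config()].
#' @param train a training `feature_matrix` (both classes present).
#' @return a fitted model object of class `mirlit_model`.
#' @export
fit_model <- function(config, train) {
  stopifnot(inherits(config, "classifier_config"),
            inherits(train, "feature_matrix"))
  if (length(unique(train$labels)) < 2) stop("training data has a single class")
  y <- factor(train$labels, levels = c(0, 1))
  set.seed(config$seed)
  hp <- config$hyperparameters
  fit <- switch(config$model,
    NB = e1071::naiveBayes(x = binary_factor_frame(train$x), y = y, laplace = 1),
    DT = rpart::rpart(label ~ ., method = "class",
                      data = data.frame(label = y, train$x, check.names = FALSE),
                      control = rpart::rpart.control(minsplit = 2,
                                                     minbucket = 1, cp = 0)),
    RF = randomForest::randomForest(x = data.frame(train$x, check.names = FALSE),
                                    y = y, ntree = hp$ntree),
    SVM = {
      g <- if (identical(hp$gamma, "scale")) gamma_scale(train$x) else hp$gamma
      e1071::svm(x = train$x, y = y, kernel = hp$kernel, cost = hp$cost,
                 gamma = g, scale = FALSE)
    })
  structure(list(model = config$model, fit = fit, config = config,
                 features = colnames(train$x)),
            class = "mirlit_model")
}

binary_factor_frame <- function(x) {
  df <- as.data.frame(lapply(as.data.frame(x, check.names = FALSE),
                             factor, levels = c(0, 1)),
                      check.names = FALSE)
  df
}

#' Predict labels and decision scores
#'
#' Scores are oriented so that higher means more positive (class 1): the
#' class-1 posterior probability for NB/DT/RF and the oriented decision
#' value for the SVM.
#'
#' @param object a fitted `mirlit_model`.
#' @param x a 0/1 feature matrix with the training columns.
#' @return list with `labels` (0/1 integer) and `scores` (numeric).
#' @export
predict_model <- function(object, x) {
  stopifnot(inherits(object, "mirlit_model"))
  x <- x[, object$features, drop = FALSE]
  scores <- switch(object$model,
    NB = stats::predict(object$fit, binary_factor_frame(x), type = "raw")[, "1"],
    DT = stats::predict(object$fit,
                        data.frame(x, check.names = FALSE), type = "prob")[, "1"],
    RF = stats::predict(object$fit,
                        data.frame(x, check.names = FALSE), type = "prob")[, "1"],
    SVM = {
      pr <- stats::predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the margin toward class "1"
      if (grepl("^1/", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
    })
  labels <- if (object$model == "SVM") {
    pr <- stats::predict(object$fit, x)
    as.integer(as.character(pr))
  } else {
    as.integer(scores > 0.5)
  }
  list(labels = labels, scores = as.numeric(scores))
}

#' Fit a classifier and predict on held-out data
#'
#' @param config a [classifier_config()].
#' @param train,test feature matrices.
#' @return list with `labels`, `scores` (on `test`) and the fitted `model`.
#' @export
fit_predict <- function(config, train, test) {
  model <- fit_model(config, train)
  pred <- predict_model(model, test$x)
  c(pred, list(model = model))
}

#' Evaluate a classifier with the full metric panel
#'
#' @param config a [classifier_config()].
#' @param train,test feature matrices.
#' @return list with `metrics` (accuracy, recall, precision, mcc, f_score,
#'   auc), `confusion`, `roc` and the fitted `model`.
#' @export
evaluate_model <- function(config, train, test) {
  pred <- fit_predict(config, train, test)
  cm <- confusion_matrix(test$labels, pred$labels)
  metrics <- metrics_from_confusion(cm)
  ra <- roc_auc(test$labels, pred$scores)
  metrics$auc <- ra$auc
  list(metrics = metrics, confusion = cm, roc = ra$roc, model = pred$model)
}

#' Permutation feature importance
#'
#' The importance of a feature is the mean drop in held-out accuracy when
#' that feature's column is randomly permuted, over `n_repeats` draws.
#' Constant columns get importance 0 by construction on average;
#' deterministic for a given seed.
#'
#' @param model a fitted `mirlit_model`.
#' @param test a `feature_matrix` to evaluate on.
#' @param n_repeats permutations per feature (default 20).
#' @param seed RNG seed.
#' @return tibble with columns `feature` and `importance`, sorted by
#'   descending importance (ties lexicographic).
#' @export
permutation_importance <- function(model, test, n_repeats = 20, seed = 1) {
  stopifnot(n_repeats >= 1)
  baseline <- mean(predict_model(model, test$x)$labels == test$labels)
  set.seed(seed)
  n <- nrow(test$x)
  imp <- vapply(model$features, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- test$x
      xp[, f] <- xp[sample.int(n), f]
      baseline - mean(predict_model(model, xp)$labels == test$labels)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- tibble::tibble(feature = model$features, importance = unname(imp))
  out[order(-out$importance, out$feature), ]
}

#' Most frequently mentioned miRNAs
#'
#' Ranks core names by the number of documents mentioning them (each core
#' counted at most once per document).
#'
#' @param tagged_corp a tagged corpus.
#' @param k number of cores to return (truncated to the number observed).
#' @return tibble with columns `core` and `n_docs`, descending counts with
#'   lexicographic tie-break.
#' @export
top_k_mirnas <- function(tagged_corp, k = 20) {
  stopifnot(k >= 1)
  tab <- table(unlist(tagged_corp$mirna_set))
  if (length(tab) == 0) return(tibble::tibble(core = character(), n_docs = integer()))
  out <- tibble::tibble(core = names(tab), n_docs = as.integer(tab))
  out <- out[order(-out$n_docs, out$core), ]
  utils::head(out, k)
}
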