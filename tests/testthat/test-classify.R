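make_tagged <- function(sets, label, base = 0) {
  corp <- corpus(pmid = as.character(base + seq_along(sets)),
                 title = "t", label = label)
  corp$mentions <- rep(list(NULL), length(sets))
  corp$mirna_set <- sets
  corp
}

test_that("feature matrix is binary presence over the core vocabulary", {
  pos <- make_tagged(list(c("miR-21"), c("miR-21", "miR-146"), character()),
                     "case")
  neg <- make_tagged(list(c("miR-146")), "control", base = 100)
  expect_message(fm <- build_feature_matrix(pos, neg), "all-zero")
  expect_equal(colnames(fm$x), c("miR-146", "miR-21"))
  expect_equal(fm$x[1, ], c("miR-146" = 0L, "miR-21" = 1L))
  expect_equal(fm$labels, c(1L, 1L, 1L, 0L))
  expect_true(all(fm$x %in% 0:1))
  # a fixed vocabulary restricts the columns
  fm2 <- suppressMessages(build_feature_matrix(pos, neg, vocabulary = "miR-21"))
  expect_equal(colnames(fm2$x), "miR-21")
  expect_error(build_feature_matrix(make_tagged(list(character()), "case"),
                                    make_tagged(list(character()), "control"),
                                    vocabulary = character()),
               "empty")
})

test_that("class balancing downsamples the larger corpus deterministically", {
  g <- generate_corpus(synth_config(n_docs = 30, seed = 12))
  pos <- g$corpus[g$corpus$label == "case", ][1:10, ]
  neg <- g$corpus[g$corpus$label == "control", ]
  bal <- balance_classes(pos, neg, seed = 5)
  expect_equal(nrow(bal$pos), 10)
  expect_equal(nrow(bal$neg), 10)
  bal2 <- balance_classes(pos, neg, seed = 5)
  expect_identical(bal$neg$pmid, bal2$neg$pmid)
  # equal sizes pass through unchanged
  bal3 <- balance_classes(pos, neg[1:10, ], seed = 5)
  expect_identical(bal3$neg$pmid, neg$pmid[1:10])
  expect_error(balance_classes(pos[0, ], neg), "non-empty")
})

test_that("holdout split is stratified, disjoint and seed-deterministic", {
  pos <- make_tagged(rep(list("miR-1"), 50), "case")
  neg <- make_tagged(rep(list("miR-2"), 50), "control", base = 100)
  fm <- build_feature_matrix(pos, neg)
  sp <- holdout_split(fm, split_config(0.3, seed = 2))
  expect_equal(nrow(sp$test$x), 30)
  expect_equal(nrow(sp$train$x), 70)
  expect_equal(sum(sp$test$labels == 1), 15)
  expect_length(intersect(sp$train$pmid, sp$test$pmid), 0)
  sp2 <- holdout_split(fm, split_config(0.3, seed = 2))
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(holdout_split(build_feature_matrix(pos[1, ], neg),
                             split_config(0.3)), "2 rows per class")
})

test_that("all four models separate a perfectly separable toy problem", {
  sets <- c(rep(list("miR-1"), 10), rep(list("miR-2"), 10))
  pos <- make_tagged(sets[1:10], "case")
  neg <- make_tagged(sets[11:20], "control", base = 100)
  fm <- build_feature_matrix(pos, neg)
  sp <- holdout_split(fm, split_config(0.3, seed = 1))
  for (m in c("NB", "DT", "RF", "SVM")) {
    ev <- evaluate_model(classifier_config(m, seed = 1), sp$train, sp$test)
    expect_equal(ev$metrics$accuracy, 1, info = m)
    expect_equal(ev$metrics$auc, 1, info = m)
  }
  expect_error(fit_model(classifier_config("SVM"),
                         structure(list(x = fm$x[1:5, ], labels = rep(1L, 5),
                                        pmid = as.character(1:5)),
                                   class = "feature_matrix")),
               "single class")
})

test_that("SVM defaults follow the reported hyperparameters", {
  cfg <- classifier_config("SVM")
  expect_equal(cfg$hyperparameters$cost, 10)
  expect_equal(cfg$hyperparameters$gamma, "scale")
  expect_equal(cfg$hyperparameters$kernel, "sigmoid")
})

test_that("confusion-matrix metrics match hand-computed values", {
  m <- metrics_from_confusion(confusion_matrix(c(1, 0), c(1, 0)))
  expect_equal(m$accuracy, 1); expect_equal(m$mcc, 1); expect_equal(m$f_score, 1)

  cm <- structure(list(tp = 30, fp = 10, fn = 20, tn = 40),
                  class = "confusion_matrix")
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_score, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$mcc, 1000 / sqrt(40 * 50 * 50 * 60))

  # zero denominators flag metrics undefined rather than zero
  none_pos <- metrics_from_confusion(confusion_matrix(c(0, 0), c(0, 0)))
  expect_true(is.na(none_pos$recall))
  expect_true(is.na(none_pos$precision))
  expect_equal(none_pos$accuracy, 1)
})

test_that("metrics agree with a brute-force recount on random instances", {
  set.seed(100)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    pred <- sample(0:1, n, replace = TRUE)
    m <- metrics_from_confusion(confusion_matrix(labels, pred))
    expect_equal(m$accuracy, mean(labels == pred))
    if (any(pred == 1))
      expect_equal(m$precision, sum(labels == 1 & pred == 1) / sum(pred == 1))
    expect_equal(m$recall, sum(labels == 1 & pred == 1) / sum(labels == 1))
  }
})

test_that("AUC equals the pairwise concordance probability", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 0), c(1, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  # Mann-Whitney oracle on random instances, including ties
  set.seed(7)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    u <- 0
    for (p in which(labels == 1)) for (q in which(labels == 0)) {
      u <- u + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
    }
    expect_equal(roc_auc(labels, scores)$auc,
                 u / (sum(labels == 1) * sum(labels == 0)))
  }
})

test_that("ROC curve starts at the origin and ends at (1, 1)", {
  set.seed(3)
  roc <- roc_auc(sample(0:1, 40, replace = TRUE), stats::runif(40))$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("permutation importance isolates the signal feature", {
  set.seed(20)
  n <- 60
  labels <- rep(c(1L, 0L), n / 2)
  x <- cbind(signal = labels, noise = sample(0:1, n, replace = TRUE),
             constant = 1L)
  fm <- structure(list(x = x, labels = labels, pmid = as.character(1:n)),
                  class = "feature_matrix")
  sp <- holdout_split(fm, split_config(0.3, seed = 2))
  model <- fit_model(classifier_config("RF", seed = 2), sp$train)
  imp <- permutation_importance(model, sp$test, n_repeats = 10, seed = 9)
  expect_equal(imp$feature[1], "signal")
  expect_true(imp$importance[1] > max(imp$importance[-1]))
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  imp2 <- permutation_importance(model, sp$test, n_repeats = 10, seed = 9)
  expect_identical(imp, imp2)
})

test_that("top miRNAs rank by per-document counts with dedup", {
  tagged <- make_tagged(list(c("miR-21"), c("miR-21", "miR-1"), "miR-1",
                             "miR-21"), "case")
  top <- top_k_mirnas(tagged, 10)
  expect_equal(top$core, c("miR-21", "miR-1"))
  expect_equal(top$n_docs, c(3L, 2L))
  expect_equal(nrow(top_k_mirnas(tagged, 1)), 1)
})
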