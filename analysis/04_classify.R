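#!/usr/bin/env Rscript
# Balanced case/control classification from binary miRNA-presence features:
# pair the classes, hold out 30% stratified, train NB/DT/RF/SVM (SVM with
# C = 10, gamma = "scale", sigmoid kernel), and report the full metric
# panel, ROC points and SVM permutation feature importance.

library(mirlit)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results"

corp <- read_pubtator(file.path(out, "synth", "corpus.pubtator"))
labels <- read.delim(file.path(out, "synth", "truth", "labels.tsv"),
                     colClasses = "character")
corp$label <- labels$label[match(corp$pmid, labels$pmid)]
bal <- balance_classes(corp[corp$label == "case", ],
                       corp[corp$label == "control", ], seed = seed)
fm <- build_feature_matrix(tag_corpus(bal$pos), tag_corpus(bal$neg))
sp <- holdout_split(fm, split_config(0.3, seed = seed))

metrics <- NULL
roc_pts <- NULL
for (m in c("NB", "DT", "RF", "SVM")) {
  ev <- evaluate_model(classifier_config(m, seed = seed), sp$train, sp$test)
  metrics <- rbind(metrics, data.frame(
    model = m, predictor = "miRNAs",
    accuracy = round(ev$metrics$accuracy, 4),
    recall = round(ev$metrics$recall, 4),
    precision = round(ev$metrics$precision, 4),
    mcc = round(ev$metrics$mcc, 4),
    f_score = round(ev$metrics$f_score, 4),
    auc = round(ev$metrics$auc, 4)))
  roc_pts <- rbind(roc_pts, cbind(model = m, ev$roc))
  if (m == "SVM") svm_model <- ev$model
}
write.table(metrics, file.path(out, "model_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(roc_pts, file.path(out, "roc_points.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(metrics, row.names = FALSE)

imp <- permutation_importance(svm_model, sp$test, n_repeats = 20, seed = seed)
write.table(imp, file.path(out, "svm_importance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top features by SVM permutation importance:\n")
print(head(imp, 10), n = 10)
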