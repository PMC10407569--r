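#!/usr/bin/env Rscript
# Fit the LDA topic model on the case-class abstracts, assign each study
# its dominant topic, and derive topic-year and miRNA-topic association
# matrices. K defaults to 3 here because the simulated corpus plants 3
# topics; pass a different K as the second argument for a sweep.

library(mirlit)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
k <- if (length(args) >= 2) as.integer(args[2]) else 3L
out <- "results"

corp <- read_pubtator(file.path(out, "synth", "corpus.pubtator"))
med <- rbind(read_medline(file.path(out, "synth", "case.medline")),
             read_medline(file.path(out, "synth", "control.medline")))
corp$pub_date <- med$pub_date[match(corp$pmid, med$pmid)]
labels <- read.delim(file.path(out, "synth", "truth", "labels.tsv"),
                     colClasses = "character")
case <- corp[labels$label[match(corp$pmid, labels$pmid)] == "case", ]

fit <- fit_lda(corpus_tokens(case), lda_config(n_topics = k, seed = seed))
tagged <- tag_corpus(case)

write.table(data.frame(pmid = case$pmid, round(fit$theta, 4)),
            file.path(out, "theta.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
tops <- top_terms(fit, 5)
cat("top terms per topic:\n")
for (t in seq_along(tops))
  cat(sprintf("  topic %d: %s\n", t, paste(tops[[t]], collapse = ", ")))

tym <- topic_year_matrix(fit, case)
write.table(cbind(topic = rownames(tym), as.data.frame(tym)),
            file.path(out, "topic_year.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

mtm <- mirna_topic_matrix(fit, tagged)
write.table(cbind(mirna = rownames(mtm), as.data.frame(mtm)),
            file.path(out, "mirna_topic.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
dom <- dominant_topic(fit)
cat("documents per dominant topic:",
    paste(table(factor(dom, levels = seq_len(k))), collapse = " / "), "\n")
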