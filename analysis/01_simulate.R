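#!/usr/bin/env Rscript
# Generate the synthetic two-class miRNA literature corpus the rest of the
# workflow analyses: 500 case and 500 control documents, 3 planted topics,
# 5 class-signal miRNAs (mention probability 0.6 in cases vs 0.1 in
# controls), 15 background miRNAs, and co-mentioned gene symbols for the
# network stage. Writes standard MEDLINE and PubTator files so the
# downstream steps consume the corpus through the same readers as real data.

library(mirlit)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/synth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(
  n_docs = 500, seed = seed,
  plant_genes = tibble::tibble(
    symbol = c("IRAK1", "TRAF6", "IL6", "TNF", "NUMB", "EGFR", "TGFB1", "STX3"),
    p = c(0.35, 0.30, 0.25, 0.25, 0.15, 0.15, 0.15, 0.10)))
g <- generate_corpus(cfg)

write_medline(g$corpus[g$corpus$label == "case", ],
              file.path(out, "case.medline"))
write_medline(g$corpus[g$corpus$label == "control", ],
              file.path(out, "control.medline"))
write_pubtator(g$corpus, file.path(out, "corpus.pubtator"))
ground_truth_report(g$truth, file.path(out, "truth"))

cat(sprintf("generated %d documents (%d case / %d control), %d planted mentions\n",
            nrow(g$corpus), sum(g$corpus$label == "case"),
            sum(g$corpus$label == "control"), nrow(g$truth$mentions)))
cat("wrote MEDLINE, PubTator and ground-truth tables under", out, "\n")
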