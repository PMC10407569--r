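#!/usr/bin/env Rscript
# For the most important miRNA from the classification stage, build the
# gene co-mention presence matrix from the PubTator annotations, intersect
# the co-mentioned genes with the bundled synthetic predicted-target list,
# and test pathway over-representation against the bundled synthetic GMT.

library(mirlit)
out <- "results"

corp <- read_pubtator(file.path(out, "synth", "corpus.pubtator"))
tagged <- tag_corpus(corp)
imp <- read.delim(file.path(out, "svm_importance.tsv"))
core <- imp$feature[1]
cat("focus miRNA (highest SVM importance):", core, "\n")

gpm <- gene_presence_matrix(tagged, core, min_docs = 2)
write.table(cbind(gene = rownames(gpm), as.data.frame(gpm)),
            file.path(out, "gene_presence.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(nrow(gpm), "genes co-mentioned in >= 2", core, "studies:",
    paste(rownames(gpm), collapse = ", "), "\n")

targets <- read_target_list(
  system.file("extdata", "synthetic_mir146_targets.tsv", package = "mirlit"),
  family = "miR-146")
hits <- intersect_target_list(rownames(gpm), targets)
cat("co-mentioned genes that are predicted miR-146 targets:",
    if (length(hits)) paste(hits, collapse = ", ") else "(none)", "\n")

gmt <- read_gmt(system.file("extdata", "synthetic_pathways.gmt",
                            package = "mirlit"))
ora <- ora_hypergeometric(rownames(gpm), gmt)
write.table(ora, file.path(out, "pathway_ora.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("pathways at p < 0.05:\n")
print(as.data.frame(ora[ora$p_value < 0.05,
                        c("set", "size", "overlap", "p_value", "adjusted_p")]),
      row.names = FALSE)
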