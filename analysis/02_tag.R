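#!/usr/bin/env Rscript
# Read the corpus back through the MEDLINE/PubTator readers, filter by
# publication type, tag miRNA mentions with the nomenclature regex, and
# report yearly counts, term frequencies and the most-studied miRNAs.

library(mirlit)
out <- "results"
corp <- read_pubtator(file.path(out, "synth", "corpus.pubtator"))
labels <- read.delim(file.path(out, "synth", "truth", "labels.tsv"),
                     colClasses = "character")
corp$label <- labels$label[match(corp$pmid, labels$pmid)]
# PubTator files carry no publication types; take them from the MEDLINE side
med <- rbind(read_medline(file.path(out, "synth", "case.medline")),
             read_medline(file.path(out, "synth", "control.medline")))
corp$pub_types <- med$pub_types[match(corp$pmid, med$pmid)]
corp$pub_date <- med$pub_date[match(corp$pmid, med$pmid)]
corp <- filter_publication_types(corp)
cat(nrow(corp), "documents retained after publication-type filtering\n")

tagged <- tag_corpus(corp)
men <- do.call(rbind, lapply(seq_len(nrow(tagged)), function(i) {
  m <- tagged$mentions[[i]]
  if (nrow(m) == 0) return(NULL)
  cbind(pmid = tagged$pmid[i], m)
}))
write.table(men, file.path(out, "mentions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

yc <- yearly_counts(corp)
write.table(yc, file.path(out, "yearly_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (cls in c("case", "control")) {
  tf <- term_frequency_table(corp[corp$label == cls, ])
  write.table(head(tf, 50), file.path(out, paste0("terms_", cls, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("top terms (%s): %s\n", cls,
              paste(head(tf$token, 5), collapse = ", ")))
}

top <- top_k_mirnas(tagged[tagged$label == "case", ], 20)
write.table(top, file.path(out, "top_mirnas_case.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("most-studied case-class miRNAs:",
    paste(head(top$core, 5), collapse = ", "), "\n")
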