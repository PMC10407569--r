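test_that("MEDLINE records round-trip through write and read", {
  corp <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".txt")
  write_medline(corp, path)
  back <- read_medline(path)
  expect_equal(back$pmid, corp$pmid)
  expect_equal(back$title, corp$title)
  expect_equal(back$abstract, corp$abstract)
  expect_equal(back$pub_types, corp$pub_types)
})

test_that("MEDLINE reader handles fixtures, continuations and bad records", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PMID- 1", "TI  - T", "AB  - A", "DP  - 2020",
               "PT  - Journal Article", ""), path)
  corp <- read_medline(path)
  expect_equal(nrow(corp), 1)
  expect_equal(corp$title, "T")
  expect_equal(corp$abstract, "A")
  expect_equal(corp$pub_date, "2020")
  expect_equal(corp$pub_types[[1]], "Journal Article")

  # continuation lines joined with single spaces
  writeLines(c("PMID- 1", "TI  - A long", "      title here", ""), path)
  expect_equal(read_medline(path)$title, "A long title here")

  # empty file -> empty corpus
  writeLines(character(), path)
  expect_equal(nrow(read_medline(path)), 0)

  # duplicate PMID -> second dropped with warning
  writeLines(c("PMID- 1", "TI  - first", "", "PMID- 1", "TI  - second", ""), path)
  expect_warning(corp <- read_medline(path), "duplicate")
  expect_equal(corp$title, "first")

  # record without PMID skipped with warning
  writeLines(c("TI  - orphan", "", "PMID- 2", "TI  - kept", ""), path)
  expect_warning(corp <- read_medline(path), "without PMID")
  expect_equal(corp$pmid, "2")

  expect_error(read_medline("no/such/file.txt"), "cannot read")
})

test_that("PubTator reader parses text, annotations and validates spans", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1|t|miR-21 in kidney",
               "1\t0\t6\tmiR-21\tGene\tx", ""), path)
  corp <- read_pubtator(path)
  expect_equal(nrow(corp), 1)
  expect_equal(corp$abstract, "")
  ann <- corp$annotations[[1]]
  expect_equal(nrow(ann), 1)
  expect_equal(ann$surface, "miR-21")
  expect_equal(ann$entity_type, "gene")

  # surface not equal to text slice -> annotation dropped, document kept
  writeLines(c("1|t|miR-21 in kidney",
               "1\t0\t6\tWRONG\tGene\tx", ""), path)
  expect_warning(corp <- read_pubtator(path), "mismatch")
  expect_equal(nrow(corp), 1)
  expect_equal(nrow(corp$annotations[[1]]), 0)

  # malformed annotation line -> error carrying the line number
  writeLines(c("1|t|title", "1\tnotanumber\t3\tx\tGene"), path)
  expect_error(read_pubtator(path), "line 2")

  # round-trip with abstract through write_pubtator
  g <- generate_corpus(synth_config(
    n_docs = 3, seed = 4,
    plant_genes = tibble::tibble(symbol = c("IRAK1", "TRAF6"), p = 1)))
  write_pubtator(g$corpus, path)
  back <- read_pubtator(path)
  expect_equal(back$pmid, g$corpus$pmid)
  expect_equal(back$abstract, g$corpus$abstract)
  expect_equal(nrow(back$annotations[[1]]), nrow(g$corpus$annotations[[1]]))
})

test_that("publication-type filter applies include and exclude lists", {
  corp <- corpus(pmid = as.character(1:4),
                 title = "t",
                 pub_types = list("Journal Article",
                                  c("Journal Article", "Review"),
                                  character(),
                                  c("journal article", "LETTER")))
  kept <- filter_publication_types(corp)
  # review excluded, empty set has no include match, matching case-insensitive
  expect_equal(kept$pmid, c("1", "4"))
  expect_true(all(c("Clinical Trail", "Clinical Trial") %in% default_include_types()))
})

test_that("publication-type filter is idempotent and commutes with concatenation", {
  g <- generate_corpus(synth_config(n_docs = 10, seed = 2))
  corp <- g$corpus
  corp$pub_types <- rep(list("Journal Article", c("Journal Article", "Review"),
                             "Editorial", "Preprint"), length.out = nrow(corp))
  once <- filter_publication_types(corp)
  expect_identical(filter_publication_types(once), once)
  a <- corp[1:8, ]; b <- corp[9:20, ]
  expect_equal(rbind(filter_publication_types(a), filter_publication_types(b))$pmid,
               filter_publication_types(rbind(a, b))$pmid)
})

test_that("yearly counts conserve documents and bucket unparseable dates", {
  corp <- corpus(pmid = as.character(1:3), title = "t",
                 pub_date = c("2019 Jan", "2019", "2020"))
  yc <- yearly_counts(corp)
  expect_equal(yc$n[yc$year == "2019"], 2L)
  expect_equal(yc$n[yc$year == "2020"], 1L)
  expect_equal(sum(yc$n), nrow(corp))

  expect_equal(nrow(yearly_counts(corpus(character(), character()))), 0)

  corp2 <- corpus(pmid = "1", title = "t", pub_date = "n.d.")
  expect_message(yc2 <- yearly_counts(corp2), "unknown")
  expect_equal(yc2$year, "unknown")
  expect_equal(yc2$n, 1L)
})

test_that("term frequency lowercases, drops stopwords and sorts", {
  corp <- corpus(pmid = "1", title = "t", abstract = "miRNA miRNA expression")
  tf <- term_frequency_table(corp)
  expect_equal(tf$token, c("mirna", "expression"))
  expect_equal(tf$n, c(2L, 1L))

  only_stop <- corpus(pmid = "1", title = "t", abstract = "the of and")
  expect_equal(nrow(term_frequency_table(only_stop)), 0)
})

test_that("planted class term dominates case-class term frequencies", {
  g <- generate_corpus(synth_config(n_docs = 60, seed = 9))
  tf <- term_frequency_table(g$corpus[g$corpus$label == "case", ])
  expect_true("diabetes" %in% utils::head(tf$token, 5))
  tf_ctrl <- term_frequency_table(g$corpus[g$corpus$label == "control", ])
  expect_false("diabetes" %in% tf_ctrl$token)
})
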