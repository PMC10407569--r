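annotated_doc <- function(pmid, mirnas, genes) {
  toks <- c(mirnas, genes)
  abstract <- paste(toks, collapse = " ")
  title <- "study"
  starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_along(toks)] + nchar(title) + 1L
  ann <- tibble::tibble(start = starts, end = starts + nchar(toks),
                        surface = toks, entity_type = "gene", concept_id = "")
  corpus(pmid = pmid, title = title, abstract = abstract,
         annotations = list(ann))
}

test_that("gene presence matrix thresholds genes and excludes miRNA rows", {
  corp <- rbind(
    annotated_doc("1", "miR-146", c("IRAK1", "TRAF6")),
    annotated_doc("2", "miR-146a", c("IRAK1", "IL6")),
    annotated_doc("3", "miR-21", c("IRAK1", "TRAF6")))
  tagged <- tag_corpus(corp)
  m <- gene_presence_matrix(tagged, "miR-146", min_docs = 2)
  expect_equal(rownames(m), "IRAK1")           # IL6/TRAF6 below threshold
  expect_equal(unname(m["IRAK1", ]), c(1L, 1L))
  expect_equal(colnames(m), c("1", "2"))
  m1 <- gene_presence_matrix(tagged, "miR-146", min_docs = 1)
  expect_false(any(grepl("^MIR", rownames(m1)))) # the miRNA is never a gene row
  expect_true(all(c("IL6", "TRAF6") %in% rownames(m1)))
  expect_error(gene_presence_matrix(tagged, "miR-999"), "no documents")
})

test_that("target intersection is case-insensitive and order-free", {
  targets <- structure(list(family = "miR-146",
                            targets = c("IRAK1", "TRAF6")),
                       class = "target_list")
  expect_equal(intersect_target_list(c("irak1", "IL6"), targets), "IRAK1")
  expect_equal(intersect_target_list(c("IL6", "TNF"), targets), character())
  expect_equal(intersect_target_list(c("TRAF6", "IRAK1"), targets),
               intersect_target_list(c("IRAK1", "TRAF6"), targets))
  expect_warning(out <- intersect_target_list("IRAK1", character()), "empty")
  expect_equal(out, character())
})

test_that("bundled synthetic target list reproduces the four-hit intersection", {
  path <- system.file("extdata", "synthetic_mir146_targets.tsv",
                      package = "mirlit")
  targets <- read_target_list(path, family = "miR-146")
  rows <- c("IRAK1", "TRAF6", "IL6", "TNF", "NUMB", "EGFR", "TGFB1", "STX3")
  hits <- intersect_target_list(rows, targets)
  expect_equal(hits, c("IRAK1", "NUMB", "STX3", "TRAF6"))
  expect_length(hits, 4)
})

test_that("GMT reader parses sets and rejects short lines", {
  path <- system.file("extdata", "synthetic_pathways.gmt", package = "mirlit")
  gmt <- read_gmt(path)
  expect_true("Toll-like receptor signaling" %in% names(gmt))
  expect_true(all(c("IRAK1", "TRAF6") %in% gmt[["Toll-like receptor signaling"]]))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("name_only\tdesc", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("hypergeometric ORA matches exact enumeration", {
  universe <- paste0("G", 1:20)
  collection <- list(setA = universe[1:5])
  query <- c(universe[1:3], universe[10])   # overlap 3 of query 4
  res <- ora_hypergeometric(query, collection, universe)
  expect_equal(res$p_value, 0.03199, tolerance = 1e-4)
  expect_equal(res$p_value, enum_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(res$overlap, 3)
  expect_equal(res$genes, "G1,G2,G3")

  # zero overlap: p near 1, never above
  res0 <- ora_hypergeometric(universe[11:12], list(s = universe[1:2]), universe)
  expect_true(res0$p_value <= 1 && res0$p_value > 0.9)

  # certainty case: query = set = universe
  res1 <- ora_hypergeometric(universe, list(s = universe), universe)
  expect_equal(res1$p_value, 1)
  expect_error(ora_hypergeometric(character(), collection, universe), "empty query")
  expect_error(ora_hypergeometric("G1", collection, character()), "empty universe")
})

test_that("ORA agrees with a Monte-Carlo resampling oracle", {
  set.seed(11)
  universe <- paste0("G", 1:40)
  for (i in 1:5) {
    set_size <- sample(5:15, 1)
    q_size <- sample(4:12, 1)
    gene_set <- sample(universe, set_size)
    query <- sample(universe, q_size)
    res <- ora_hypergeometric(query, list(s = gene_set), universe)
    set_idx <- which(universe %in% gene_set)
    draws <- replicate(100000, sum(sample.int(40, q_size) %in% set_idx))
    p_mc <- mean(draws >= res$overlap)
    se <- sqrt(p_mc * (1 - p_mc) / 100000)
    expect_lt(abs(res$p_value - p_mc), 3 * se + 1e-6)
  }
})

test_that("BH adjustment preserves p-value order and dominates raw p", {
  set.seed(13)
  universe <- paste0("G", 1:50)
  collection <- lapply(1:8, function(i) sample(universe, sample(5:20, 1)))
  names(collection) <- paste0("set", 1:8)
  res <- ora_hypergeometric(sample(universe, 10), collection, universe)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  expect_true(all(diff(res$p_value) >= 0))        # sorted ascending
  expect_true(all(diff(res$adjusted_p) >= -1e-12))  # monotone in that order
  expect_identical(res$adjusted_p,
                   stats::p.adjust(res$p_value, method = "BH"))
})
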