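#' Gene co-mention presence matrix for one miRNA
#'
#' Restricts a tagged, annotated corpus to documents whose miRNA set
#' contains the chosen core, then builds a binary gene x document presence
#' matrix from the PubTator-style gene annotations. Annotation surfaces are
#' uppercased to gene symbols; surfaces that are themselves miRNA names are
#' excluded, and genes mentioned in fewer than `min_docs` documents are
#' dropped.
#'
#' @param tagged_corp corpus with `mirna_set` and `annotations` columns.
#' @param core a normalized miRNA core name, e.g. `"miR-146"`.
#' @param min_docs minimum documents a gene must appear in (default 2).
#' @return 0/1 matrix, gene symbols (rows) x document pmids (columns).
#' @export
gene_presence_matrix <- function(tagged_corp, core, min_docs = 2) {
  keep <- vapply(tagged_corp$mirna_set, function(s) core %in% s, logical(1))
  if (!any(keep)) stop("no documents mention ", core)
  sub <- tagged_corp[keep, , drop = FALSE]
  genes_per_doc <- lapply(sub$annotations, function(a) {
    if (is.null(a) || nrow(a) == 0) return(character())
    g <- a$surface[a$entity_type == "gene"]
    g <- g[regexpr(mirna_regex(include_lin4 = TRUE), g, perl = TRUE) < 0]
    unique(toupper(g))
  })
  genes <- sort(unique(unlist(genes_per_doc)))
  m <- matrix(0L, length(genes), nrow(sub),
              dimnames = list(gene = genes, pmid = sub$pmid))
  for (j in seq_along(genes_per_doc)) m[genes_per_doc[[j]], j] <- 1L
  m[rowSums(m) >= min_docs, , drop = FALSE]
}

#' Read a TargetScan-style target list
#'
#' Minimal tab-separated dialect with at least a miRNA-family column and a
#' target-gene-symbol column; a header row is auto-detected (a first line
#' mentioning "family", "gene", "target" or "symbol").
#'
#' @param path path to the TSV file.
#' @param family optional family name to filter on (matched after
#'   normalizing case).
#' @return list of class `target_list` with `family` and `targets`
#'   (uppercase, deduplicated gene symbols).
#' @export
read_target_list <- function(path, family = NULL) {
  first <- readLines(path, n = 1, warn = FALSE)
  has_header <- grepl("family|gene|target|symbol", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("target list needs at least two columns")
  fam <- as.character(tab[[1]])
  sym <- toupper(as.character(tab[[2]]))
  if (!is.null(family)) {
    keep <- tolower(fam) == tolower(family)
    fam <- fam[keep]; sym <- sym[keep]
  }
  structure(list(family = if (is.null(family)) unique(fam) else family,
                 targets = sort(unique(sym))),
            class = "target_list")
}

#' Intersect co-mentioned genes with a predicted-target list
#'
#' Case-insensitive set intersection between gene symbols (e.g. the rows of
#' a [gene_presence_matrix()]) and a target list; the result is the set of
#' co-mentioned genes that are predicted targets.
#'
#' @param genes character vector of gene symbols.
#' @param targets a `target_list` (or plain character vector).
#' @return sorted uppercase character vector of hits.
#' @export
intersect_target_list <- function(genes, targets) {
  if (inherits(targets, "target_list")) targets <- targets$targets
  if (length(targets) == 0) {
    warning("empty target list", call. = FALSE)
    return(character())
  }
  sort(intersect(unique(toupper(genes)), unique(toupper(targets))))
}

#' Read a GMT gene-set collection
#'
#' @param path path to a tab-separated GMT file (name, description,
#'   genes...).
#' @return named list of uppercase gene-symbol vectors; descriptions in
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the overlap with the query is larger
#' than expected when drawing `|query|` genes from the universe: the
#' p-value is the upper-tail hypergeometric probability P(X >= overlap).
#' Sets are intersected with the universe before testing, the query is
#' restricted to the universe, and p-values are Benjamini-Hochberg
#' adjusted across the collection.
#'
#' @param query character vector of gene symbols.
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe background gene set; defaults to the union of the
#'   collection's genes.
#' @return tibble of class `enrichment_result` with columns `set`, `size`,
#'   `overlap`, `genes` (comma-joined overlap symbols), `p_value`,
#'   `adjusted_p`, sorted by ascending p-value.
#' @export
ora_hypergeometric <- function(query, collection, universe = NULL) {
  if (is.null(universe)) universe <- unique(toupper(unlist(collection)))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- intersect(unique(toupper(query)), universe)
  if (length(query) == 0) stop("empty query after restriction to universe")
  N <- length(universe); k <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(toupper(collection[[nm]])), universe)
    ov <- intersect(query, s)
    p <- stats::phyper(length(ov) - 1, length(s), N - length(s), k,
                       lower.tail = FALSE)
    tibble::tibble(set = nm, size = length(s), overlap = length(ov),
                   genes = paste(sort(ov), collapse = ","),
                   p_value = min(p, 1))
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), ]
  class(out) <- c("enrichment_result", class(out))
  out
}
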