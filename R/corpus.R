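#' Construct a literature corpus
#'
#' A corpus is a tibble with one row per literature record and columns
#' `pmid` (character, unique), `title`, `abstract` (possibly empty string),
#' `pub_date` (free-text date or year), `pub_types` (list of character
#' vectors) and `annotations` (list of tibbles with columns `start`, `end`,
#' `surface`, `entity_type`, `concept_id`; 0-based half-open offsets into
#' `title + " " + abstract`). An optional `label` column carries a class tag
#' per document (e.g. "case"/"control").
#'
#' @param pmid character vector of PubMed identifiers (nonempty, unique).
#' @param title,abstract character vectors; missing abstracts become `""`.
#' @param pub_date character vector of dates or years (may be `NA`).
#' @param pub_types list of character vectors (publication types per record).
#' @param annotations list of annotation tibbles (or `NULL` entries).
#' @param label optional character vector of class tags.
#' @return a tibble of class `mirlit_corpus`.
#' @export
corpus <- function(pmid, title, abstract = "", pub_date = NA_character_,
                   pub_types = list(character()), annotations = list(NULL),
                   label = NULL) {
  n <- length(pmid)
  pmid <- as.character(pmid)
  if (n == 0) {
    out <- tibble::tibble(pmid = character(), title = character(),
                          abstract = character(), pub_date = character(),
                          pub_types = list(), annotations = list())
    class(out) <- c("mirlit_corpus", class(out))
    return(out)
  }
  stopifnot(all(nzchar(pmid)))
  if (anyDuplicated(pmid)) stop("duplicate pmid in corpus")
  abstract <- rep_len(ifelse(is.na(abstract), "", abstract), n)
  out <- tibble::tibble(
    pmid = pmid,
    title = rep_len(as.character(title), n),
    abstract = as.character(abstract),
    pub_date = rep_len(as.character(pub_date), n),
    pub_types = rep_len(pub_types, n),
    annotations = rep_len(annotations, n)
  )
  if (!is.null(label)) out$label <- rep_len(as.character(label), n)
  ok <- validate_annotations(out)
  out$annotations <- ok
  class(out) <- c("mirlit_corpus", class(out))
  out
}

as_mirlit_corpus <- function(x) {
  if (!inherits(x, "mirlit_corpus")) class(x) <- c("mirlit_corpus", class(x))
  x
}

#' Concatenated searchable text of a document
#'
#' Title and abstract joined with a single space; an empty abstract yields
#' the title alone. Annotation spans index into this string.
#'
#' @param title,abstract character vectors.
#' @return character vector.
#' @export
doc_text <- function(title, abstract = "") {
  abstract <- ifelse(is.na(abstract), "", abstract)
  ifelse(nzchar(abstract), paste(title, abstract), title)
}

# Drop annotations whose surface does not equal the text slice at the span.
validate_annotations <- function(corp) {
  lapply(seq_len(nrow(corp)), function(i) {
    ann <- corp$annotations[[i]]
    if (is.null(ann) || nrow(ann) == 0) return(ann)
    txt <- doc_text(corp$title[i], corp$abstract[i])
    slice <- substr(rep(txt, nrow(ann)), ann$start + 1L, ann$end)
    bad <- ann$start < 0 | ann$end > nchar(txt) | ann$start >= ann$end |
      slice != ann$surface
    if (any(bad)) {
      warning(sprintf("pmid %s: dropped %d annotation(s) with span/text mismatch",
                      corp$pmid[i], sum(bad)), call. = FALSE)
      ann <- ann[!bad, , drop = FALSE]
    }
    ann
  })
}

empty_annotations <- function() {
  tibble::tibble(start = integer(), end = integer(), surface = character(),
                 entity_type = character(), concept_id = character())
}

#' Tokenized text per document
#'
#' Tokenizes a chosen text field of every document (see [tokenize()]).
#'
#' @param corp a corpus.
#' @param fields one of "abstract", "title", "title_abstract".
#' @return list of character vectors, one per document.
#' @export
corpus_tokens <- function(corp, fields = c("abstract", "title", "title_abstract")) {
  fields <- match.arg(fields)
  txt <- switch(fields,
    abstract = corp$abstract,
    title = corp$title,
    title_abstract = doc_text(corp$title, corp$abstract)
  )
  lapply(txt, tokenize)
}
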