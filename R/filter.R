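#' Default publication-type inclusion list
#'
#' The inclusion list used for corpus filtering. PubMed's controlled
#' "Clinical Trial" value is accepted alongside the common misspelling
#' "Clinical Trail", which appears in study-type listings in the wild.
#'
#' @return character vector.
#' @export
default_include_types <- function() {
  c("Case Reports", "Clinical Study", "Clinical Trail", "Clinical Trial",
    "Comparative Study", "English Abstract", "Evaluation Study",
    "Journal Article", "Letter", "Preprint")
}

#' Default publication-type exclusion list
#' @return character vector.
#' @export
default_exclude_types <- function() {
  c("Retraction of Publication", "Published Erratum", "Editorial", "News",
    "Dataset", "Clinical trial protocol", "Review", "Systematic review")
}

#' Filter a corpus by publication type
#'
#' A document is retained iff at least one of its publication types is in
#' `include` and none is in `exclude`. Matching is case-insensitive exact
#' string comparison (PubMed publication types are a controlled vocabulary).
#' The operation is idempotent and commutes with corpus concatenation.
#'
#' @param corp a corpus.
#' @param include,exclude character vectors of publication types.
#' @return the filtered corpus.
#' @export
filter_publication_types <- function(corp,
                                     include = default_include_types(),
                                     exclude = default_exclude_types()) {
  inc <- tolower(include)
  exc <- tolower(exclude)
  keep <- vapply(corp$pub_types, function(pt) {
    pt <- tolower(pt)
    any(pt %in% inc) && !any(pt %in% exc)
  }, logical(1))
  as_mirlit_corpus(corp[keep, , drop = FALSE])
}

#' Document counts per publication year
#'
#' Extracts a 4-digit year from each document's publication date; documents
#' with no parseable year are counted under `"unknown"`.
#'
#' @param corp a corpus.
#' @return tibble with columns `year` (character) and `n`, sorted by year
#'   with any `"unknown"` bucket last.
#' @export
yearly_counts <- function(corp) {
  if (nrow(corp) == 0) return(tibble::tibble(year = character(), n = integer()))
  yr <- extract_year(corp$pub_date)
  if (anyNA(yr)) {
    message(sum(is.na(yr)), " document(s) without parseable year counted as 'unknown'")
    yr[is.na(yr)] <- "unknown"
  }
  tab <- table(yr)
  out <- tibble::tibble(year = names(tab), n = as.integer(tab))
  known <- out$year != "unknown"
  rbind(out[known, ][order(out$year[known]), ], out[!known, ])
}

extract_year <- function(pub_date) {
  m <- regmatches(pub_date, regexpr("\\b(1[89]|20)\\d{2}\\b", pub_date))
  out <- rep(NA_character_, length(pub_date))
  out[regexpr("\\b(1[89]|20)\\d{2}\\b", pub_date) > 0] <- m
  out
}

#' Corpus-wide term frequency table
#'
#' Tokenizes the chosen field of every document (hyphen-preserving, see
#' [tokenize()]), lowercases, removes stopwords, and counts tokens over the
#' whole corpus.
#'
#' @param corp a corpus.
#' @param stopwords character vector of stopwords (lowercase).
#' @param fields which text field(s) to count (default `"abstract"`).
#' @return tibble with columns `token`, `n`, sorted by descending count
#'   (ties lexicographic).
#' @export
term_frequency_table <- function(corp, stopwords = mirlit_stopwords(),
                                 fields = c("abstract", "title", "title_abstract")) {
  toks <- tolower(unlist(corpus_tokens(corp, match.arg(fields))))
  toks <- toks[!toks %in% stopwords]
  if (length(toks) == 0) return(tibble::tibble(token = character(), n = integer()))
  tab <- table(toks)
  out <- tibble::tibble(token = names(tab), n = as.integer(tab))
  out[order(-out$n, out$token), ]
}

#' Default English stopword list
#'
#' A compact list of high-frequency English function words (snowball-style)
#' used for term-frequency reporting and LDA vocabulary construction.
#'
#' @return character vector of lowercase stopwords.
#' @export
mirlit_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "also", "am",
    "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "had", "has", "have", "having", "he", "her",
    "here", "hers", "him", "his", "how", "however", "i", "if", "in", "into",
    "is", "it", "its", "itself", "may", "me", "might", "more", "most", "my",
    "no", "nor", "not", "of", "off", "on", "once", "only", "or", "other",
    "our", "ours", "out", "over", "own", "same", "she", "should", "so",
    "some", "such", "than", "that", "the", "their", "theirs", "them",
    "themselves", "then", "there", "these", "they", "this", "those",
    "through", "to", "too", "under", "until", "up", "very", "was", "we",
    "were", "what", "when", "where", "which", "while", "who", "whom", "why",
    "will", "with", "within", "would", "you", "your", "yours")
}
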