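# miRNA recognition pattern. The permissive branch admits any prefix
# degeneration of miR/miRNA/micro-RNA/microRNA followed by a number with
# optional letter, genomic-copy (-1..-5) and arm (-3p/-5p) suffixes; the
# second branch covers let-N. Matching is case-insensitive by construction.
MIRNA_PATTERN <- paste0(
  "[Mm][Ii][Cc]?[Rr][Oo]?[Rr]?[Nn]?[Aa]?-?\\d+[a-zA-Z]?-?[12345]?-?[35]?[Pp]?",
  "|[Ll][Ee][Tt]-?\\d+[a-zA-Z]?-?[35]?[Pp]?")

# Strict variant: full miR / miRNA / microRNA / micro-RNA / let prefixes only.
MIRNA_PATTERN_STRICT <- paste0(
  "(?:[Mm][Ii][Cc][Rr][Oo]-?[Rr][Nn][Aa]|[Mm][Ii][Rr][Nn][Aa]|[Mm][Ii][Rr])",
  "-?\\d+[a-zA-Z]?-?[12345]?-?[35]?[Pp]?",
  "|[Ll][Ee][Tt]-?\\d+[a-zA-Z]?-?[35]?[Pp]?")

LIN4_PATTERN <- "[Ll][Ii][Nn]-?4"

mirna_regex <- function(strict = FALSE, include_lin4 = FALSE) {
  p <- if (strict) MIRNA_PATTERN_STRICT else MIRNA_PATTERN
  if (include_lin4) p <- paste0(p, "|", LIN4_PATTERN)
  p
}

#' Hyphen-preserving tokenizer
#'
#' Splits text on whitespace and punctuation while preserving internal
#' hyphens, so nomenclature tokens such as `miR-146a-5p` or compound words
#' such as `wound-healing` survive as single tokens. Case is preserved.
#'
#' @param text a character scalar.
#' @return character vector of tokens (empty for empty text).
#' @export
tokenize <- function(text) {
  token_spans(text)$token
}

# Tokens with 0-based half-open character spans.
token_spans <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(token = substring(text, m, m + len - 1L),
                 start = as.integer(m - 1L),
                 end = as.integer(m - 1L + len))
}

#' Find miRNA mentions in text
#'
#' Applies the recognition pattern tokenwise after hyphen-preserving
#' tokenization (so a species prefix such as `hsa-` does not block the match
#' inside `hsa-miR-21`), taking the leftmost-longest match within each
#' token, and maps match offsets back to the full text.
#'
#' @param text a character scalar.
#' @param strict require a full `miR`/`miRNA`/`microRNA`/`let` prefix
#'   instead of the permissive default pattern.
#' @param include_lin4 also recognize the historical name `lin-4`.
#' @return tibble with columns `surface`, `start`, `end` (0-based half-open
#'   offsets into `text`) and `core` (normalized name).
#' @export
find_mirna_mentions <- function(text, strict = FALSE, include_lin4 = FALSE) {
  ts <- token_spans(text)
  empty <- tibble::tibble(surface = character(), start = integer(),
                          end = integer(), core = character())
  if (nrow(ts) == 0) return(empty)
  pat <- mirna_regex(strict, include_lin4)
  m <- regexpr(pat, ts$token, perl = TRUE)
  hit <- m > 0
  if (!any(hit)) return(empty)
  off <- as.integer(m[hit] - 1L)
  len <- attr(m, "match.length")[hit]
  surface <- substring(ts$token[hit], m[hit], m[hit] + len - 1L)
  tibble::tibble(
    surface = surface,
    start = ts$start[hit] + off,
    end = ts$start[hit] + off + as.integer(len),
    core = vapply(surface, normalize_core, "", USE.NAMES = FALSE)
  )
}

#' Normalize a miRNA surface form to its core name
#'
#' Reduces any recognized surface form to `prefix-number`: the prefix is
#' `miR` for all miR/miRNA/microRNA/micro-RNA variants and `let` for let
#' variants (output casing fixed); the number is the first digit run.
#' Species prefixes (`hsa-`), letter suffixes (`a`, `b`), genomic-copy
#' suffixes (`-1`..`-5`) and arm suffixes (`-3p`/`-5p`) are all dropped.
#' Idempotent on its own outputs.
#'
#' @param surface a recognized miRNA surface form.
#' @return the core name, e.g. `"miR-146"` or `"let-7"`.
#' @export
normalize_core <- function(surface) {
  m <- regexpr(mirna_regex(strict = FALSE, include_lin4 = TRUE), surface,
               perl = TRUE)
  if (m < 0) stop("not a recognizable miRNA surface form: ", surface)
  hit <- substring(surface, m, m + attr(m, "match.length") - 1L)
  head2 <- tolower(substr(hit, 1, 2))
  prefix <- if (head2 == "le") "let" else if (head2 == "li") "lin" else "miR"
  num <- regmatches(hit, regexpr("\\d+", hit))
  paste0(prefix, "-", num)
}

#' Tag a document with its miRNA mentions
#'
#' Runs [find_mirna_mentions()] over `title + " " + abstract` and derives
#' the per-document deduplicated set of core names (each miRNA is counted at
#' most once per document).
#'
#' @param title,abstract the document's text fields.
#' @inheritParams find_mirna_mentions
#' @return list with elements `mentions` (tibble, ordered by span) and
#'   `mirna_set` (sorted character vector of unique cores).
#' @export
tag_document <- function(title, abstract = "", strict = FALSE,
                         include_lin4 = FALSE) {
  mentions <- find_mirna_mentions(doc_text(title, abstract), strict, include_lin4)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  list(mentions = mentions, mirna_set = sort(unique(mentions$core)))
}

#' Tag every document of a corpus
#'
#' @param corp a corpus.
#' @param fields which text fields to tag: the full `title + " " + abstract`
#'   concatenation (default) or the title only.
#' @inheritParams find_mirna_mentions
#' @return the corpus with added list-columns `mentions` and `mirna_set`.
#' @export
tag_corpus <- function(corp, fields = c("title_abstract", "title"),
                       strict = FALSE, include_lin4 = FALSE) {
  fields <- match.arg(fields)
  tags <- lapply(seq_len(nrow(corp)), function(i) {
    if (fields == "title") tag_document(corp$title[i], "", strict, include_lin4)
    else tag_document(corp$title[i], corp$abstract[i], strict, include_lin4)
  })
  corp$mentions <- lapply(tags, `[[`, "mentions")
  corp$mirna_set <- lapply(tags, `[[`, "mirna_set")
  as_mirlit_corpus(corp)
}

#' QC report: regex mentions without gene-annotation support
#'
#' For a document carrying PubTator-style entity annotations, reports the
#' regex mentions whose span overlaps no gene-type annotation. This is a
#' quality-control report only; nothing is filtered.
#'
#' @param mentions a mention tibble from [tag_document()].
#' @param annotations the document's annotation tibble (may be `NULL`).
#' @return the subset of `mentions` lacking gene-annotation overlap, with an
#'   added `flag` column (`"no-annotation"` when the document carries no
#'   annotations at all, otherwise `"unsupported"`).
#' @export
validate_against_gene_annotations <- function(mentions, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    mentions$flag <- rep("no-annotation", nrow(mentions))
    return(mentions)
  }
  gene <- annotations[annotations$entity_type == "gene", , drop = FALSE]
  unsupported <- vapply(seq_len(nrow(mentions)), function(i) {
    !any(mentions$start[i] < gene$end & gene$start < mentions$end[i])
  }, logical(1))
  out <- mentions[unsupported, , drop = FALSE]
  out$flag <- rep("unsupported", nrow(out))
  out
}
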