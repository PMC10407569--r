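#' Topic model configuration
#'
#' @param n_topics number of topics K (>= 2; default 13).
#' @param doc_topic_prior symmetric Dirichlet prior on document-topic
#'   weights (alpha; default 0.1).
#' @param topic_word_prior symmetric Dirichlet prior on topic-word weights
#'   (beta; default 0.01).
#' @param max_iterations Gibbs sweeps over the corpus (default 200).
#' @param min_df minimum number of documents a term must appear in to enter
#'   the vocabulary (default 2).
#' @param seed RNG seed; identical seed + input gives identical results.
#' @return list of class `lda_config`.
#' @export
lda_config <- function(n_topics = 13, doc_topic_prior = 0.1,
                       topic_word_prior = 0.01, max_iterations = 200,
                       min_df = 2, seed = 1) {
  stopifnot(n_topics >= 2, doc_topic_prior > 0, topic_word_prior > 0,
            max_iterations >= 1, min_df >= 1)
  structure(list(n_topics = as.integer(n_topics),
                 doc_topic_prior = doc_topic_prior,
                 topic_word_prior = topic_word_prior,
                 max_iterations = as.integer(max_iterations),
                 min_df = as.integer(min_df),
                 seed = as.integer(seed)),
            class = "lda_config")
}

#' Fit an LDA topic model
#'
#' Fits Latent Dirichlet Allocation by collapsed Gibbs sampling. The
#' vocabulary is built from lowercased tokens after stopword removal,
#' dropping single-character tokens and terms below the minimum document
#' frequency. Documents left empty after filtering keep a (uniform) theta
#' row.
#'
#' @param tokens list of character vectors, one per document (e.g. from
#'   [corpus_tokens()]).
#' @param config an [lda_config()].
#' @param stopwords stopword list used for vocabulary construction.
#' @return list of class `lda_result` with elements `theta` (documents x
#'   topics; rows sum to 1), `phi` (topics x vocabulary; rows sum to 1),
#'   `vocabulary` and `config`.
#' @export
fit_lda <- function(tokens, config = lda_config(),
                    stopwords = mirlit_stopwords()) {
  stopifnot(inherits(config, "lda_config"))
  if (length(tokens) < config$n_topics)
    stop("need at least n_topics documents")
  toks <- lapply(tokens, function(tk) {
    tk <- tolower(tk)
    tk[nchar(tk) > 1 & !tk %in% stopwords]
  })
  df <- table(unlist(lapply(toks, unique)))
  vocab <- sort(names(df)[df >= config$min_df])
  if (length(vocab) == 0) stop("vocabulary empty after filtering")
  ids <- lapply(toks, function(tk) {
    i <- match(tk, vocab)
    as.integer(i[!is.na(i)] - 1L)
  })
  set.seed(config$seed)
  fit <- lda_gibbs_cpp(ids, length(vocab), config$n_topics,
                       config$doc_topic_prior, config$topic_word_prior,
                       config$max_iterations)
  colnames(fit$phi) <- vocab
  structure(list(theta = fit$theta, phi = fit$phi, vocabulary = vocab,
                 config = config),
            class = "lda_result")
}

#' Dominant topic per document
#'
#' Argmax of each document's topic-probability row; ties break toward the
#' lowest topic index. Topics are reported 1-based.
#'
#' @param theta documents x topics probability matrix (or an `lda_result`).
#' @return integer vector of topic indices.
#' @export
dominant_topic <- function(theta) {
  if (inherits(theta, "lda_result")) theta <- theta$theta
  apply(theta, 1, which.max)
}

#' Top-weighted terms per topic
#'
#' @param phi topics x vocabulary probability matrix with term column names
#'   (or an `lda_result`).
#' @param k number of terms per topic (<= vocabulary size).
#' @return list (one per topic) of character vectors of length `k`, sorted
#'   by descending weight with lexicographic tie-break.
#' @export
top_terms <- function(phi, k = 5) {
  if (inherits(phi, "lda_result")) phi <- phi$phi
  stopifnot(k <= ncol(phi))
  terms <- colnames(phi)
  lapply(seq_len(nrow(phi)), function(t) {
    terms[order(-phi[t, ], terms)][seq_len(k)]
  })
}

#' Topic-by-year document counts
#'
#' Cross-tabulates dominant topic against publication year; documents
#' without a parseable year are omitted.
#'
#' @param result an `lda_result` fitted on `corp` (same document order).
#' @param corp the corpus.
#' @return matrix, topics (rows, all 1..K) x years (columns, ascending).
#' @export
topic_year_matrix <- function(result, corp) {
  stopifnot(nrow(result$theta) == nrow(corp))
  K <- result$config$n_topics
  if (nrow(corp) == 0) return(matrix(0L, K, 0, dimnames = list(seq_len(K), NULL)))
  topic <- dominant_topic(result)
  yr <- extract_year(corp$pub_date)
  keep <- !is.na(yr)
  tab <- table(factor(topic[keep], levels = seq_len(K)), yr[keep])
  m <- matrix(as.integer(tab), nrow = K,
              dimnames = list(topic = rownames(tab), year = colnames(tab)))
  m[, order(colnames(m)), drop = FALSE]
}

#' miRNA-by-topic document counts
#'
#' Cell (m, t) counts documents whose dominant topic is t and whose
#' deduplicated miRNA set contains core m.
#'
#' @param result an `lda_result` fitted on the same documents.
#' @param tagged_corp a corpus with a `mirna_set` column ([tag_corpus()]).
#' @return matrix, miRNA cores (rows, sorted) x topics (columns 1..K).
#' @export
mirna_topic_matrix <- function(result, tagged_corp) {
  stopifnot(nrow(result$theta) == nrow(tagged_corp))
  K <- result$config$n_topics
  topic <- dominant_topic(result)
  cores <- sort(unique(unlist(tagged_corp$mirna_set)))
  m <- matrix(0L, length(cores), K,
              dimnames = list(mirna = cores, topic = seq_len(K)))
  for (i in seq_len(nrow(tagged_corp))) {
    for (core in tagged_corp$mirna_set[[i]]) m[core, topic[i]] <- m[core, topic[i]] + 1L
  }
  m
}
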