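#' Default keyword pools for planted topics
#'
#' Three built-in, pairwise-disjoint pools mimic recurring themes of the
#' diabetes miRNA literature (inflammation, kidney disease, islet biology);
#' additional topics get generic disjoint pools.
#'
#' @param n_topics number of pools required.
#' @return list of character vectors.
#' @export
default_topic_pools <- function(n_topics = 3) {
  base <- list(
    c("inflammation", "cytokine", "macrophage", "interleukin", "immune",
      "stroke", "nfkb", "tlr4", "signaling", "neuropathy"),
    c("kidney", "nephropathy", "renal", "albuminuria", "fibrosis",
      "glomerular", "podocyte", "proteinuria", "mesangial", "tubular"),
    c("islet", "beta-cell", "insulin", "secretion", "pancreatic",
      "glucose", "metabolism", "glycemic", "incretin", "apoptosis"))
  if (n_topics <= 3) return(base[seq_len(n_topics)])
  extra <- lapply(seq(4, n_topics), function(k)
    paste0("theme", k, "term", letters[1:10]))
  c(base, extra)
}

default_filler_vocab <- function() {
  # weighted toward the tokens that dominate real abstract word counts
  c(mirna = 0.20, expression = 0.15, patient = 0.10, study = 0.07,
    level = 0.07, analysis = 0.06, cell = 0.06, gene = 0.06,
    target = 0.06, regulation = 0.06, serum = 0.06, pathway = 0.05)
}

#' Default surface-form family weights
#'
#' All default families are coverable by the recognition pattern, so a
#' default-mode corpus round-trips through the tagger with perfect recall.
#'
#' @return named numeric weights summing to 1.
#' @export
default_surface_weights <- function() {
  c(plain = 0.25, nohyphen = 0.10, mirna = 0.10, microrna = 0.10,
    species = 0.10, letter = 0.10, copy = 0.05, arm = 0.15, upper = 0.05)
}

#' Synthetic corpus configuration
#'
#' Defines the generative conditions: two document classes (case/control)
#' with class-conditional miRNA mention probabilities, topic-structured
#' abstract vocabulary, and realistic miRNA surface-form variation.
#' Synthetic miRNA numbers are drawn from 900-999 to avoid colliding with
#' real literature names in mixed tests.
#'
#' @param n_docs documents per class (default 500).
#' @param n_topics planted topics (default 3).
#' @param topic_pools list of pairwise-disjoint keyword pools, one per topic.
#' @param signal_mirnas tibble with columns `core`, `p_case`, `p_control`:
#'   per-document Bernoulli mention probabilities by class (default 5
#'   miRNAs at 0.6 in cases vs 0.1 in controls).
#' @param background_mirnas tibble with columns `core`, `p`: cores mentioned
#'   at the same rate in both classes.
#' @param words_per_abstract integer range (min, max) of abstract length.
#' @param p_topic_word,p_filler,p_class_term per-slot probabilities of
#'   drawing from the topic pool, the shared filler vocabulary, or the
#'   class marker term (the class-term mass falls back to filler in
#'   control documents).
#' @param class_term token planted at high rate in case documents only
#'   (default "diabetes").
#' @param surface_weights surface-form family weights
#'   ([default_surface_weights()]).
#' @param plant_genes optional tibble with columns `symbol`, `p`: gene
#'   symbols planted (with PubTator-style gene annotations) per document;
#'   when given, planted miRNA surfaces are annotated as genes too.
#' @param adversarial also emit surface forms the recognition pattern
#'   cannot cover (for negative testing).
#' @param years candidate publication years.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 500, n_topics = 3,
                         topic_pools = default_topic_pools(n_topics),
                         signal_mirnas = tibble::tibble(
                           core = paste0("miR-", 901:905),
                           p_case = 0.6, p_control = 0.1),
                         background_mirnas = tibble::tibble(
                           core = paste0("miR-", 910:924), p = 0.15),
                         words_per_abstract = c(40, 80),
                         p_topic_word = 0.55, p_filler = 0.35,
                         p_class_term = 0.10, class_term = "diabetes",
                         surface_weights = default_surface_weights(),
                         plant_genes = NULL, adversarial = FALSE,
                         years = 2006:2023, seed = 1) {
  stopifnot(n_docs >= 1, n_topics >= 2, length(topic_pools) == n_topics,
            all(signal_mirnas$p_case >= 0 & signal_mirnas$p_case <= 1),
            all(signal_mirnas$p_control >= 0 & signal_mirnas$p_control <= 1),
            length(words_per_abstract) == 2,
            abs(p_topic_word + p_filler + p_class_term - 1) < 1e-8)
  all_pool <- unlist(topic_pools)
  if (anyDuplicated(all_pool)) stop("topic pools must be pairwise disjoint")
  structure(list(n_docs = as.integer(n_docs), n_topics = as.integer(n_topics),
                 topic_pools = topic_pools, signal_mirnas = signal_mirnas,
                 background_mirnas = background_mirnas,
                 words_per_abstract = as.integer(words_per_abstract),
                 p_topic_word = p_topic_word, p_filler = p_filler,
                 p_class_term = p_class_term, class_term = class_term,
                 surface_weights = surface_weights,
                 plant_genes = plant_genes, adversarial = adversarial,
                 years = years, seed = as.integer(seed)),
            class = "synth_config")
}

#' Sample one miRNA surface form
#'
#' Renders a core name in one of the naming-variant families observed in
#' the literature (plain `miR-155`, `miR155`, `miRNA-155`, `microRNA-155`,
#' species-prefixed `hsa-miR-155`, letter suffix `miR-155a`, genomic-copy
#' suffix `miR-155-2`, arm suffix `miR-155-5p`, all-caps). `let` cores fall
#' back to `let`-compatible variants. In adversarial mode, forms the
#' recognition pattern cannot cover (`lin-4`, `micro-RNA-155`) are mixed in
#' for negative testing. Uses the current RNG state.
#'
#' @param core a core name matching `^(miR|let)-[0-9]+$`.
#' @param weights surface-family weights.
#' @param adversarial emit non-coverable forms with probability 0.2.
#' @return a single surface-form string.
#' @export
sample_surface_form <- function(core, weights = default_surface_weights(),
                                adversarial = FALSE) {
  if (!grepl("^(miR|let)-[0-9]+$", core)) stop("malformed core: ", core)
  num <- sub("^.*-", "", core)
  is_let <- startsWith(core, "let")
  if (adversarial && stats::runif(1) < 0.2) {
    return(sample(c("lin-4", paste0("micro-RNA-", num)), 1))
  }
  fam <- sample(names(weights), 1, prob = weights)
  if (is_let && fam %in% c("mirna", "microrna")) fam <- "plain"
  switch(fam,
    plain = core,
    nohyphen = sub("-", "", core),
    mirna = paste0("miRNA-", num),
    microrna = paste0("microRNA-", num),
    species = paste0("hsa-", core),
    letter = paste0(core, sample(c("a", "b"), 1)),
    copy = paste0(core, "-", sample(1:3, 1)),
    arm = paste0(core, sample(c("-5p", "-3p"), 1)),
    upper = toupper(core))
}

#' Generate a synthetic labeled corpus with ground truth
#'
#' Each document gets a planted topic (uniform over topics); abstract
#' tokens are drawn per slot from that topic's keyword pool, the shared
#' filler vocabulary, or (case documents only) the class marker term.
#' Signal and background miRNAs are planted independently with their
#' class-conditional Bernoulli probabilities and rendered through
#' [sample_surface_form()]; optional gene symbols are planted with
#' PubTator-style annotations for network tests. Fully deterministic for a
#' given config (including its seed).
#'
#' @param config a [synth_config()].
#' @return list with `corpus` (a labeled [corpus()]; case pmids start at
#'   100001, control at 200001) and `truth` (list with `docs`: pmid, label,
#'   topic; `mentions`: pmid, core, surface, start, end — spans index into
#'   `title + " " + abstract`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  filler <- default_filler_vocab()
  rows <- list(); truth_docs <- list(); truth_mentions <- list()
  for (cls in c("case", "control")) {
    base_pmid <- if (cls == "case") 100000L else 200000L
    for (d in seq_len(config$n_docs)) {
      pmid <- as.character(base_pmid + d)
      topic <- sample.int(config$n_topics, 1)
      L <- sample(seq(config$words_per_abstract[1],
                      config$words_per_abstract[2]), 1)
      u <- stats::runif(L)
      pool <- config$topic_pools[[topic]]
      words <- character(L)
      from_topic <- u < config$p_topic_word
      from_class <- u >= config$p_topic_word + config$p_filler & cls == "case"
      from_fill <- !from_topic & !from_class
      words[from_topic] <- sample(pool, sum(from_topic), replace = TRUE)
      words[from_class] <- config$class_term
      words[from_fill] <- sample(names(filler), sum(from_fill),
                                 replace = TRUE, prob = filler)

      # plant miRNA mentions
      sm <- config$signal_mirnas
      p_sig <- if (cls == "case") sm$p_case else sm$p_control
      planted <- sm$core[stats::runif(nrow(sm)) < p_sig]
      bm <- config$background_mirnas
      if (!is.null(bm) && nrow(bm) > 0)
        planted <- c(planted, bm$core[stats::runif(nrow(bm)) < bm$p])
      surfaces <- vapply(planted, sample_surface_form, "",
                         weights = config$surface_weights,
                         adversarial = config$adversarial, USE.NAMES = FALSE)

      # plant gene symbols
      gene_syms <- character()
      if (!is.null(config$plant_genes) && nrow(config$plant_genes) > 0) {
        pg <- config$plant_genes
        gene_syms <- pg$symbol[stats::runif(nrow(pg)) < pg$p]
      }

      extra <- c(surfaces, gene_syms)
      kind <- c(rep("mirna", length(surfaces)), rep("gene", length(gene_syms)))
      if (length(extra) > 0) {
        pos <- sort(sample.int(length(words) + 1L, length(extra),
                               replace = TRUE))
        tokens <- append_tokens(words, extra, pos)
        marks <- tokens$mark
        tokens <- tokens$tokens
      } else {
        tokens <- words
        marks <- integer(length(words))
      }

      title <- paste(c(sample(pool, 2), "study"), collapse = " ")
      abstract <- paste(tokens, collapse = " ")
      starts <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)] +
        nchar(title) + 1L
      ends <- starts + nchar(tokens)

      ann <- NULL
      if (!is.null(config$plant_genes)) {
        idx <- which(marks > 0)
        if (length(idx) > 0) {
          ann <- tibble::tibble(start = starts[idx], end = ends[idx],
                                surface = tokens[idx],
                                entity_type = "gene", concept_id = "")
        } else ann <- empty_annotations()
      }

      mir_idx <- which(marks > 0 & marks <= length(surfaces))
      if (length(mir_idx) > 0) {
        truth_mentions[[length(truth_mentions) + 1L]] <- tibble::tibble(
          pmid = pmid,
          core = planted[marks[mir_idx]],
          surface = tokens[mir_idx],
          start = starts[mir_idx], end = ends[mir_idx])
      }
      truth_docs[[length(truth_docs) + 1L]] <- tibble::tibble(
        pmid = pmid, label = cls, topic = topic)
      rows[[length(rows) + 1L]] <- list(
        pmid = pmid, title = title, abstract = abstract,
        pub_date = as.character(sample(config$years, 1)),
        annotations = ann, label = cls)
    }
  }
  corp <- corpus(
    pmid = vapply(rows, `[[`, "", "pmid"),
    title = vapply(rows, `[[`, "", "title"),
    abstract = vapply(rows, `[[`, "", "abstract"),
    pub_date = vapply(rows, `[[`, "", "pub_date"),
    pub_types = rep(list("Journal Article"), length(rows)),
    annotations = lapply(rows, `[[`, "annotations"),
    label = vapply(rows, `[[`, "", "label"))
  truth <- list(
    docs = do.call(rbind, truth_docs),
    mentions = if (length(truth_mentions) > 0) do.call(rbind, truth_mentions)
               else tibble::tibble(pmid = character(), core = character(),
                                   surface = character(), start = integer(),
                                   end = integer()))
  list(corpus = corp, truth = truth)
}

# Insert extra tokens into a word vector at (sorted, 1-based, with
# replacement) gap positions; returns tokens plus a marker vector giving,
# for inserted tokens, their index into `extra` (0 for base words).
append_tokens <- function(words, extra, pos) {
  n <- length(words) + length(extra)
  tokens <- character(n)
  mark <- integer(n)
  wi <- 1L; ei <- 1L
  for (i in seq_len(n)) {
    if (ei <= length(extra) && (wi > length(words) || pos[ei] <= wi)) {
      tokens[i] <- extra[ei]; mark[i] <- ei; ei <- ei + 1L
    } else {
      tokens[i] <- words[wi]; wi <- wi + 1L
    }
  }
  list(tokens = tokens, mark = mark)
}

#' Write ground-truth tables
#'
#' Emits TSV tables sufficient to score tagger recall/precision, topic
#' recovery and classifier accuracy against the generator's truth.
#'
#' @param truth the `truth` element of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the three file paths.
#' @export
ground_truth_report <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("labels.tsv", "topics.tsv", "mentions.tsv"))
  utils::write.table(truth$docs[, c("pmid", "label")], paths[1],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$docs[, c("pmid", "topic")], paths[2],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$mentions, paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
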