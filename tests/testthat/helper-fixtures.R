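`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny hand-built corpus used across corpus-io tests
tiny_corpus <- function() {
  corpus(
    pmid = c("1", "2", "3"),
    title = c("miR-21 in diabetic kidney disease",
              "let-7a-5p and wound-healing",
              "A study without miRNAs"),
    abstract = c("Expression of miR-21 and miR-21-3p was measured.",
                 "Exosomal let-7a levels rose.",
                 ""),
    pub_date = c("2019 Jan", "2019", "2020 Mar 5"),
    pub_types = list("Journal Article", c("Journal Article", "Review"), "Letter")
  )
}

# maximal permutation-matched agreement between two topic labelings
best_permutation_agreement <- function(assigned, truth, k) {
  perms <- perms_of(seq_len(k))
  max(vapply(perms, function(p) mean(p[assigned] == truth), numeric(1)))
}

perms_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# per-document core sets from a generator truth table
truth_core_sets <- function(truth) {
  sets <- split(truth$mentions$core, truth$mentions$pmid)
  lapply(sets, function(s) sort(unique(s)))
}

# independent exact upper-tail hypergeometric by direct enumeration
enum_hyper_upper <- function(overlap, set_size, universe, draws) {
  xs <- overlap:min(set_size, draws)
  sum(choose(set_size, xs) * choose(universe - set_size, draws - xs)) /
    choose(universe, draws)
}
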