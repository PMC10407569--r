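#' Read a PubTator annotation file
#'
#' The PubTator flat format carries, per document, a `PMID|t|title` line, an
#' optional `PMID|a|abstract` line, and zero or more tab-separated
#' annotation lines `PMID <tab> start <tab> end <tab> surface <tab> type
#' [<tab> conceptID]`. Spans are 0-based half-open offsets into
#' `title + " " + abstract`; annotations whose surface does not equal the
#' text slice at their span are dropped with a warning.
#'
#' @param path path to a PubTator-format file.
#' @return a [corpus()] whose documents carry entity annotations.
#' @export
read_pubtator <- function(path) {
  if (!file.exists(path)) stop("cannot read PubTator file: ", path)
  lines <- readLines(path, warn = FALSE)
  title <- list(); abstract <- list(); ann <- list()
  order_seen <- character()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln))) next
    if (grepl("^[^\t|]+\\|t\\|", ln)) {
      pmid <- sub("\\|.*$", "", ln)
      title[[pmid]] <- sub("^[^|]+\\|t\\|", "", ln)
      if (!pmid %in% order_seen) order_seen <- c(order_seen, pmid)
    } else if (grepl("^[^\t|]+\\|a\\|", ln)) {
      pmid <- sub("\\|.*$", "", ln)
      abstract[[pmid]] <- sub("^[^|]+\\|a\\|", "", ln)
    } else if (grepl("\t", ln)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 5) stop("malformed PubTator annotation at line ", k)
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) stop("malformed PubTator annotation at line ", k)
      pmid <- f[1]
      ann[[pmid]] <- rbind(ann[[pmid]], tibble::tibble(
        start = start, end = end, surface = f[4],
        entity_type = tolower(f[5]),
        concept_id = if (length(f) >= 6) f[6] else ""
      ))
    } else {
      stop("malformed PubTator line ", k)
    }
  }
  if (length(order_seen) == 0) return(corpus(character(), character()))
  corpus(
    pmid = order_seen,
    title = vapply(order_seen, function(p) title[[p]] %||% "", ""),
    abstract = vapply(order_seen, function(p) abstract[[p]] %||% "", ""),
    annotations = lapply(order_seen, function(p) ann[[p]] %||% empty_annotations())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus in PubTator format
#'
#' @param corp a corpus (annotations, where present, are written).
#' @param path output path.
#' @export
write_pubtator <- function(corp, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(corp))) {
    writeLines(paste0(corp$pmid[i], "|t|", corp$title[i]), con)
    if (nzchar(corp$abstract[i]))
      writeLines(paste0(corp$pmid[i], "|a|", corp$abstract[i]), con)
    a <- corp$annotations[[i]]
    if (!is.null(a) && nrow(a) > 0) {
      writeLines(paste(corp$pmid[i], a$start, a$end, a$surface, a$entity_type,
                       a$concept_id, sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
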