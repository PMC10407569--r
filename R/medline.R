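#' Read a MEDLINE flat file
#'
#' Parses the tag-value MEDLINE dialect (`PMID- `, `TI  - `, `AB  - `,
#' `DP  - `, `PT  - `, ...). Continuation lines (leading whitespace) are
#' joined to the previous value with a single space. Records missing a PMID
#' are skipped with a warning; a record repeating an already-seen PMID is
#' dropped with a warning (first occurrence wins).
#'
#' @param path path to a MEDLINE flat file.
#' @return a [corpus()].
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) stop("cannot read MEDLINE file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  tag <- NULL
  flush_field <- function() cur
  push <- function(cur) {
    if (!is.null(cur)) recs[[length(recs) + 1L]] <<- cur
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {  # blank line = record separator
      push(cur); cur <- NULL; tag <- NULL
      next
    }
    if (grepl("^[A-Z]{1,4}\\s*- ", ln)) {
      tag <- sub("^([A-Z]{1,4})\\s*- .*$", "\\1", ln)
      val <- sub("^[A-Z]{1,4}\\s*- ", "", ln)
      if (is.null(cur)) cur <- list()
      cur[[tag]] <- c(cur[[tag]], val)
    } else if (grepl("^\\s", ln) && !is.null(tag)) {
      i <- length(cur[[tag]])
      cur[[tag]][i] <- paste(cur[[tag]][i], trimws(ln))
    }
  }
  push(cur)

  seen <- character()
  rows <- list()
  for (r in recs) {
    if (is.null(r$PMID) || !nzchar(trimws(r$PMID[1]))) {
      warning("MEDLINE record without PMID skipped", call. = FALSE)
      next
    }
    pmid <- trimws(r$PMID[1])
    if (pmid %in% seen) {
      warning("duplicate PMID ", pmid, " dropped", call. = FALSE)
      next
    }
    seen <- c(seen, pmid)
    rows[[length(rows) + 1L]] <- list(
      pmid = pmid,
      title = if (is.null(r$TI)) "" else paste(r$TI, collapse = " "),
      abstract = if (is.null(r$AB)) "" else paste(r$AB, collapse = " "),
      pub_date = if (is.null(r$DP)) NA_character_ else r$DP[1],
      pub_types = if (is.null(r$PT)) character() else r$PT
    )
  }
  if (length(rows) == 0) return(corpus(character(), character()))
  corpus(
    pmid = vapply(rows, `[[`, "", "pmid"),
    title = vapply(rows, `[[`, "", "title"),
    abstract = vapply(rows, `[[`, "", "abstract"),
    pub_date = vapply(rows, `[[`, "", "pub_date"),
    pub_types = lapply(rows, `[[`, "pub_types")
  )
}

#' Write a corpus as a MEDLINE flat file
#'
#' Inverse of [read_medline()] up to whitespace normalization. Only the
#' fields the pipeline consumes (PMID, TI, AB, DP, PT) are written.
#'
#' @param corp a corpus.
#' @param path output path.
#' @export
write_medline <- function(corp, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(corp))) {
    lines <- c(paste0("PMID- ", corp$pmid[i]),
               paste0("TI  - ", corp$title[i]))
    if (nzchar(corp$abstract[i])) lines <- c(lines, paste0("AB  - ", corp$abstract[i]))
    if (!is.na(corp$pub_date[i])) lines <- c(lines, paste0("DP  - ", corp$pub_date[i]))
    for (pt in corp$pub_types[[i]]) lines <- c(lines, paste0("PT  - ", pt))
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}
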