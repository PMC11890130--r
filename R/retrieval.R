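# Evidence retrieval: run the final query against PubMed (live, via NCBI
# E-utilities) or against an offline JSONL fixture store, keep the top
# open-access systematic reviews / meta-analyses, and fetch their text.
#
# Fixture mode is a pure function of (query, store) and is the path the
# test suite exercises; live mode applies the same contract over esearch /
# efetch with polite rate limiting.

#' Retrieval configuration
#'
#' @param max_results Number of articles to keep (default 20).
#' @param mode `"fixture"` or `"live"`.
#' @param fixture_path JSONL article store (required in fixture mode).
#' @param open_access_filter Filter clause restricting to freely available
#'   full text (default `"free full text[Filter]"`; set `NULL` to disable).
#' @param publication_filter Clause restricting publication types (default
#'   systematic reviews and meta-analyses; `NULL` to disable).
#' @param email,api_key NCBI etiquette for live mode.
#' @param max_retries,backoff_base Live-mode retry policy (exponential
#'   backoff).
#' @return List of class `retrieval_config`.
#' @export
retrieval_config <- function(max_results = 20L,
                             mode = c("fixture", "live"),
                             fixture_path = NULL,
                             open_access_filter = "free full text[Filter]",
                             publication_filter =
                               "(systematic review[Publication Type] OR meta-analysis[Publication Type])",
                             email = NULL, api_key = NULL,
                             max_retries = 3L, backoff_base = 1) {
  mode <- match.arg(mode)
  stopifnot(max_results >= 1L)
  if (mode == "fixture" && is.null(fixture_path)) {
    stop("fixture mode requires fixture_path")
  }
  structure(list(max_results = as.integer(max_results), mode = mode,
                 fixture_path = fixture_path,
                 open_access_filter = open_access_filter,
                 publication_filter = publication_filter,
                 email = email, api_key = api_key,
                 max_retries = as.integer(max_retries),
                 backoff_base = backoff_base),
            class = "retrieval_config")
}

new_article_record <- function(pmid, title = "", pmcid = NULL, rank = NA_integer_,
                               text = NULL, sentences = NULL,
                               excluded = FALSE, exclusion_reason = NULL) {
  structure(list(pmid = pmid, pmcid = pmcid, title = title,
                 rank = as.integer(rank), text = text, sentences = sentences,
                 excluded = excluded, exclusion_reason = exclusion_reason),
            class = "article_record")
}

#' @export
print.article_record <- function(x, ...) {
  cat(sprintf("<article pmid=%s rank=%s%s> %s\n", x$pmid,
              ifelse(is.na(x$rank), "?", x$rank),
              if (isTRUE(x$excluded)) " EXCLUDED" else "", x$title))
  invisible(x)
}

#' Load a JSONL article fixture store
#'
#' One article per line: `pmid`, optional `pmcid`, `title`, `text`,
#' optional `mesh_terms` (array of descriptor strings).
#'
#' @param path JSONL file.
#' @return List of article entries (plain lists).
#' @export
load_article_store <- function(path) {
  if (!file.exists(path)) stop("fixture store not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) stop("malformed store line ", i,
                                           call. = FALSE))
    if (is.null(x$pmid)) stop("store line ", i, " missing pmid")
    x$mesh_terms <- unlist(x$mesh_terms) %||% character(0)
    x
  })
}

query_term_texts <- function(query) {
  toks <- lex_query(query)
  vals <- vapply(Filter(function(t) t$type == "word", toks),
                 function(t) tolower(t$value), character(1))
  unique(vals)
}

#' Search for the top related articles
#'
#' Fixture mode scores every store article by the number of distinct query
#' terms (quoted phrases and bare words of the final query) found in its
#' title, text or MeSH annotations, keeps positive scores and ranks by
#' score descending with ties broken by ascending PMID — a deterministic
#' stand-in for relevance ordering. Live mode appends the open-access and
#' publication-type filter clauses and submits the query to E-utilities
#' esearch, retrying with exponential backoff.
#'
#' @param query Final PubMed query string.
#' @param config A [retrieval_config()].
#' @return List of `article_record`, at most `max_results`, ranks `1..n`.
#' @export
search_top_articles <- function(query, config) {
  stopifnot(nzchar(trimws(query)))
  if (config$mode == "fixture") {
    store <- load_article_store(config$fixture_path)
    terms <- query_term_texts(query)
    scores <- vapply(store, function(a) {
      hay <- tolower(paste(a$title %||% "", a$text %||% "",
                           paste(a$mesh_terms, collapse = " ")))
      hay <- paste0(" ", gsub("[^a-z0-9à-ÿ-]+", " ", hay), " ")
      sum(vapply(terms, function(tm) {
        grepl(paste0(" ", gsub("[^a-z0-9à-ÿ-]+", " ", tm), " "), hay,
              fixed = TRUE)
      }, logical(1)))
    }, numeric(1))
    keep <- which(scores > 0)
    if (length(keep) == 0L) return(list())
    pmids <- vapply(store[keep], function(a) as.character(a$pmid), character(1))
    ord <- keep[order(-scores[keep], as.numeric(pmids))]
    ord <- utils::head(ord, config$max_results)
    lapply(seq_along(ord), function(r) {
      a <- store[[ord[r]]]
      new_article_record(as.character(a$pmid), title = a$title %||% "",
                         pmcid = a$pmcid, rank = r)
    })
  } else {
    live_search(query, config)
  }
}

#' Compose the live-mode query with its filter clauses
#'
#' @param query Final query string.
#' @param config A [retrieval_config()].
#' @return The query submitted to esearch.
#' @export
live_query_string <- function(query, config) {
  parts <- c(paste0("(", query, ")"),
             config$open_access_filter, config$publication_filter)
  paste(parts[!vapply(parts, is.null, logical(1))], collapse = " AND ")
}

live_search <- function(query, config) {
  q <- live_query_string(query, config)
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi"
  url <- paste0(base, "?db=pubmed&sort=relevance&retmax=", config$max_results,
                "&term=", utils::URLencode(q, reserved = TRUE),
                if (!is.null(config$email))
                  paste0("&email=", utils::URLencode(config$email)),
                if (!is.null(config$api_key))
                  paste0("&api_key=", config$api_key))
  xml <- with_retries(function() paste(readLines(url, warn = FALSE),
                                       collapse = ""),
                      config$max_retries, config$backoff_base)
  doc <- xml2::read_xml(xml)
  ids <- xml2::xml_text(xml2::xml_find_all(doc, "//IdList/Id"))
  lapply(seq_along(ids), function(r) new_article_record(ids[r], rank = r))
}

with_retries <- function(fn, max_retries, backoff_base) {
  for (attempt in seq_len(max_retries)) {
    out <- tryCatch(fn(), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (attempt == max_retries) stop("retrieval failed after ", max_retries,
                                     " attempts: ", conditionMessage(out))
    Sys.sleep(backoff_base * 2^(attempt - 1))
  }
}

#' Fetch and segment an article's text
#'
#' Populates `sentences` via [segment_sentences()] over the article's
#' abstract+body text (fixture store `text` field; live mode fetches the
#' abstract via efetch). Idempotent: an already-fetched record is returned
#' unchanged. An article without retrievable text is flagged
#' `excluded = TRUE` with a reason.
#'
#' @param record An `article_record`.
#' @param config A [retrieval_config()].
#' @return The updated record.
#' @export
fetch_article_text <- function(record, config) {
  if (!is.null(record$sentences)) return(record)
  txt <- if (config$mode == "fixture") {
    store <- load_article_store(config$fixture_path)
    hit <- Filter(function(a) as.character(a$pmid) == record$pmid, store)
    if (length(hit)) hit[[1L]]$text %||% "" else NULL
  } else {
    live_fetch_abstract(record$pmid, config)
  }
  if (is.null(txt) || !nzchar(trimws(txt %||% ""))) {
    record$excluded <- TRUE
    record$exclusion_reason <- "no retrievable text"
    return(record)
  }
  record$text <- txt
  record$sentences <- segment_sentences(txt, doc_id = paste0("pmid", record$pmid))
  record
}

live_fetch_abstract <- function(pmid, config) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
  url <- paste0(base, "?db=pubmed&rettype=abstract&retmode=xml&id=", pmid,
                if (!is.null(config$api_key))
                  paste0("&api_key=", config$api_key))
  xml <- with_retries(function() paste(readLines(url, warn = FALSE),
                                       collapse = ""),
                      config$max_retries, config$backoff_base)
  doc <- xml2::read_xml(xml)
  paste(xml2::xml_text(xml2::xml_find_all(doc, "//AbstractText")),
        collapse = " ")
}

#' PubMed URL for a PMID
#'
#' @param pmid Numeric PMID string.
#' @return `https://pubmed.ncbi.nlm.nih.gov/<pmid>/`
#' @export
pubmed_url <- function(pmid) {
  if (!grepl("^[0-9]+$", pmid)) stop("pmid must be a numeric string: ", pmid)
  paste0("https://pubmed.ncbi.nlm.nih.gov/", pmid, "/")
}

#' Flag listed PMIDs as excluded
#'
#' Mechanises the manual relevance screen: records on the exclusion list
#' are flagged (not removed), so survivor ranks are untouched. Unknown
#' PMIDs are ignored with a warning.
#'
#' @param records List of `article_record`.
#' @param exclusion_list Character vector of PMIDs.
#' @return Updated record list.
#' @export
apply_exclusions <- function(records, exclusion_list) {
  if (length(exclusion_list) == 0L) return(records)
  known <- vapply(records, function(r) r$pmid, character(1))
  unknown <- setdiff(exclusion_list, known)
  if (length(unknown)) {
    warning("exclusion list PMIDs not in batch (ignored): ",
            paste(unknown, collapse = ", "))
  }
  lapply(records, function(r) {
    if (r$pmid %in% exclusion_list) {
      r$excluded <- TRUE
      r$exclusion_reason <- r$exclusion_reason %||% "exclusion list"
    }
    r
  })
}
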