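# Corpus ingestion: HTML -> cleaned text -> ordered, id-stamped sentences.
#
# A Document is the pipeline's unit of processing: a web page or article
# reduced to sentences with character spans into the cleaned text. Spans are
# 0-based half-open, so `substr(text, start + 1, end)` recovers each
# sentence exactly.

#' Construct a Document
#'
#' A Document holds a cleaned text and its ordered sentences. If `text` is
#' supplied the sentences are produced by [segment_sentences()]; otherwise a
#' pre-built sentence table can be passed directly.
#'
#' @param doc_id Unique identifier within a corpus.
#' @param text Cleaned plain text (optional if `sentences` given).
#' @param source `"webpage"` or `"article"`.
#' @param disease_tag Optional disease label for the page.
#' @param title Optional title.
#' @param sentences Optional pre-built sentence data frame
#'   (`sent_id`, `text`, `start`, `end`).
#' @return An object of class `mfc_document`.
#' @export
new_document <- function(doc_id, text = NULL, source = c("webpage", "article"),
                         disease_tag = NULL, title = NULL, sentences = NULL) {
  source <- match.arg(source)
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (is.null(sentences)) {
    text <- text %||% ""
    sentences <- segment_sentences(text, doc_id = doc_id)
  }
  structure(
    list(doc_id = doc_id, source = source,
         disease_tag = disease_tag, title = title,
         text = text, sentences = sentences),
    class = "mfc_document")
}

#' @export
print.mfc_document <- function(x, ...) {
  cat(sprintf("<Document %s> source=%s, %d sentence(s)\n",
              x$doc_id, x$source, nrow(x$sentences)))
  if (!is.null(x$disease_tag)) cat("  disease:", x$disease_tag, "\n")
  invisible(x)
}

empty_sentences <- function() {
  data.frame(sent_id = character(0), text = character(0),
             start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Extract the main content of an HTML page
#'
#' Strips navigation, headers, footers, scripts and other boilerplate from a
#' web page and returns the main-content paragraphs joined by newlines. A
#' paragraph is kept when it reads like prose: enough characters, a high
#' enough density of function words, and a low density of link text — the
#' stopword-density heuristic popularised by boilerplate-removal tools.
#'
#' @param html An HTML document as a single string. Real-world tag soup is
#'   tolerated.
#' @param min_chars Minimum paragraph length in characters (default 25).
#' @param stopword_threshold Minimum fraction of stopword tokens for a short
#'   paragraph to count as prose (default 0.25). Long paragraphs
#'   (>= `long_chars`) are kept regardless of density.
#' @param max_link_density Paragraphs whose anchor text exceeds this fraction
#'   of their characters are discarded as link lists (default 0.5).
#' @param long_chars Length at which a paragraph is kept unconditionally.
#' @return The concatenated main text, `""` when nothing qualifies (including
#'   empty or non-HTML input — never an error).
#' @export
extract_main_text <- function(html, min_chars = 25, stopword_threshold = 0.25,
                              max_link_density = 0.5, long_chars = 150) {
  if (!is.character(html) || length(html) != 1L) return("")
  if (!nzchar(trimws(html)) || !grepl("<", html, fixed = TRUE)) return("")
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return("")

  drop <- xml2::xml_find_all(
    doc, "//script|//style|//nav|//header|//footer|//aside|//noscript|//form|//button")
  xml2::xml_remove(drop)

  blocks <- xml2::xml_find_all(
    doc, "//p|//h1|//h2|//h3|//h4|//li|//blockquote|//td")
  if (length(blocks) == 0L) return("")

  keep <- character(0)
  for (b in blocks) {
    txt <- squish(xml2::xml_text(b))
    if (!nzchar(txt)) next
    anchors <- xml2::xml_find_all(b, ".//a")
    link_chars <- sum(nchar(vapply(anchors, function(a)
      squish(xml2::xml_text(a)), character(1))))
    if (nchar(txt) > 0 && link_chars / nchar(txt) > max_link_density) next
    toks <- tokenize(txt)
    good <- nchar(txt) >= long_chars ||
      (nchar(txt) >= min_chars && stopword_density(toks) >= stopword_threshold)
    if (good) keep <- c(keep, txt)
  }
  paste(keep, collapse = "\n")
}

squish <- function(x) gsub("[ \t\r\n]+", " ", trimws(x))

#' Segment cleaned text into sentences
#'
#' Deterministic rule-based segmentation: a run of `.`, `!` or `?` ends a
#' sentence when it is followed by whitespace and an upper-case letter,
#' digit or opening quote, unless the preceding word is a known abbreviation
#' (`e.g.`, `Dr.`, ...). Decimal points never split (no whitespace follows
#' them). Fragments shorter than 3 characters after trimming are merged into
#' the following sentence, so every non-whitespace character of the input is
#' covered exactly once.
#'
#' @param text Cleaned plain text.
#' @param doc_id Identifier used to stamp sentence ids (`<doc_id>-s<k>`).
#' @return Data frame with columns `sent_id`, `text`, `start`, `end`; spans
#'   are 0-based half-open offsets into `text`.
#' @export
segment_sentences <- function(text, doc_id = "doc") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    return(empty_sentences())
  }
  n <- nchar(text)
  chars <- strsplit(text, "")[[1]]

  m <- gregexpr("[.!?]+", text)[[1]]
  ends <- integer(0)
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      p <- m[i] + attr(m, "match.length")[i] - 1L   # last char of the run
      if (p == n) { ends <- c(ends, p); next }
      nxt <- chars[p + 1L]
      if (!grepl("[ \t\n\r]", nxt)) next            # decimals, URLs, etc.
      j <- p + 1L
      while (j <= n && grepl("[ \t\n\r\"'“‘(]", chars[j])) j <- j + 1L
      if (j <= n && !grepl("[A-Z0-9À-Þ]", chars[j])) next
      # abbreviation guard: word (possibly dotted, e.g. "e.g") before the run
      before <- substr(text, max(1L, m[i] - 20L), m[i] - 1L)
      word <- regmatches(before, regexpr("[A-Za-z]+(\\.[A-Za-z]+)*$", before))
      if (length(word) == 1L && tolower(word) %in% mfc_abbreviations()) next
      ends <- c(ends, p)
    }
  }
  if (length(ends) == 0L || ends[length(ends)] < n) ends <- c(ends, n)

  starts <- c(1L, head(ends, -1L) + 1L)
  pieces <- data.frame(start = starts, end = ends)

  # trim whitespace, adjusting offsets; merge pieces < 3 chars forward
  out <- list(); pending <- NULL
  for (i in seq_len(nrow(pieces))) {
    s <- pieces$start[i]; e <- pieces$end[i]
    if (!is.null(pending)) { s <- pending; pending <- NULL }
    while (s <= e && grepl("[ \t\n\r]", chars[s])) s <- s + 1L
    while (e >= s && grepl("[ \t\n\r]", chars[e])) e <- e - 1L
    if (s > e) next
    if (e - s + 1L < 3L && i < nrow(pieces)) { pending <- s; next }
    out[[length(out) + 1L]] <- c(s, e)
  }
  if (length(out) == 0L) return(empty_sentences())
  spans <- do.call(rbind, out)
  data.frame(
    sent_id = sprintf("%s-s%d", doc_id, seq_len(nrow(spans))),
    text = substr(rep(text, nrow(spans)), spans[, 1], spans[, 2]),
    start = as.integer(spans[, 1] - 1L),        # 0-based
    end = as.integer(spans[, 2]),               # half-open
    stringsAsFactors = FALSE)
}

document_to_list <- function(doc) {
  sents <- doc$sentences
  list(
    doc_id = doc$doc_id,
    source = doc$source,
    disease_tag = doc$disease_tag,
    title = doc$title,
    text = doc$text,
    sentences = lapply(seq_len(nrow(sents)), function(i) {
      list(sent_id = sents$sent_id[i], text = sents$text[i],
           start = as.integer(sents$start[i]), end = as.integer(sents$end[i]))
    }))
}

document_from_list <- function(x, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" at line %d", line)
  if (is.null(x$doc_id)) stop("document missing doc_id", where, call. = FALSE)
  if (is.null(x$sentences)) stop("document missing sentences", where, call. = FALSE)
  sents <- x$sentences
  tab <- if (length(sents) == 0L) empty_sentences() else data.frame(
    sent_id = vapply(sents, function(s) s$sent_id, character(1)),
    text = vapply(sents, function(s) s$text, character(1)),
    start = vapply(sents, function(s) as.integer(s$start), integer(1)),
    end = vapply(sents, function(s) as.integer(s$end), integer(1)),
    stringsAsFactors = FALSE)
  new_document(x$doc_id, source = x$source %||% "webpage",
               disease_tag = x$disease_tag, title = x$title,
               text = x$text %||% paste(tab$text, collapse = " "),
               sentences = tab)
}

#' Read documents from JSONL or a directory of text files
#'
#' @param path File (jsonl) or directory (text_dir) path.
#' @param format `"jsonl"` (one Document object per line) or `"text_dir"`
#'   (every `.txt` file becomes a Document, segmented on load).
#' @return List of `mfc_document` objects, input order preserved.
#' @export
load_documents <- function(path, format = c("jsonl", "text_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed JSON at line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
      document_from_list(x, line = i)
    })
  } else {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    lapply(files, function(f) {
      txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n")
      new_document(tools_file_sans_ext(basename(f)), text = txt)
    })
  }
}

tools_file_sans_ext <- function(x) sub("\\.[^.]*$", "", x)

#' Read and write labeled sentence corpora (JSONL)
#'
#' One object per line with fields `sent_id`, `text`, `label` — the format
#' used for classifier training data.
#'
#' @param path JSONL file.
#' @return Data frame with columns `sent_id`, `text`, `label`.
#' @export
load_labeled_corpus <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON at line ", i, call. = FALSE))
    for (f in c("sent_id", "text", "label")) {
      if (is.null(x[[f]])) stop("line ", i, " missing ", f, call. = FALSE)
    }
    data.frame(sent_id = x$sent_id, text = x$text, label = x$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname load_labeled_corpus
#' @param corpus Data frame with `sent_id`, `text`, `label`.
#' @export
save_labeled_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    as.character(jsonlite::toJSON(
      list(sent_id = corpus$sent_id[i], text = corpus$text[i],
           label = corpus$label[i]), auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write documents as canonical JSONL
#'
#' Field order and number formatting are fixed, so save -> load -> save is
#' byte-identical.
#'
#' @param docs List of `mfc_document`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_documents <- function(docs, path) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lines <- vapply(docs, function(d) {
    as.character(jsonlite::toJSON(document_to_list(d), auto_unbox = TRUE,
                                  null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
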