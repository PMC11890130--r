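# MeSH term extraction against a loaded descriptor vocabulary.
#
# The vocabulary maps canonical descriptor names to their tree numbers
# (e.g. "Arthritis, Rheumatoid" -> C05.550.114.154, C17.300.775.099) and to
# lowercase entry terms used for free-text matching. The packaged
# mini-vocabulary (inst/extdata/mesh_mini.tsv, ~50 descriptors spanning
# arthritis, COPD, COVID-19, hypertension, lung cancer, prostate cancer and
# diabetes) is a miniature test vocabulary; the loader accepts any TSV in
# the same descriptor / tree_numbers / entry_terms layout, so a full NLM
# export converted to that layout drops in unchanged.

TREE_NUMBER_RE <- "^[A-Z][0-9]{2}(\\.[0-9]{3})*$"

#' Load a MeSH descriptor vocabulary
#'
#' @param path TSV with columns `descriptor`, `tree_numbers`
#'   (semicolon-separated) and optionally `entry_terms` (pipe-separated
#'   lowercase synonyms; the lowercased descriptor itself is always
#'   included). Defaults to the packaged mini-vocabulary.
#' @return Object of class `mesh_vocabulary`: data frame with list-columns
#'   `tree_numbers` and `entry_terms`.
#' @export
load_mesh_vocabulary <- function(path = mfc_extdata("mesh_mini.tsv")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           encoding = "UTF-8")
  stopifnot(all(c("descriptor", "tree_numbers") %in% names(raw)))
  tn <- strsplit(raw$tree_numbers, ";", fixed = TRUE)
  ok <- vapply(tn, function(x) all(grepl(TREE_NUMBER_RE, x)), logical(1))
  if (any(!ok)) {
    stop("malformed tree numbers for: ",
         paste(raw$descriptor[!ok], collapse = ", "))
  }
  entries <- if ("entry_terms" %in% names(raw)) {
    strsplit(raw$entry_terms, "|", fixed = TRUE)
  } else {
    vector("list", nrow(raw))
  }
  entries <- Map(function(d, e) unique(c(tolower(d), e[nzchar(e)])),
                 raw$descriptor, entries)
  out <- data.frame(descriptor = raw$descriptor, stringsAsFactors = FALSE)
  out$tree_numbers <- tn
  out$entry_terms <- unname(entries)
  class(out) <- c("mesh_vocabulary", "data.frame")
  out
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat(sprintf("<mesh_vocabulary: %d descriptors>\n", nrow(x)))
  invisible(x)
}

#' Extract MeSH terms from text
#'
#' Dictionary backend: each vocabulary entry term is matched in the
#' lowercased text at word boundaries; an exact phrase hit scores 1, a
#' stemmed hit (plural `s`/`es` on the final token) scores 0.9. A
#' descriptor's score is its best entry-term hit. The backend is a pure
#' function of (text, vocabulary). Terms a tagging backend proposes that
#' are absent from the vocabulary are dropped with a warning, so every
#' returned descriptor is guaranteed to carry tree numbers.
#'
#' @param text Non-empty text (typically all sentences of one thematic
#'   category of one page, concatenated).
#' @param vocabulary A [load_mesh_vocabulary()] object.
#' @param threshold Minimum score to keep a term (default 0.5).
#' @param backend Only `"dictionary"` is built in; a tagging backend can be
#'   supplied as a function `text -> data.frame(descriptor, score)` whose
#'   output is then resolved against the vocabulary.
#' @return Data frame with columns `descriptor`, `tree_numbers`
#'   (list-column) and `score`, sorted by score descending then descriptor.
#' @export
extract_mesh_terms <- function(text, vocabulary = load_mesh_vocabulary(),
                               threshold = 0.5, backend = "dictionary") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("text must be a non-empty string")
  }
  if (is.null(vocabulary) || !inherits(vocabulary, "mesh_vocabulary")) {
    stop("a loaded mesh_vocabulary is required")
  }
  hits <- if (is.function(backend)) {
    resolve_tagged_terms(backend(text), vocabulary)
  } else {
    match.arg(backend, "dictionary")
    dictionary_match(text, vocabulary)
  }
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  ord <- order(-hits$score, hits$descriptor)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

dictionary_match <- function(text, vocabulary) {
  low <- paste0(" ", gsub("[^a-z0-9à-ÿ-]+", " ", tolower(text)), " ")
  score <- vapply(vocabulary$entry_terms, function(terms) {
    best <- 0
    for (e in terms) {
      pat_exact <- paste0(" ", gsub("[^a-z0-9à-ÿ-]+", " ", e), " ")
      if (grepl(pat_exact, low, fixed = TRUE)) { best <- max(best, 1); next }
      pat_stem <- paste0(" ", gsub("[^a-z0-9à-ÿ-]+", " ", e), "e?s ")
      if (grepl(pat_stem, low)) best <- max(best, 0.9)
    }
    best
  }, numeric(1))
  keep <- score > 0
  out <- data.frame(descriptor = vocabulary$descriptor[keep],
                    stringsAsFactors = FALSE)
  out$tree_numbers <- vocabulary$tree_numbers[keep]
  out$score <- score[keep]
  out
}

resolve_tagged_terms <- function(tags, vocabulary) {
  stopifnot(is.data.frame(tags), all(c("descriptor", "score") %in% names(tags)))
  idx <- match(tags$descriptor, vocabulary$descriptor)
  if (anyNA(idx)) {
    warning("dropping terms absent from the vocabulary: ",
            paste(tags$descriptor[is.na(idx)], collapse = ", "))
  }
  keep <- !is.na(idx)
  out <- data.frame(descriptor = tags$descriptor[keep],
                    stringsAsFactors = FALSE)
  out$tree_numbers <- vocabulary$tree_numbers[idx[keep]]
  out$score <- tags$score[keep]
  out
}
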