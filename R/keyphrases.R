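# Keyphrase extraction: the query builder's second ingredient besides MeSH
# terms. The built-in backend is a deterministic term-frequency ranker over
# stopword-free 1-3-grams; an embedding-similarity ranker can be plugged in
# as a function.

#' Extract ranked keyphrases from text
#'
#' TF backend: candidates are contiguous 1-3-grams containing no stopword;
#' a candidate's raw weight is frequency x length-in-tokens (so a phrase
#' seen as often as its constituent words outranks them), normalised by the
#' maximum to a score in (0, 1]. Ties are broken alphabetically. The backend
#' is a pure function of the text.
#'
#' @param text Non-empty text.
#' @param top_n Maximum number of phrases to return (default 5 — AND-joining
#'   many phrases into a PubMed subquery quickly yields empty result sets).
#' @param backend `"tf"` or a function `text -> data.frame(phrase, score)`
#'   (e.g. an embedding ranker); function output is lowercased, deduplicated
#'   case-insensitively and re-ranked under the same tie rule.
#' @param max_ngram Longest candidate in tokens (default 3, hard cap 4).
#' @return Data frame with columns `phrase` (lowercase) and `score`, at most
#'   `top_n` rows, score descending.
#' @export
extract_keyphrases <- function(text, top_n = 5L, backend = "tf",
                               max_ngram = 3L) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("text must be a non-empty string")
  }
  stopifnot(top_n >= 1L, max_ngram >= 1L, max_ngram <= 4L)
  cand <- if (is.function(backend)) {
    out <- backend(text)
    stopifnot(is.data.frame(out), all(c("phrase", "score") %in% names(out)))
    out$phrase <- tolower(out$phrase)
    out
  } else {
    match.arg(backend, "tf")
    tf_candidates(text, max_ngram)
  }
  # dedupe case-insensitively, keeping the best score
  cand <- cand[order(-cand$score, cand$phrase), , drop = FALSE]
  cand <- cand[!duplicated(cand$phrase), , drop = FALSE]
  cand <- utils::head(cand, top_n)
  rownames(cand) <- NULL
  cand
}

tf_candidates <- function(text, max_ngram) {
  toks <- tokenize(text)
  stop_mask <- toks %in% mfc_stopwords()
  grams <- character(0)
  for (k in seq_len(max_ngram)) {
    if (length(toks) < k) break
    for (i in seq_len(length(toks) - k + 1L)) {
      span <- i:(i + k - 1L)
      if (any(stop_mask[span])) next
      grams <- c(grams, paste(toks[span], collapse = " "))
    }
  }
  if (length(grams) == 0L) {
    return(data.frame(phrase = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  freq <- table(grams)
  nlen <- lengths(strsplit(names(freq), " ", fixed = TRUE))
  raw <- as.numeric(freq) * nlen
  data.frame(phrase = names(freq), score = raw / max(raw),
             stringsAsFactors = FALSE)
}

#' Drop keyphrases already covered by extracted MeSH terms
#'
#' Case-insensitive comparison of each phrase against the MeSH descriptors
#' and their entry terms; duplicates are removed (and reported via
#' `message`) before query assembly so the same concept is not ANDed with
#' itself across subqueries.
#'
#' @param phrases Keyphrase data frame from [extract_keyphrases()].
#' @param mesh_terms MeSH term data frame from [extract_mesh_terms()].
#' @param vocabulary Vocabulary used to resolve entry terms (optional).
#' @return Filtered keyphrase data frame.
#' @export
dedupe_keyphrases <- function(phrases, mesh_terms,
                              vocabulary = NULL) {
  if (nrow(phrases) == 0L || nrow(mesh_terms) == 0L) return(phrases)
  covered <- tolower(mesh_terms$descriptor)
  if (!is.null(vocabulary)) {
    idx <- match(mesh_terms$descriptor, vocabulary$descriptor)
    covered <- c(covered, unlist(vocabulary$entry_terms[idx[!is.na(idx)]]))
  }
  dup <- phrases$phrase %in% covered
  if (any(dup)) {
    message("dropping keyphrases already covered by MeSH terms: ",
            paste(phrases$phrase[dup], collapse = ", "))
  }
  phrases[!dup, , drop = FALSE]
}
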