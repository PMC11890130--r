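# Sentence similarity and credibility scoring.
#
# Web-page sentences are compared only against literature sentences that
# the same classifier put in the same thematic category; a web sentence
# with at least one match at or above the threshold (default 0.87, applied
# to cosine on its raw [-1,1] scale and to Jaccard on [0,1]) counts as
# credible, and the page score is the credible fraction of its categorized
# (non-neutral) sentences.

#' Deterministic feature-hashing sentence embedder
#'
#' 256-dimensional signed feature hashing of the lowercase token bag: each
#' token is hashed (integer arithmetic only, platform-stable), its hash
#' selects a coordinate and a sign, and token counts accumulate. Word order
#' is ignored by construction. Tokens beyond `max_tokens` are dropped, as
#' in the classifier's truncation contract.
#'
#' @param text A single sentence.
#' @param dim Embedding dimension (default 256).
#' @param max_tokens Truncation length (default 128).
#' @return Numeric vector of length `dim`.
#' @export
hashing_embedder <- function(text, dim = 256L, max_tokens = 128L) {
  toks <- truncate_tokens(tokenize(text), max_tokens)
  hash_token_bag(toks, dim = dim)
}

#' Embed a set of sentences
#'
#' @param sentences Character vector of texts, or data frame with `text`.
#' @param backend Function mapping one text to a numeric vector (default
#'   [hashing_embedder()]).
#' @return Matrix with one row per sentence, order preserved.
#' @export
embed_sentences <- function(sentences, backend = hashing_embedder) {
  texts <- if (is.data.frame(sentences)) sentences$text else sentences
  if (length(texts) == 0L) return(matrix(numeric(0), nrow = 0L))
  if (any(!nzchar(trimws(texts)))) stop("cannot embed empty texts")
  vecs <- lapply(texts, backend)
  len <- unique(lengths(vecs))
  if (length(len) != 1L) stop("backend returned vectors of differing length")
  do.call(rbind, vecs)
}

#' Cosine similarity of two vectors
#'
#' @param u,v Equal-length nonzero numeric vectors.
#' @return `u.v / (|u||v|)`, in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu2 <- sum(u^2); nv2 <- sum(v^2)
  if (nu2 == 0 || nv2 == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / sqrt(nu2 * nv2)
}

#' Jaccard similarity of two sentences' token sets
#'
#' Intersection over union of the lowercased, punctuation-stripped token
#' sets. Two empty sets are identical, so 1 is returned (reported via a
#' message).
#'
#' @param a,b Sentence texts.
#' @return Similarity in [0, 1].
#' @export
jaccard_similarity <- function(a, b) {
  ta <- unique(tokenize(a)); tb <- unique(tokenize(b))
  if (length(ta) == 0L && length(tb) == 0L) {
    message("jaccard_similarity: both token sets empty; returning 1")
    return(1)
  }
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Match web sentences against literature sentences
#'
#' For every categorized (non-neutral) web sentence, scores every article
#' sentence of the same category and keeps pairs at or above the
#' threshold. Neutral sentences on either side never participate.
#'
#' @param web Data frame of web sentences: `sent_id`, `text`, `label`.
#' @param articles Data frame of article sentences: `sent_id`, `text`,
#'   `label`, `pmid`.
#' @param metric `"cosine"` (embeddings via `embedder`) or `"jaccard"`
#'   (token sets).
#' @param threshold Minimum score (default 0.87, the raw-scale equivalent
#'   of an 87% similarity cut).
#' @param embedder Sentence embedding backend for the cosine metric.
#' @return Data frame `web_sent_id`, `article_sent_id`, `pmid`, `category`,
#'   `metric`, `score`, sorted by web sentence id then score descending
#'   (ties by article sentence id).
#' @export
match_sentences <- function(web, articles, metric = c("cosine", "jaccard"),
                            threshold = 0.87, embedder = hashing_embedder) {
  metric <- match.arg(metric)
  empty <- data.frame(web_sent_id = character(0), article_sent_id = character(0),
                      pmid = character(0), category = character(0),
                      metric = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  web <- web[web$label != "neutral", , drop = FALSE]
  articles <- articles[articles$label != "neutral", , drop = FALSE]
  if (nrow(web) == 0L || nrow(articles) == 0L) return(empty)

  if (metric == "cosine") {
    wv <- embed_sentences(web, backend = embedder)
    av <- embed_sentences(articles, backend = embedder)
  }
  rows <- list()
  for (i in seq_len(nrow(web))) {
    same <- which(articles$label == web$label[i])
    for (j in same) {
      s <- if (metric == "cosine") cosine_similarity(wv[i, ], av[j, ])
           else jaccard_similarity(web$text[i], articles$text[j])
      if (s >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          web_sent_id = web$sent_id[i],
          article_sent_id = articles$sent_id[j],
          pmid = as.character(articles$pmid[j]),
          category = web$label[i], metric = metric, score = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$web_sent_id, -out$score, out$article_sent_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize matches into a per-page credibility report
#'
#' @param doc An `mfc_document` (or a doc id string).
#' @param labeled_sentences The page's sentence table with `label` column
#'   (from [predict_labels()]).
#' @param matches Match table from [match_sentences()] for this page.
#' @return Object of class `page_report`: `doc_id`, `n_categorized`
#'   (non-neutral sentences), `n_credible` (sentences with >= 1 match),
#'   `credible_fraction`, `matches`, and `best_evidence` (per credible
#'   sentence its best-scoring literature sentence and PubMed link).
#' @export
summarize_page <- function(doc, labeled_sentences, matches) {
  doc_id <- if (inherits(doc, "mfc_document")) doc$doc_id else doc
  categorized <- labeled_sentences[labeled_sentences$label != "neutral", ,
                                   drop = FALSE]
  unknown <- setdiff(matches$web_sent_id, labeled_sentences$sent_id)
  if (length(unknown)) {
    stop("matches reference sentences not in the document: ",
         paste(unknown, collapse = ", "))
  }
  credible_ids <- unique(matches$web_sent_id)
  n_cat <- nrow(categorized)
  n_cred <- length(credible_ids)
  best <- if (nrow(matches)) {
    do.call(rbind, lapply(split(matches, matches$web_sent_id), function(m) {
      m[which.max(m$score), , drop = FALSE]
    }))
  } else {
    matches
  }
  if (nrow(best)) {
    best$pubmed_url <- vapply(best$pmid, pubmed_url, character(1))
    rownames(best) <- NULL
  }
  structure(list(doc_id = doc_id, n_categorized = n_cat,
                 n_credible = n_cred,
                 credible_fraction = if (n_cat > 0) n_cred / n_cat else 0,
                 matches = matches, best_evidence = best),
            class = "page_report")
}

#' @export
print.page_report <- function(x, ...) {
  cat(sprintf("<page_report %s>\n", x$doc_id))
  cat(sprintf("  categorized sentences: %d\n", x$n_categorized))
  # percentages round half-even to the integer
  cat(sprintf("  credible: %d (%d%%)\n", x$n_credible,
              round(100 * x$credible_fraction)))
  if (!is.null(x$best_evidence) && nrow(x$best_evidence)) {
    cat("  best evidence per credible sentence:\n")
    for (i in seq_len(nrow(x$best_evidence))) {
      b <- x$best_evidence[i, ]
      cat(sprintf("    %s -> %s (score %.4f) %s\n", b$web_sent_id,
                  b$article_sent_id, b$score, b$pubmed_url))
    }
  }
  invisible(x)
}

#' Write a match table as TSV
#' @param matches Match data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, path) {
  m <- matches
  m$score <- sprintf("%.4f", m$score)   # scores reported to 4 decimals
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a page report as JSON
#' @param report A `page_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_page_report <- function(report, path) {
  jsonlite::write_json(
    list(doc_id = report$doc_id, n_categorized = report$n_categorized,
         n_credible = report$n_credible,
         credible_fraction = report$credible_fraction,
         best_evidence = report$best_evidence,
         matches = report$matches),
    path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
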