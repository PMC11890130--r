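# End-to-end orchestration: classify -> extract terms -> build query ->
# retrieve + fetch -> categorize literature with the same classifier ->
# match -> per-page credibility report. One query per (page, thematic
# category); categories with no extractable terms are skipped with a
# logged reason.

#' Pipeline configuration
#'
#' @param model A trained `thematic_classifier`, or `NULL` to train one
#'   from `training_corpus`.
#' @param training_corpus Labeled sentence corpus (required when `model`
#'   is `NULL`).
#' @param classifier A [classifier_config()] used when training here.
#' @param retrieval A [retrieval_config()].
#' @param metric `"cosine"` or `"jaccard"`.
#' @param threshold Similarity threshold (default 0.87).
#' @param top_n_keyphrases Keyphrases per category query (default 5).
#' @param mesh_threshold MeSH extraction score threshold (default 0.5).
#' @param vocabulary A loaded MeSH vocabulary (default: packaged mini).
#' @param embedder Sentence embedding backend for the cosine metric.
#' @param exclusions PMIDs to flag as excluded after retrieval.
#' @param output_dir Where intermediates and reports are written (`NULL`
#'   for none).
#' @param resume Skip documents whose report file already exists in
#'   `output_dir`.
#' @param seed Integer seed recorded in the run and used for training.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(model = NULL, training_corpus = NULL,
                            classifier = classifier_config(),
                            retrieval = NULL,
                            metric = c("cosine", "jaccard"),
                            threshold = 0.87, top_n_keyphrases = 5L,
                            mesh_threshold = 0.5, vocabulary = NULL,
                            embedder = hashing_embedder,
                            exclusions = character(0),
                            output_dir = NULL, resume = FALSE, seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(model) && is.null(training_corpus)) {
    stop("either a trained model or a training corpus is required")
  }
  if (is.null(retrieval)) stop("a retrieval_config is required")
  structure(list(model = model, training_corpus = training_corpus,
                 classifier = classifier, retrieval = retrieval,
                 metric = metric, threshold = threshold,
                 top_n_keyphrases = as.integer(top_n_keyphrases),
                 mesh_threshold = mesh_threshold, vocabulary = vocabulary,
                 embedder = embedder, exclusions = exclusions,
                 output_dir = output_dir, resume = isTRUE(resume),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the fact-checking pipeline over documents
#'
#' For every page: classify sentences; per non-neutral category present,
#' concatenate its sentences, extract MeSH terms and keyphrases, assemble
#' the boolean PubMed query, retrieve and fetch the top articles,
#' categorize their sentences with the same classifier, and match web
#' sentences against same-category literature sentences. Matches are
#' aggregated into one [summarize_page()] report per document. When
#' `output_dir` is set, intermediates (classified sentences, query
#' manifest, match tables, reports) are written as they are produced, and
#' `resume = TRUE` skips documents already reported.
#'
#' @param documents List of `mfc_document` (webpages).
#' @param config A [pipeline_config()].
#' @return List of `page_report`, one per document, with the query
#'   manifest attached as `attr(, "queries")` (data frame: doc_id,
#'   category, query).
#' @export
run_pipeline <- function(documents, config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- config$model %||%
    train_classifier(config$training_corpus, config$classifier)
  vocab <- config$vocabulary %||% load_mesh_vocabulary()
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  reports <- list()
  queries <- list()
  for (doc in documents) {
    report_path <- if (!is.null(outdir))
      file.path(outdir, paste0(doc$doc_id, "-report.json"))
    if (config$resume && !is.null(outdir) && file.exists(report_path)) {
      message("resume: skipping already-reported ", doc$doc_id)
      next
    }
    labeled <- predict_labels(model, doc$sentences)
    if (!is.null(outdir)) {
      write_labeled_jsonl(labeled,
                          file.path(outdir,
                                    paste0(doc$doc_id, "-classified.jsonl")))
    }
    matches <- list()
    for (cat in setdiff(THEMATIC_LABELS, "neutral")) {
      web_cat <- labeled[labeled$label == cat, , drop = FALSE]
      if (nrow(web_cat) == 0L) next
      cat_text <- paste(web_cat$text, collapse = " ")
      mesh <- extract_mesh_terms(cat_text, vocab,
                                 threshold = config$mesh_threshold)
      phrases <- extract_keyphrases(cat_text,
                                    top_n = config$top_n_keyphrases)
      phrases <- suppressMessages(dedupe_keyphrases(phrases, mesh, vocab))
      subs <- list(build_mesh_subquery(group_terms_by_category(mesh)),
                   build_keyphrase_subquery(phrases))
      if (all(vapply(subs, is_empty_query, logical(1)))) {
        message(doc$doc_id, "/", cat, ": no extractable terms, skipped")
        next
      }
      query <- build_final_query(subs)
      queries[[length(queries) + 1L]] <- data.frame(
        doc_id = doc$doc_id, category = cat, query = query,
        stringsAsFactors = FALSE)

      records <- search_top_articles(query, config$retrieval)
      records <- apply_exclusions(records, config$exclusions)
      records <- lapply(records, function(r) {
        if (isTRUE(r$excluded)) r else fetch_article_text(r, config$retrieval)
      })
      active <- Filter(function(r) !isTRUE(r$excluded) &&
                         !is.null(r$sentences) && nrow(r$sentences) > 0,
                       records)
      if (length(active) == 0L) next
      art <- do.call(rbind, lapply(active, function(r) {
        s <- predict_labels(model, r$sentences)
        s$pmid <- r$pmid
        s[, c("sent_id", "text", "label", "pmid")]
      }))
      m <- match_sentences(web_cat, art, metric = config$metric,
                           threshold = config$threshold,
                           embedder = config$embedder)
      if (nrow(m)) matches[[length(matches) + 1L]] <- m
    }
    all_matches <- if (length(matches)) do.call(rbind, matches) else
      match_sentences(labeled[0, , drop = FALSE],
                      data.frame(sent_id = character(0), text = character(0),
                                 label = character(0), pmid = character(0)),
                      metric = config$metric)
    rep <- summarize_page(doc, labeled, all_matches)
    reports[[doc$doc_id]] <- rep
    if (!is.null(outdir)) {
      write_match_table(all_matches,
                        file.path(outdir, paste0(doc$doc_id, "-matches.tsv")))
      write_page_report(rep, report_path)
    }
  }
  qdf <- if (length(queries)) do.call(rbind, queries) else
    data.frame(doc_id = character(0), category = character(0),
               query = character(0), stringsAsFactors = FALSE)
  if (!is.null(outdir)) {
    jsonlite::write_json(qdf, file.path(outdir, "queries.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(reports, "queries") <- qdf
  reports
}

write_labeled_jsonl <- function(labeled, path) {
  lines <- vapply(seq_len(nrow(labeled)), function(i) {
    as.character(jsonlite::toJSON(
      list(sent_id = labeled$sent_id[i], text = labeled$text[i],
           label = labeled$label[i],
           confidence = round(labeled$confidence[i], 6)),
      auto_unbox = TRUE, digits = 8))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
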