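# Synthetic study material: labeled template corpora, a mock article store
# with planted evidence, and ground-truth keys. Everything the pipeline
# needs to build, run and test offline.
#
# Templates instantiate the thematic category definitions: epidemiology
# sentences carry prevalence/incidence/mortality statistics, semiology
# sentences a sign/symptom lexicon, management sentences treatment /
# prevention / diagnosis vocabulary, and neutral sentences site filler.
# With noise_rate = 0 the classes are lexically separable by construction,
# so a term-frequency classifier can reach accuracy 1 — real annotated web
# corpora are far harder; see the methods vignette for what that does and
# does not show.

#' The seven disease subjects used throughout examples and fixtures
#' @export
DEFAULT_DISEASES <- c(
  "rheumatoid arthritis", "chronic obstructive pulmonary disease",
  "COVID-19", "hypertension", "lung cancer", "prostate cancer", "diabetes")

#' Generator specification
#'
#' @param n_per_class Sentences per thematic class (>= 1).
#' @param diseases Disease names to instantiate templates with.
#' @param noise_rate Probability that a sentence's interior tokens are
#'   shuffled (in [0, 1]).
#' @param seed Integer seed; identical specs produce identical output.
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(n_per_class = 25L, diseases = DEFAULT_DISEASES,
                           noise_rate = 0, seed = 1L) {
  stopifnot(n_per_class >= 1L, noise_rate >= 0, noise_rate <= 1,
            length(diseases) >= 1L)
  structure(list(n_per_class = as.integer(n_per_class), diseases = diseases,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

synthetic_templates <- function() {
  list(
    epidemiology = c(
      "As of {year}, the global prevalence rate of {disease} was about {pct}%.",
      "The incidence of {disease} increased to {n} new cases per 100000 people in {year}.",
      "Epidemiologic surveys estimate that {pct}% of adults worldwide live with {disease}.",
      "Smoking and obesity are major risk factors for {disease} in the population.",
      "Mortality attributable to {disease} reached {n} deaths in {year}."),
    semiology = c(
      "{disease} has symptoms such as pain, discomfort, weakness, and fatigue.",
      "High blood pressure is another sign of {disease}.",
      "Early signs of {disease} include persistent cough, fever, and shortness of breath.",
      "Patients with {disease} often complain of swelling, stiffness, and tenderness.",
      "Severe fatigue and unexplained weight loss are warning symptoms of {disease}."),
    management = c(
      "Drug treatment and surgical intervention are options for managing {disease}.",
      "A complete medical examination carried out by a doctor can determine the severity of {disease}.",
      "Doctors recommend regular screening to diagnose {disease} at an early stage.",
      "Vaccination and healthy lifestyle choices help prevent {disease}.",
      "Physical therapy combined with prescribed medication improves outcomes in {disease}."),
    neutral = c(
      "This website provides further reading about {disease} for interested readers.",
      "Our editorial team reviews pages about {disease} every month.",
      "More resources about {disease} are listed in the reference section below.",
      "The author of this page has written extensively about {disease}.",
      "Please contact our office if you have questions about this page on {disease}."))
}

fill_template <- function(tmpl, disease) {
  out <- tmpl
  out <- gsub("{disease}", disease, out, fixed = TRUE)
  out <- gsub("{year}", as.character(sample(1990:2024, 1L)), out, fixed = TRUE)
  out <- gsub("{pct}", sprintf("%.2f", stats::runif(1, 0.1, 25)), out,
              fixed = TRUE)
  out <- gsub("{n}", as.character(sample(100:99999, 1L)), out, fixed = TRUE)
  # capitalize after substitution at sentence start
  paste0(toupper(substr(out, 1L, 1L)), substr(out, 2L, nchar(out)))
}

# shuffle interior tokens, preserving the leading capital and the final
# period so downstream segmentation boundaries survive
shuffle_sentence <- function(text) {
  body <- sub("\\.$", "", text)
  toks <- strsplit(body, " ", fixed = TRUE)[[1]]
  if (length(toks) > 1L) toks <- sample(toks)
  out <- tolower(paste(toks, collapse = " "))
  out <- paste0(toupper(substr(out, 1L, 1L)), substr(out, 2L, nchar(out)))
  paste0(out, ".")
}

#' Generate a labeled synthetic sentence corpus
#'
#' `n_per_class` sentences per thematic label, built from the category
#' templates with diseases and numeric slots sampled under the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @param classes Labels to generate (default all four).
#' @param id_prefix Prefix for sentence ids.
#' @return Data frame `sent_id`, `text`, `label`.
#' @export
generate_labeled_corpus <- function(spec = generator_spec(),
                                    classes = THEMATIC_LABELS,
                                    id_prefix = "syn") {
  tmpl <- synthetic_templates()
  stopifnot(all(classes %in% names(tmpl)))
  set.seed(spec$seed)
  rows <- list()
  for (cls in classes) {
    for (i in seq_len(spec$n_per_class)) {
      t_i <- tmpl[[cls]][((i - 1L) %% length(tmpl[[cls]])) + 1L]
      disease <- sample(spec$diseases, 1L)
      txt <- fill_template(t_i, disease)
      if (spec$noise_rate > 0 && stats::runif(1) < spec$noise_rate) {
        txt <- shuffle_sentence(txt)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sent_id = sprintf("%s-%s-%04d", id_prefix, cls, i),
        text = txt, label = cls, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

disease_mesh_descriptor <- function(disease) {
  map <- c("rheumatoid arthritis" = "Arthritis, Rheumatoid",
           "chronic obstructive pulmonary disease" =
             "Pulmonary Disease, Chronic Obstructive",
           "COVID-19" = "COVID-19", "hypertension" = "Hypertension",
           "lung cancer" = "Lung Neoplasms",
           "prostate cancer" = "Prostatic Neoplasms",
           "diabetes" = "Diabetes Mellitus")
  unname(map[disease])
}

#' Generate a mock article store with planted evidence
#'
#' Builds a companion categorized web-sentence set (the three non-neutral
#' classes, `n_per_class` each) and a JSONL article store whose sentences
#' contain, for a known `overlap_fraction` of the web sentences, a
#' same-category near-duplicate (token-shuffled with probability
#' `noise_rate`; an exact copy at noise 0). Planting is deterministic: the
#' first `round(overlap_fraction * n)` web sentences in corpus order are
#' planted. Filler sentences are template instantiations extended with a
#' pooled-analysis clause so they never collide with web sentences.
#'
#' @param spec A [generator_spec()].
#' @param overlap_fraction Fraction of web sentences with planted evidence.
#' @param path Where to write the JSONL store (default: a tempfile).
#' @param sentences_per_article Planted + filler sentences per article.
#' @return List: `web` (sentence data frame with gold labels),
#'   `store_path`, `articles` (article sentence table: `sent_id`, `text`,
#'   `label`, `pmid`), and `key` (planted pairs: `web_sent_id`,
#'   `article_sent_id`, `pmid`, `category`).
#' @export
generate_article_store <- function(spec = generator_spec(),
                                   overlap_fraction = 0.5,
                                   path = tempfile(fileext = ".jsonl"),
                                   sentences_per_article = 5L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  web <- generate_labeled_corpus(
    spec, classes = setdiff(THEMATIC_LABELS, "neutral"), id_prefix = "web")
  n <- nrow(web)
  k <- round(overlap_fraction * n)
  set.seed(spec$seed + 1L)

  planted <- if (k > 0) {
    data.frame(web_sent_id = web$sent_id[seq_len(k)],
               text = vapply(web$text[seq_len(k)], function(tx) {
                 if (spec$noise_rate > 0 && stats::runif(1) < spec$noise_rate)
                   shuffle_sentence(tx) else tx
               }, character(1)),
               category = web$label[seq_len(k)], stringsAsFactors = FALSE)
  } else {
    data.frame(web_sent_id = character(0), text = character(0),
               category = character(0), stringsAsFactors = FALSE)
  }

  # filler: same thematic material, but extended so no accidental duplicate
  n_filler <- max(6L, ceiling(n / 3))
  filler_corpus <- generate_labeled_corpus(
    generator_spec(n_per_class = ceiling(n_filler / 3), diseases = spec$diseases,
                   noise_rate = 0, seed = spec$seed + 2L),
    classes = setdiff(THEMATIC_LABELS, "neutral"), id_prefix = "fill")
  filler_corpus$text <- mapply(function(tx, k) {
    sub("\\.$", sprintf(", according to a pooled analysis of %d studies.", k),
        tx)
  }, filler_corpus$text, sample(5:95, nrow(filler_corpus), replace = TRUE),
  USE.NAMES = FALSE)

  all_sent <- data.frame(
    text = c(planted$text, filler_corpus$text),
    category = c(planted$category, filler_corpus$label),
    web_sent_id = c(planted$web_sent_id, rep(NA_character_,
                                             nrow(filler_corpus))),
    stringsAsFactors = FALSE)

  n_art <- max(1L, ceiling(nrow(all_sent) / sentences_per_article))
  art_idx <- rep(seq_len(n_art), each = sentences_per_article,
                 length.out = nrow(all_sent))
  key_rows <- list(); store_lines <- character(0); art_tables <- list()
  for (a in seq_len(n_art)) {
    rows <- which(art_idx == a)
    pmid <- as.character(100000L + a)
    sents <- all_sent[rows, , drop = FALSE]
    sent_ids <- sprintf("pmid%s-s%d", pmid, seq_len(nrow(sents)))
    for (j in seq_len(nrow(sents))) {
      if (!is.na(sents$web_sent_id[j])) {
        key_rows[[length(key_rows) + 1L]] <- data.frame(
          web_sent_id = sents$web_sent_id[j], article_sent_id = sent_ids[j],
          pmid = pmid, category = sents$category[j], stringsAsFactors = FALSE)
      }
    }
    diseases_here <- unique(unlist(lapply(spec$diseases, function(d) {
      if (any(grepl(tolower(d), tolower(sents$text), fixed = TRUE))) d
    })))
    mesh <- disease_mesh_descriptor(diseases_here)
    mesh <- mesh[!is.na(mesh)]
    store_lines <- c(store_lines, as.character(jsonlite::toJSON(
      list(pmid = pmid, pmcid = paste0("PMC", pmid),
           title = sprintf("Systematic review %d of %s", a,
                           paste(utils::head(diseases_here, 2L),
                                 collapse = " and ")),
           text = paste(sents$text, collapse = " "),
           mesh_terms = as.list(mesh)),
      auto_unbox = TRUE, digits = NA)))
    art_tables[[a]] <- data.frame(sent_id = sent_ids, text = sents$text,
                                  label = sents$category, pmid = pmid,
                                  stringsAsFactors = FALSE)
  }
  writeLines(store_lines, path, useBytes = TRUE)
  key <- if (length(key_rows)) do.call(rbind, key_rows) else
    data.frame(web_sent_id = character(0), article_sent_id = character(0),
               pmid = character(0), category = character(0),
               stringsAsFactors = FALSE)
  list(web = web, store_path = path,
       articles = do.call(rbind, art_tables), key = key)
}

#' Fraction of planted pairs recovered by a match table
#'
#' @param matches Output of [match_sentences()].
#' @param key Planted-pair key from [generate_article_store()].
#' @param n_web Optional number of web sentences; when given, the recovered
#'   planted-pair count is reported as a fraction of the web set (so it is
#'   directly comparable to `overlap_fraction`). Otherwise the fraction of
#'   key pairs recovered is returned (1 for an empty key — nothing to miss).
#' @return Recovered fraction in [0, 1].
#' @export
planted_recovery <- function(matches, key, n_web = NULL) {
  found <- paste(matches$web_sent_id, matches$article_sent_id)
  hits <- sum(paste(key$web_sent_id, key$article_sent_id) %in% found)
  if (!is.null(n_web)) return(hits / n_web)
  if (nrow(key) == 0L) return(1)
  hits / nrow(key)
}
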