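test_that("cosine similarity matches closed-form values and its bounds", {
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(cosine_similarity(c(3, -1, 2), c(3, -1, 2)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
  set.seed(1)
  for (i in 1:50) {
    u <- rnorm(16); v <- rnorm(16)
    s <- cosine_similarity(u, v)
    expect_lte(abs(s), 1 + 1e-12)
    expect_equal(s, cosine_similarity(v, u))
  }
})

test_that("jaccard similarity is set arithmetic over normalized tokens", {
  expect_equal(jaccard_similarity("high blood pressure",
                                  "blood pressure medication"), 0.5)
  expect_equal(jaccard_similarity("Pain, and fatigue!", "pain and fatigue"), 1)
  expect_equal(jaccard_similarity("alpha beta", "gamma delta"), 0)
  expect_message(expect_equal(jaccard_similarity("...", "!!!"), 1), "empty")
  # 1 - J is a metric on token sets: triangle inequality spot-check
  set.seed(2)
  pool <- c("pain", "fever", "cough", "fatigue", "rash", "ache", "chills")
  for (i in 1:30) {
    s <- vapply(1:3, function(j)
      paste(sample(pool, sample(2:5, 1)), collapse = " "), character(1))
    d <- function(a, b) 1 - jaccard_similarity(a, b)
    expect_lte(d(s[1], s[3]), d(s[1], s[2]) + d(s[2], s[3]) + 1e-12)
  }
})

test_that("hashing embedder is a deterministic bag of tokens", {
  expect_identical(hashing_embedder("blood pressure"),
                   hashing_embedder("blood pressure"))
  expect_identical(hashing_embedder("blood pressure"),
                   hashing_embedder("pressure blood"))
  expect_equal(length(hashing_embedder("anything")), 256L)
  expect_equal(cosine_similarity(hashing_embedder("insulin therapy works"),
                                 hashing_embedder("insulin therapy works")), 1)
  # token-disjoint sentences are near-orthogonal at dimension 256
  set.seed(3)
  corp <- generate_labeled_corpus(generator_spec(n_per_class = 5, seed = 8))
  for (i in 1:20) {
    a <- paste(sample(c("zebra", "quartz", "violin", "meadow"), 3), collapse = " ")
    b <- sample(corp$text, 1)
    expect_lt(abs(cosine_similarity(hashing_embedder(a),
                                    hashing_embedder(b))), 0.2)
  }
})

test_that("embedding a sentence set preserves order and shape", {
  M <- embed_sentences(c("a b", "c d", "e"), backend = hashing_embedder)
  expect_equal(dim(M), c(3L, 256L))
  expect_identical(M[1, ], hashing_embedder("a b"))
  expect_error(embed_sentences(c("ok", " ")), "empty")
})

test_that("matcher equals the brute-force all-pairs oracle on random fixtures", {
  set.seed(404)
  pool <- c("blood", "pressure", "insulin", "pain", "fever", "screening",
            "therapy", "prevalence", "cases", "doctor", "cough", "risk")
  for (rep in 1:10) {
    web <- random_sentence_table(sample(3:6, 1), "w", pool, THEMATIC_LABELS)
    art <- random_sentence_table(sample(5:10, 1), "a", pool, THEMATIC_LABELS)
    for (metric in c("cosine", "jaccard")) {
      th <- sample(c(0.3, 0.6, 0.87), 1)
      got <- match_sentences(web, art, metric = metric, threshold = th)
      want <- brute_force_matches(web, art, metric = metric, threshold = th)
      expect_identical(pair_key(got), pair_key(want))
    }
  }
})

test_that("matching is category-stratified and threshold-monotone", {
  web <- data.frame(sent_id = "w1", text = "insulin therapy works",
                    label = "semiology", stringsAsFactors = FALSE)
  art <- data.frame(sent_id = "a1", text = "insulin therapy works",
                    label = "management", pmid = "1", stringsAsFactors = FALSE)
  expect_equal(nrow(match_sentences(web, art, threshold = 0.5)), 0L)
  art$label <- "semiology"
  expect_equal(nrow(match_sentences(web, art, threshold = 0.5)), 1L)
  expect_equal(nrow(match_sentences(web, art, threshold = 1.01)), 0L)

  set.seed(7)
  pool <- c("blood", "pressure", "insulin", "pain", "fever", "screening")
  webr <- random_sentence_table(6, "w", pool, c("semiology", "management"))
  artr <- random_sentence_table(10, "a", pool, c("semiology", "management"))
  sizes <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th)
    nrow(match_sentences(webr, artr, threshold = th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # neutral sentences never participate
  webn <- data.frame(sent_id = "w9", text = "insulin therapy works",
                     label = "neutral", stringsAsFactors = FALSE)
  expect_equal(nrow(match_sentences(webn, art, threshold = 0)), 0L)
})

test_that("page summaries compute the credible fraction", {
  labeled <- data.frame(
    sent_id = sprintf("p-s%d", 1:30),
    text = sprintf("sentence %d", 1:30),
    label = c(rep("neutral", 3), rep(c("semiology", "epidemiology",
                                       "management"), each = 9)),
    stringsAsFactors = FALSE)
  matches <- data.frame(
    web_sent_id = sprintf("p-s%d", 4:10),
    article_sent_id = sprintf("pmid1-s%d", 1:7),
    pmid = "1", category = "semiology", metric = "cosine",
    score = seq(0.99, 0.87, length.out = 7), stringsAsFactors = FALSE)
  rep <- summarize_page("p", labeled, matches)
  expect_equal(rep$n_categorized, 27L)
  expect_equal(rep$n_credible, 7L)
  expect_equal(rep$credible_fraction, 7 / 27)
  expect_equal(nrow(rep$best_evidence), 7L)
  expect_match(rep$best_evidence$pubmed_url[1], "pubmed.ncbi.nlm.nih.gov/1/")

  none <- summarize_page("p", labeled, matches[0, ])
  expect_equal(none$credible_fraction, 0)
  all_neutral <- summarize_page("p", labeled[labeled$label == "neutral", ],
                                matches[0, ])
  expect_equal(all_neutral$n_categorized, 0L)
  expect_equal(all_neutral$credible_fraction, 0)

  bad <- matches; bad$web_sent_id[1] <- "q-s1"
  expect_error(summarize_page("p", labeled, bad), "not in the document")
})
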