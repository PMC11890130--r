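test_that("main-text extraction keeps body prose and drops chrome", {
  out <- extract_main_text(nav_page_html)
  expect_match(out, "^High blood pressure is a common condition")
  expect_false(grepl("Home|About|Contact|Legal", out))
})

test_that("degenerate html inputs yield empty string, never an error", {
  expect_identical(extract_main_text(""), "")
  expect_identical(extract_main_text("just some plain text"), "")
  expect_identical(extract_main_text(footer_only_html), "")
})

test_that("segmentation splits on terminators but not decimals or abbreviations", {
  s <- segment_sentences("High blood pressure is a sign. It has symptoms.", "d")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text, c("High blood pressure is a sign.", "It has symptoms."))

  one <- segment_sentences("The prevalence was 0.24% in 2014.", "d")
  expect_equal(nrow(one), 1L)

  ab <- segment_sentences(
    "Symptoms include pain, e.g. headaches. Dr. Smith disagrees strongly.", "d")
  expect_equal(ab$text, c("Symptoms include pain, e.g. headaches.",
                          "Dr. Smith disagrees strongly."))

  expect_equal(nrow(segment_sentences("", "d")), 0L)
})

test_that("sentence spans are exact, ordered and cover all non-boilerplate text", {
  txt <- paste("The incidence rose to 51 cases in 2019. Symptoms include",
               "fatigue! Is screening useful? Doctors say yes.")
  s <- segment_sentences(txt, "p")
  # text equals the substring at the 0-based half-open span
  for (i in seq_len(nrow(s))) {
    expect_identical(s$text[i], substr(txt, s$start[i] + 1L, s$end[i]))
  }
  # spans strictly increasing, non-overlapping
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
  # concatenation recovers every non-whitespace character exactly once
  expect_identical(gsub("\\s", "", paste(s$text, collapse = "")),
                   gsub("\\s", "", txt))
  # deterministic across runs
  expect_identical(s, segment_sentences(txt, "p"))
})

test_that("jsonl document round trip is byte-identical", {
  docs <- list(
    new_document("a", text = "One sentence here. And a second one.",
                 disease_tag = "hypertension", title = "Page A"),
    new_document("b", text = "Prevalence was 0.24% in 2014."),
    new_document("c", text = "Screening helps. Treatment exists. Really."))
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  save_documents(docs, f1)
  docs2 <- load_documents(f1, "jsonl")
  expect_equal(length(docs2), 3L)
  expect_identical(docs2[[1]]$sentences, docs[[1]]$sentences)
  save_documents(docs2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed jsonl lines are reported with their line number", {
  f <- tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","sentences":[]}',
               '{"title":"missing id","sentences":[]}'), f)
  expect_error(load_documents(f, "jsonl"), "line 2")
  expect_error(load_documents(f, "badformat"))
  expect_error(load_documents(tempfile(), "jsonl"), "does not exist")
})

test_that("a directory of text files loads as segmented documents", {
  d <- tempfile(); dir.create(d)
  writeLines("First sentence here. Second sentence there.",
             file.path(d, "p1.txt"))
  writeLines("Only one sentence in this file.", file.path(d, "p2.txt"))
  docs <- load_documents(d, "text_dir")
  expect_equal(length(docs), 2L)
  expect_equal(docs[[1]]$doc_id, "p1")
  expect_equal(nrow(docs[[1]]$sentences), 2L)
  expect_equal(nrow(docs[[2]]$sentences), 1L)
})

test_that("labeled corpora round-trip through jsonl", {
  corp <- generate_labeled_corpus(generator_spec(n_per_class = 3, seed = 2))
  f <- tempfile(fileext = ".jsonl")
  save_labeled_corpus(corp, f)
  expect_identical(load_labeled_corpus(f), corp)
  writeLines('{"sent_id":"a","text":"t"}', f)
  expect_error(load_labeled_corpus(f), "missing label")
})

test_that("duplicate doc ids are rejected at save time", {
  docs <- list(new_document("a", text = "One."), new_document("a", text = "Two."))
  expect_error(save_documents(docs, tempfile()), "duplicate doc_id")
})
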