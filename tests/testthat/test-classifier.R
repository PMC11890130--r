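corpus_100 <- generate_labeled_corpus(generator_spec(n_per_class = 100, seed = 7))

test_that("keyword baseline separates the noiseless template corpus perfectly", {
  model <- train_classifier(corpus_100, classifier_config(backend = "keyword"))
  pred <- predict(model, corpus_100)
  expect_equal(mean(pred$label == corpus_100$label), 1.0)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
})

test_that("category exemplar sentences get their thematic label", {
  model <- train_classifier(corpus_100, classifier_config(backend = "keyword"))
  pred <- predict(model, c(
    "this disease has symptoms such as pain",
    "as of 2014, the global prevalence rate of rheumatoid arthritis was about 0.24%",
    "drug treatment and surgical intervention are options"))
  expect_equal(pred$label, c("semiology", "epidemiology", "management"))
})

test_that("training rejects corpora with an absent class, naming it", {
  broken <- corpus_100[corpus_100$label != "management", ]
  expect_error(train_classifier(broken), "management")
  empties <- corpus_100
  empties$text[3] <- "   "
  expect_error(train_classifier(empties), "empty")
})

test_that("prediction is deterministic and order-invariant", {
  cfg <- classifier_config(backend = "multinomial", seed = 42)
  held <- generate_labeled_corpus(generator_spec(n_per_class = 20, seed = 99))
  m1 <- train_classifier(corpus_100, cfg)
  m2 <- train_classifier(corpus_100, cfg)
  expect_identical(predict(m1, held), predict(m2, held))

  mk <- train_classifier(corpus_100, classifier_config(backend = "keyword"))
  fwd <- predict(mk, held$text)
  rev <- predict(mk, rev(held$text))
  expect_identical(fwd$label, rev(rev$label))
})

test_that("empty inputs produce empty predictions", {
  model <- train_classifier(corpus_100, classifier_config(backend = "keyword"))
  expect_equal(nrow(predict(model, character(0))), 0L)
  expect_equal(nrow(predict_labels(model, character(0))), 0L)
})

test_that("long sentences are truncated, never rejected", {
  model <- train_classifier(corpus_100,
                            classifier_config(backend = "keyword",
                                              max_seq_len = 8L))
  long_text <- paste(rep("filler", 500), collapse = " ")
  expect_silent(p <- predict(model, long_text))
  expect_equal(nrow(p), 1L)
})

test_that("evaluation metrics match hand-computed counts", {
  g <- c("semiology", "semiology", "epidemiology", "management")
  p <- c("semiology", "epidemiology", "epidemiology", "management")
  ev <- evaluate_classification(g, p)
  pc <- ev$per_class
  expect_equal(pc$precision[pc$class == "semiology"], 1)
  expect_equal(pc$recall[pc$class == "semiology"], 0.5)
  expect_equal(pc$f1[pc$class == "semiology"], 2 / 3)
  expect_equal(pc$precision[pc$class == "epidemiology"], 0.5)
  expect_equal(pc$recall[pc$class == "epidemiology"], 1)
  expect_equal(pc$f1[pc$class == "epidemiology"], 2 / 3)
  # confusion-matrix mass conservation and row sums = support
  expect_equal(sum(ev$confusion), length(g))
  expect_equal(unname(rowSums(ev$confusion)),
               pc$support[match(THEMATIC_LABELS, pc$class)])
})

test_that("perfect and degenerate labelings hit the metric conventions", {
  g <- c("semiology", "epidemiology", "management", "semiology")
  perfect <- evaluate_classification(g, g)
  present <- perfect$per_class$support > 0
  expect_true(all(perfect$per_class$f1[present] == 1))

  all_neutral <- evaluate_classification(g, rep("neutral", 4))
  expect_true(all(all_neutral$per_class$f1 == 0))
  expect_true(any(all_neutral$per_class$zero_division))

  expect_error(evaluate_classification(g, g[-1]), "equal length")
})

test_that("cohen kappa follows the marginal-product chance correction", {
  # identical annotations over >= 2 categories
  expect_equal(cohen_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c")), 1)
  # crossed labeling: po = 0.5 = pe
  expect_equal(cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "x", "y")), 0)
  # fully discordant with balanced marginals: po = 0, pe = 0.5
  expect_equal(cohen_kappa(c("x", "y", "x", "y"), c("y", "x", "y", "x")), -1)
  # disjoint single-category annotators: pe = 0, so kappa = po = 0
  expect_equal(cohen_kappa(rep("x", 4), rep("y", 4)), 0)
  # degenerate identical single category: pe = 1, defined as 1
  expect_equal(cohen_kappa(rep("x", 5), rep("x", 5)), 1)
  expect_error(cohen_kappa(c("x", "y"), "x"), "equal length")
})

test_that("kappa is symmetric and rewards self-agreement across random labelings", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(THEMATIC_LABELS, 30, replace = TRUE)
    b <- sample(THEMATIC_LABELS, 30, replace = TRUE)
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
    if (length(unique(a)) >= 2) expect_equal(cohen_kappa(a, a), 1)
  }
})

test_that("stratified split keeps every class in both halves", {
  sp <- split_corpus(corpus_100, prop = 0.8, seed = 3)
  expect_setequal(unique(sp$train$label), THEMATIC_LABELS)
  expect_setequal(unique(sp$validation$label), THEMATIC_LABELS)
  expect_equal(nrow(sp$train) + nrow(sp$validation), nrow(corpus_100))
})
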