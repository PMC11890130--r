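# Thematic sentence classification.
#
# Every sentence of a page gets exactly one of four labels: neutral,
# semiology (signs/symptoms), epidemiology (statistics, prevalence, risk)
# or management (treatment, prevention, diagnosis). Non-neutral sentences
# are the claims worth verifying; the same classifier later categorises
# literature sentences so that matching stays within a theme.

#' Thematic label set, in fixed tie-break order
#' @export
THEMATIC_LABELS <- c("neutral", "semiology", "epidemiology", "management")

#' Classifier configuration
#'
#' Defaults follow the fine-tuning settings used for the transformer route
#' (maximum sequence length 128 tokens; learning rate 3e-5; weight decay
#' 1e-3; 3 epochs; batch size 32). The deterministic backends consume only
#' `max_seq_len`, `weight_decay` (as the multinomial ridge penalty) and
#' `seed`; the remaining fields are kept for provenance and for transformer
#' backends hosted outside this package.
#'
#' @param backend `"keyword"` (per-class term-frequency scoring; fully
#'   deterministic, used throughout the tests) or `"multinomial"`
#'   (regularised multinomial logistic regression over hashed bag-of-words
#'   features, via [nnet::multinom()]).
#' @param model_id Free-form identifier recorded in the model.
#' @param max_seq_len Token truncation length (>= 8); longer sentences are
#'   silently truncated, never rejected.
#' @param learning_rate,weight_decay,epochs,batch_size Training
#'   hyperparameters (see above).
#' @param seed Integer seed controlling any stochastic step.
#' @param hash_dim Feature dimension for the multinomial backend.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(backend = c("keyword", "multinomial"),
                              model_id = "medfactcheck-default",
                              max_seq_len = 128L, learning_rate = 3e-5,
                              weight_decay = 1e-3, epochs = 3L,
                              batch_size = 32L, seed = 1L, hash_dim = 256L) {
  backend <- match.arg(backend)
  stopifnot(max_seq_len >= 8L, epochs >= 1L, hash_dim >= 2L)
  structure(list(backend = backend, model_id = model_id,
                 max_seq_len = as.integer(max_seq_len),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), hash_dim = as.integer(hash_dim)),
            class = "classifier_config")
}

check_labeled_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus), all(c("text", "label") %in% names(corpus)))
  if (any(!nzchar(trimws(corpus$text)))) stop("corpus contains empty texts")
  bad <- setdiff(unique(corpus$label), THEMATIC_LABELS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  missing <- setdiff(THEMATIC_LABELS, unique(corpus$label))
  if (length(missing)) {
    stop("corpus is missing classes: ", paste(missing, collapse = ", "))
  }
  invisible(corpus)
}

truncate_tokens <- function(toks, max_seq_len) {
  if (length(toks) > max_seq_len) toks[seq_len(max_seq_len)] else toks
}

#' Train a thematic sentence classifier
#'
#' Fits the configured backend on a labeled sentence corpus and returns a
#' classed model object with [predict()], [print()] and [summary()] methods.
#'
#' The keyword backend scores a sentence by letting each known token vote
#' for the classes: a token's vote is its smoothed class-conditional
#' frequency normalised across classes, so class-specific vocabulary votes
#' near 1 for its class while ubiquitous words split their vote evenly.
#' The multinomial backend hashes the token bag into `hash_dim` signed
#' features and fits a ridge-penalised multinomial logistic model.
#'
#' @param corpus Data frame with columns `text` and `label` (and optionally
#'   `sent_id`); every one of the four classes must be represented.
#' @param config A [classifier_config()].
#' @return An object of class `thematic_classifier`.
#' @export
train_classifier <- function(corpus, config = classifier_config()) {
  check_labeled_corpus(corpus)
  labels <- factor(corpus$label, levels = THEMATIC_LABELS)
  toks <- lapply(tokenize_many(corpus$text), truncate_tokens,
                 max_seq_len = config$max_seq_len)

  fit <- if (config$backend == "keyword") {
    train_keyword_backend(toks, labels)
  } else {
    train_multinomial_backend(toks, labels, config)
  }
  structure(list(config = config, labels = THEMATIC_LABELS, fit = fit,
                 n_train = nrow(corpus)),
            class = "thematic_classifier")
}

tokenize_many <- function(text) {
  out <- tokenize(text)
  if (length(text) == 1L) list(out) else out
}

train_keyword_backend <- function(toks, labels, alpha = 0.5) {
  vocab <- sort(unique(unlist(toks)))
  counts <- matrix(0, nrow = length(vocab), ncol = length(THEMATIC_LABELS),
                   dimnames = list(vocab, THEMATIC_LABELS))
  for (i in seq_along(toks)) {
    tt <- table(toks[[i]])
    counts[names(tt), as.character(labels[i])] <-
      counts[names(tt), as.character(labels[i])] + as.numeric(tt)
  }
  totals <- colSums(counts)
  # smoothed class-conditional token frequencies, normalised across classes
  p <- sweep(counts + alpha, 2, totals + alpha * length(vocab), "/")
  votes <- p / rowSums(p)
  list(kind = "keyword", votes = votes)
}

train_multinomial_backend <- function(toks, labels, config) {
  X <- t(vapply(toks, hash_token_bag, numeric(config$hash_dim),
                dim = config$hash_dim))
  colnames(X) <- paste0("h", seq_len(ncol(X)))
  df <- data.frame(.label = labels, X, check.names = FALSE)
  set.seed(config$seed)
  fit <- nnet::multinom(.label ~ ., data = df, decay = config$weight_decay,
                        maxit = 100L * config$epochs, trace = FALSE,
                        MaxNWts = 100000L)
  list(kind = "multinomial", model = fit, hash_dim = config$hash_dim)
}

# signed feature hashing of a token bag (shared with the sentence embedder)
hash_token_bag <- function(tokens, dim = 256L) {
  v <- numeric(dim)
  for (t in tokens) {
    h <- mfc_hash(t)
    idx <- (h %% dim) + 1L
    sgn <- if ((h %/% dim) %% 2 == 0) 1 else -1
    v[idx] <- v[idx] + sgn
  }
  v
}

#' @export
print.thematic_classifier <- function(x, ...) {
  cat(sprintf("<thematic_classifier: %s backend, %d training sentences>\n",
              x$config$backend, x$n_train))
  invisible(x)
}

#' @export
summary.thematic_classifier <- function(object, ...) {
  cat(sprintf("Thematic sentence classifier (%s backend)\n",
              object$config$backend))
  cat("  labels:", paste(object$labels, collapse = ", "), "\n")
  cat("  trained on", object$n_train, "sentences\n")
  cat("  max_seq_len:", object$config$max_seq_len,
      " seed:", object$config$seed, "\n")
  if (object$fit$kind == "keyword") {
    cat("  vocabulary size:", nrow(object$fit$votes), "\n")
  }
  invisible(object)
}

#' Predict thematic labels for sentences
#'
#' @param object A `thematic_classifier`.
#' @param newdata Character vector of sentence texts, or a data frame with a
#'   `text` column.
#' @param ... Unused.
#' @return Data frame with columns `label` and `confidence` (the backend's
#'   probability for the chosen label), one row per input sentence, order
#'   preserved. Ties are broken by the fixed label order
#'   neutral < semiology < epidemiology < management.
#' @export
predict.thematic_classifier <- function(object, newdata, ...) {
  texts <- if (is.data.frame(newdata)) newdata$text else newdata
  if (length(texts) == 0L) {
    return(data.frame(label = character(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  toks <- lapply(tokenize_many(texts), truncate_tokens,
                 max_seq_len = object$config$max_seq_len)
  scores <- if (object$fit$kind == "keyword") {
    score_keyword(object$fit, toks)
  } else {
    score_multinomial(object$fit, toks)
  }
  pick <- apply(scores, 1L, which.max)        # which.max: first max = fixed order
  conf <- scores[cbind(seq_along(pick), pick)] / pmax(rowSums(scores), 1e-12)
  data.frame(label = THEMATIC_LABELS[pick], confidence = as.numeric(conf),
             stringsAsFactors = FALSE)
}

score_keyword <- function(fit, toks) {
  t(vapply(toks, function(tt) {
    tt <- tt[tt %in% rownames(fit$votes)]
    if (length(tt) == 0L) {
      # no known vocabulary: uniform (argmax falls back to fixed order)
      rep(1 / ncol(fit$votes), ncol(fit$votes))
    } else {
      colSums(fit$votes[tt, , drop = FALSE])
    }
  }, numeric(length(THEMATIC_LABELS))))
}

score_multinomial <- function(fit, toks) {
  X <- t(vapply(toks, hash_token_bag, numeric(fit$hash_dim),
                dim = fit$hash_dim))
  colnames(X) <- paste0("h", seq_len(ncol(X)))
  p <- stats::predict(fit$model, newdata = as.data.frame(X), type = "probs")
  if (is.null(dim(p))) {                       # single row: named vector
    p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  }
  p[, THEMATIC_LABELS, drop = FALSE]
}

#' Predict labels for a sentence table
#'
#' Convenience wrapper around [predict.thematic_classifier()] that keeps the
#' spec-level contract: one label per sentence, order preserved.
#'
#' @param model A `thematic_classifier`.
#' @param sentences Data frame with a `text` column (e.g. a Document's
#'   sentence table) or a character vector.
#' @return The input as a data frame with `label` and `confidence` columns
#'   appended (or a fresh two-column frame for character input).
#' @export
predict_labels <- function(model, sentences) {
  pred <- predict(model, sentences)
  if (is.data.frame(sentences)) cbind(sentences, pred) else pred
}

#' Stratified train/validation split
#'
#' @param corpus Labeled sentence data frame.
#' @param prop Training proportion (default 0.8), stratified by class.
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
split_corpus <- function(corpus, prop = 0.8, seed = 1L) {
  stopifnot(prop > 0, prop < 1)
  set.seed(seed)
  idx_train <- unlist(lapply(split(seq_len(nrow(corpus)), corpus$label),
                             function(ix) {
    k <- max(1L, floor(length(ix) * prop))
    sort(sample(ix, k))
  }), use.names = FALSE)
  list(train = corpus[sort(idx_train), , drop = FALSE],
       validation = corpus[-sort(idx_train), , drop = FALSE])
}
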