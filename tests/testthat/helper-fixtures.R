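# Shared fixtures and independent oracles, built in code at test time.

# Brute-force all-pairs matcher: independent of match_sentences (raw loops,
# inline similarity formulas), used as the oracle for matcher equivalence.
brute_force_matches <- function(web, articles, metric = "cosine",
                                threshold = 0.87,
                                embedder = hashing_embedder) {
  web <- web[web$label != "neutral", , drop = FALSE]
  articles <- articles[articles$label != "neutral", , drop = FALSE]
  wv <- lapply(web$text, embedder)
  av <- lapply(articles$text, embedder)
  rows <- list()
  for (i in seq_len(nrow(web))) {
    for (j in seq_len(nrow(articles))) {
      if (web$label[i] != articles$label[j]) next
      s <- if (metric == "cosine") {
        u <- wv[[i]]; v <- av[[j]]
        sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      } else {
        ta <- unique(tokenize(web$text[i]))
        tb <- unique(tokenize(articles$text[j]))
        length(intersect(ta, tb)) / length(union(ta, tb))
      }
      if (s >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          web_sent_id = web$sent_id[i], article_sent_id = articles$sent_id[j],
          score = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(web_sent_id = character(0),
                      article_sent_id = character(0), score = numeric(0)))
  }
  do.call(rbind, rows)
}

# canonical pair-set representation for comparing matchers
pair_key <- function(df) sort(paste(df$web_sent_id, df$article_sent_id))

# random labeled sentence tables for matcher fuzzing
random_sentence_table <- function(n, prefix, word_pool, seed_labels) {
  data.frame(
    sent_id = sprintf("%s-%d", prefix, seq_len(n)),
    text = vapply(seq_len(n), function(i) {
      paste(sample(word_pool, sample(3:8, 1), replace = TRUE), collapse = " ")
    }, character(1)),
    label = sample(seed_labels, n, replace = TRUE),
    pmid = "12345",
    stringsAsFactors = FALSE)
}

# random MeSH-term tables for query-builder fuzzing
random_term_set <- function(n_terms, n_letters = 4) {
  letters_pool <- sample(LETTERS[1:12], n_letters)
  words <- function() paste(
    replicate(sample(1:3, 1),
              paste(sample(letters, sample(3:8, 1), replace = TRUE),
                    collapse = "")),
    collapse = " ")
  descriptors <- unique(replicate(n_terms, words()))
  out <- data.frame(descriptor = descriptors, stringsAsFactors = FALSE)
  out$tree_numbers <- lapply(seq_along(descriptors), function(i) {
    k <- sample(1:3, 1)
    vapply(seq_len(k), function(j) {
      depth <- sample(0:3, 1)
      paste0(sample(letters_pool, 1), sprintf("%02d", sample(0:99, 1)),
             if (depth > 0)
               paste0(".", sprintf("%03d", sample(0:999, depth)),
                      collapse = "") else "")
    }, character(1))
  })
  out$score <- 1
  out
}

nav_page_html <- paste0(
  "<html><head><title>t</title><script>var x=1;</script></head><body>",
  "<nav><a href='/home'>Home</a> <a href='/about'>About us</a></nav>",
  "<p>High blood pressure is a common condition that affects many adults ",
  "in the general population of the world.</p>",
  "<footer><a href='/contact'>Contact</a> <a href='/legal'>Legal</a></footer>",
  "</body></html>")

footer_only_html <- paste0(
  "<html><body><footer><ul>",
  "<li><a href='/a'>Link one</a></li><li><a href='/b'>Link two</a></li>",
  "</ul></footer></body></html>")
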