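#' @keywords internal
#' @importFrom stats predict runif setNames
#' @importFrom utils head read.delim write.table URLencode
"_PACKAGE"

# Shared text primitives. Everything here is deterministic and pure: the
# pipeline's offline backends (keyword classifier, dictionary MeSH matcher,
# TF keyphrase ranker, hashing embedder) all tokenize through these helpers,
# so a single definition of "token" keeps the stages consistent.

.mfc_env <- new.env(parent = emptyenv())

mfc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "medfactcheck")
  if (!nzchar(path)) {
    # during development (pkgload) extdata may sit at inst/extdata
    path <- system.file("inst", "extdata", file, package = "medfactcheck")
  }
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' English stopword list used across the pipeline
#'
#' The list ships with the package and backs boilerplate detection
#' (stopword density), keyphrase candidate filtering and the keyword
#' classifier's feature selection.
#'
#' @return Character vector of lowercase stopwords.
#' @export
mfc_stopwords <- function() {
  if (is.null(.mfc_env$stopwords)) {
    .mfc_env$stopwords <- readLines(mfc_extdata("stopwords_en.txt"),
                                    encoding = "UTF-8", warn = FALSE)
  }
  .mfc_env$stopwords
}

mfc_abbreviations <- function() {
  if (is.null(.mfc_env$abbrev)) {
    .mfc_env$abbrev <- readLines(mfc_extdata("abbreviations_en.txt"),
                                 encoding = "UTF-8", warn = FALSE)
  }
  .mfc_env$abbrev
}

#' Tokenize text into lowercase word tokens
#'
#' Lowercases, strips punctuation (keeping internal hyphens and digits) and
#' splits on whitespace. This is the token definition used by every
#' deterministic backend in the package.
#'
#' @param text Character vector.
#' @return A list of character vectors (one per input element), or a single
#'   character vector when `text` has length 1.
#' @export
tokenize <- function(text) {
  out <- lapply(text, function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9à-ÿ%' -]", " ", x)
    x <- gsub("'", "", x)
    toks <- strsplit(trimws(x), "[ ]+")[[1]]
    toks <- toks[nzchar(toks)]
    # strip leading/trailing hyphens left by punctuation removal
    toks <- gsub("^-+|-+$", "", toks)
    toks[nzchar(toks)]
  })
  if (length(text) == 1L) out[[1L]] else out
}

# Deterministic 31-ary rolling hash of a string, mod 2^31. Pure integer
# arithmetic carried in doubles (exact below 2^53), so the value is identical
# across platforms and R builds.
mfc_hash <- function(token) {
  codes <- utf8ToInt(token)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483648
  h
}

stopword_density <- function(tokens) {
  if (length(tokens) == 0L) return(0)
  mean(tokens %in% mfc_stopwords())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
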