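# Boolean PubMed query assembly.
#
# Three levels, mirroring the pipeline's query strategy:
#   subsubquery: OR over the MeSH terms sharing one top-level tree category
#   subquery:    AND across those category groups (plus a keyphrase
#                subquery: AND over keyphrases)
#   final query: OR across the subqueries
# A query is held as a tree (Term / Op nodes) and emitted as a PubMed
# string; a round-trip parser is shipped so emitted strings can be checked
# against the builder's tree.

#' Boolean query term node
#' @param text Term text; embedded double quotes are stripped.
#' @param field Optional PubMed field tag (e.g. `"MeSH Terms"`).
#' @return A `boolean_query` term node.
#' @export
query_term <- function(text, field = NULL) {
  text <- gsub('"', "", text, fixed = TRUE)
  stopifnot(nzchar(text))
  structure(list(kind = "term", text = text, field = field),
            class = "boolean_query")
}

#' Boolean query operator node
#' @param op `"AND"` or `"OR"`.
#' @param children List of >= 2 `boolean_query` nodes.
#' @return A `boolean_query` op node.
#' @export
query_op <- function(op, children) {
  op <- match.arg(op, c("AND", "OR"))
  stopifnot(length(children) >= 2L)
  structure(list(kind = "op", op = op, children = children),
            class = "boolean_query")
}

#' Empty-subquery marker (dropped at final assembly)
#' @return A `boolean_query` empty marker.
#' @export
empty_query <- function() {
  structure(list(kind = "empty"), class = "boolean_query")
}

is_empty_query <- function(q) {
  inherits(q, "boolean_query") && identical(q$kind, "empty")
}

#' @export
print.boolean_query <- function(x, ...) {
  if (is_empty_query(x)) cat("<empty query>\n")
  else cat(emit_query(x), "\n")
  invisible(x)
}

#' Group MeSH terms by top-level tree category
#'
#' The category of a tree number is its leading letter; a term whose tree
#' numbers span k categories is replicated into all k groups (once per
#' group). Groups are ordered alphabetically by letter; no empty group is
#' stored. A term with no tree numbers goes to the reserved miscellaneous
#' group `"X"` with a warning.
#'
#' @param terms MeSH term data frame (`descriptor`, list-column
#'   `tree_numbers`) as returned by [extract_mesh_terms()].
#' @return Named list (class `category_groups`) mapping category letter to a
#'   character vector of descriptors.
#' @export
group_terms_by_category <- function(terms) {
  groups <- list()
  if (!is.null(terms) && nrow(terms) > 0L) {
    for (i in seq_len(nrow(terms))) {
      tns <- terms$tree_numbers[[i]]
      letters_i <- unique(substr(tns, 1L, 1L))
      if (length(letters_i) == 0L) {
        warning("term without tree numbers routed to group X: ",
                terms$descriptor[i])
        letters_i <- "X"
      }
      for (L in letters_i) {
        if (!terms$descriptor[i] %in% groups[[L]]) {
          groups[[L]] <- c(groups[[L]], terms$descriptor[i])
        }
      }
    }
    groups <- groups[order(names(groups))]
  }
  structure(groups, class = "category_groups")
}

#' Build the MeSH subquery from category groups
#'
#' OR within each category group (the subsubqueries), AND across groups.
#' Singleton groups contribute the bare term. Terms carry the
#' `[MeSH Terms]` field tag and are double-quoted when multi-word.
#'
#' @param groups A [group_terms_by_category()] result.
#' @return A `boolean_query` (empty marker when `groups` is empty).
#' @export
build_mesh_subquery <- function(groups) {
  if (length(groups) == 0L) return(empty_query())
  parts <- lapply(unclass(groups), function(terms) {
    nodes <- lapply(terms, query_term, field = "MeSH Terms")
    if (length(nodes) == 1L) nodes[[1L]] else query_op("OR", nodes)
  })
  if (length(parts) == 1L) parts[[1L]] else query_op("AND", unname(parts))
}

#' Build the keyphrase subquery
#'
#' AND over the phrases; multi-word phrases are double-quoted; no field tag
#' (all-fields search).
#'
#' @param phrases Character vector of phrases, or a data frame with a
#'   `phrase` column.
#' @return A `boolean_query` (empty marker for no phrases).
#' @export
build_keyphrase_subquery <- function(phrases) {
  if (is.data.frame(phrases)) phrases <- phrases$phrase
  phrases <- phrases[nzchar(phrases)]
  if (length(phrases) == 0L) return(empty_query())
  nodes <- lapply(phrases, query_term)
  if (length(nodes) == 1L) nodes[[1L]] else query_op("AND", nodes)
}

#' Assemble the final PubMed query string
#'
#' Non-empty subqueries are OR-joined, each parenthesised; empty markers
#' are dropped; a single surviving subquery is emitted bare.
#'
#' @param subqueries List of `boolean_query` nodes.
#' @return The final query string.
#' @export
build_final_query <- function(subqueries) {
  keep <- Filter(Negate(is_empty_query), subqueries)
  if (length(keep) == 0L) {
    stop("no query material: every subquery is empty")
  }
  if (length(keep) == 1L) return(emit_query(keep[[1L]]))
  paste(vapply(keep, function(q) paste0("(", emit_query(q), ")"),
               character(1)),
        collapse = " OR ")
}

#' Combined tree corresponding to [build_final_query()]
#'
#' @param subqueries List of `boolean_query` nodes.
#' @return The OR-of-subqueries tree (or the single surviving subquery).
#' @export
final_query_tree <- function(subqueries) {
  keep <- Filter(Negate(is_empty_query), subqueries)
  if (length(keep) == 0L) stop("no query material: every subquery is empty")
  if (length(keep) == 1L) keep[[1L]] else query_op("OR", keep)
}

#' Emit a query tree as a PubMed query string
#'
#' Multi-word terms are double-quoted; child operator nodes are
#' parenthesised, so the string re-parses to the same tree.
#'
#' @param q A `boolean_query`.
#' @return Query string.
#' @export
emit_query <- function(q) {
  stopifnot(inherits(q, "boolean_query"))
  if (is_empty_query(q)) return("")
  if (q$kind == "term") {
    txt <- if (grepl("\\s", q$text)) paste0('"', q$text, '"') else q$text
    if (!is.null(q$field)) txt <- paste0(txt, "[", q$field, "]")
    return(txt)
  }
  parts <- vapply(q$children, function(ch) {
    s <- emit_query(ch)
    if (ch$kind == "op") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", q$op, " "))
}

#' Parse a PubMed query string back into a tree
#'
#' Recognises the grammar [emit_query()] produces: quoted or bare terms
#' with optional `[Field]` tags, `AND`/`OR`, and parentheses. Operators at
#' one nesting level must agree (the emitter never mixes them without
#' parentheses).
#'
#' @param s Query string.
#' @return A `boolean_query` tree.
#' @export
parse_query <- function(s) {
  toks <- lex_query(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  node <- parse_expr(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing input after position ", st$pos, " in query")
  }
  node
}

lex_query <- function(s) {
  toks <- list(); i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch); i <- i + 1L; next
    }
    if (ch == '"') {
      j <- regexpr('"', substr(s, i + 1L, n), fixed = TRUE)
      if (j == -1L) stop("unterminated quote in query")
      toks[[length(toks) + 1L]] <-
        list(type = "word", value = substr(s, i + 1L, i + j - 1L))
      i <- i + j + 1L; next
    }
    if (ch == "[") {
      j <- regexpr("]", substr(s, i + 1L, n), fixed = TRUE)
      if (j == -1L) stop("unterminated field tag in query")
      toks[[length(toks) + 1L]] <-
        list(type = "field", value = substr(s, i + 1L, i + j - 1L))
      i <- i + j + 1L; next
    }
    m <- regexpr("^[^\\s()\\[\\]\"]+", substr(s, i, n), perl = TRUE)
    w <- regmatches(substr(s, i, n), m)
    if (w %in% c("AND", "OR")) {
      toks[[length(toks) + 1L]] <- list(type = "op", value = w)
    } else {
      toks[[length(toks) + 1L]] <- list(type = "word", value = w)
    }
    i <- i + nchar(w)
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }

parse_expr <- function(st) {
  operands <- list(parse_operand(st))
  op <- NULL
  repeat {
    t <- peek(st)
    if (is.null(t) || t$type != "op") break
    if (is.null(op)) op <- t$value
    else if (!identical(op, t$value)) {
      stop("mixed ", op, "/", t$value, " without parentheses")
    }
    advance(st)
    operands[[length(operands) + 1L]] <- parse_operand(st)
  }
  if (length(operands) == 1L) operands[[1L]] else query_op(op, operands)
}

parse_operand <- function(st) {
  t <- peek(st)
  if (is.null(t)) stop("unexpected end of query")
  if (t$type == "(") {
    advance(st)
    node <- parse_expr(st)
    close <- advance(st)
    if (is.null(close) || close$type != ")") stop("unbalanced parentheses")
    return(node)
  }
  if (t$type != "word") stop("unexpected token of type ", t$type)
  advance(st)
  words <- t$value
  # bare multi-word term cannot occur (emitter quotes them); single word only
  field <- NULL
  nxt <- peek(st)
  if (!is.null(nxt) && nxt$type == "field") {
    field <- nxt$value
    advance(st)
  }
  query_term(words, field = field)
}

#' Structural equality of two query trees
#'
#' @param a,b `boolean_query` trees.
#' @return TRUE when kind, operator, term text, field tags and child order
#'   all agree.
#' @export
query_trees_identical <- function(a, b) {
  if (!identical(a$kind, b$kind)) return(FALSE)
  if (a$kind == "term") {
    return(identical(a$text, b$text) &&
             identical(a$field %||% "", b$field %||% ""))
  }
  if (a$kind == "empty") return(TRUE)
  if (!identical(a$op, b$op) ||
      length(a$children) != length(b$children)) return(FALSE)
  all(mapply(query_trees_identical, a$children, b$children))
}
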