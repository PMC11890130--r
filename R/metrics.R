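# Evaluation: per-class precision/recall/F1 from the confusion matrix, and
# chance-corrected inter-annotator agreement (Cohen's kappa).

#' Evaluate a 4-class labeling against gold
#'
#' Builds the confusion matrix (rows = gold, columns = predicted) over the
#' thematic label set and derives per-class precision, recall and F1.
#' Classes with zero predicted positives get precision 0 by convention and
#' are flagged (`zero_division`), likewise recall for classes with zero
#' support.
#'
#' @param gold,predicted Character vectors of labels from
#'   [THEMATIC_LABELS], equal length.
#' @return An object of class `mfc_eval`: list with `confusion` (4x4 count
#'   matrix), `per_class` (data frame: precision, recall, f1, support,
#'   zero_division), `accuracy`, `macro_f1`, `n`.
#' @export
evaluate_classification <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop("gold and predicted must have equal length (",
         length(gold), " vs ", length(predicted), ")")
  }
  bad <- setdiff(unique(c(gold, predicted)), THEMATIC_LABELS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  g <- factor(gold, levels = THEMATIC_LABELS)
  p <- factor(predicted, levels = THEMATIC_LABELS)
  cm <- table(gold = g, predicted = p)
  cm <- matrix(as.integer(cm), nrow = length(THEMATIC_LABELS),
               dimnames = list(gold = THEMATIC_LABELS,
                               predicted = THEMATIC_LABELS))
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  support <- rowSums(cm)
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    class = THEMATIC_LABELS,
    precision = as.numeric(precision), recall = as.numeric(recall),
    f1 = as.numeric(f1), support = as.integer(support),
    zero_division = pred_pos == 0 | support == 0,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(confusion = cm, per_class = per_class,
                 accuracy = sum(tp) / length(gold),
                 macro_f1 = mean(f1), n = length(gold)),
            class = "mfc_eval")
}

#' @export
print.mfc_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Classification evaluation over %d sentences\n", x$n))
  cat(sprintf("  accuracy %.3f, macro-F1 %.3f\n", x$accuracy, x$macro_f1))
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab, row.names = FALSE)
  if (any(x$per_class$zero_division)) {
    cat("  (0 reported where a class had no predictions or no support)\n")
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' The full report goes to JSON; the confusion matrix additionally to TSV.
#'
#' @param eval An `mfc_eval`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the eval object.
#' @export
write_eval_report <- function(eval, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(accuracy = eval$accuracy, macro_f1 = eval$macro_f1, n = eval$n,
           per_class = eval$per_class,
           confusion = as.data.frame.matrix(eval$confusion)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(eval$confusion, tsv_path, sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(eval)
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement: kappa = (po - pe) / (1 - pe), where po is the
#' observed agreement and pe the expected agreement from the product of the
#' annotators' marginal label frequencies. In the degenerate case pe = 1
#' (both annotators use a single identical category) the annotations agree
#' everywhere and 1 is returned.
#'
#' @param a,b Equal-length label vectors (any label set).
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) {
    stop("annotation vectors must have equal length (",
         length(a), " vs ", length(b), ")")
  }
  if (length(a) == 0L) stop("annotation vectors must be non-empty")
  cats <- sort(unique(c(a, b)))
  fa <- factor(a, levels = cats)
  fb <- factor(b, levels = cats)
  po <- mean(fa == fb)
  pe <- sum(prop.table(table(fa)) * prop.table(table(fb)))
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(1)
  (po - pe) / (1 - pe)
}
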