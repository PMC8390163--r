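#' Build a confusion matrix
#'
#' Tallies predictions against truth into a square integer matrix with
#' rows = true class and columns = predicted class, both ordered by the
#' class vocabulary.
#'
#' @param truth,estimate Factors or character vectors of class labels.
#' @param classes Class vocabulary (defaults to the three echogenicity
#'   classes).
#' @return Integer matrix of class `plaque_cm`.
#' @export
confusion_matrix <- function(truth, estimate, classes = plaque_classes()) {
  truth <- factor(as.character(truth), levels = classes)
  estimate <- factor(as.character(estimate), levels = classes)
  if (anyNA(truth) || anyNA(estimate)) {
    rlang::abort("labels outside the class vocabulary")
  }
  cm <- table(truth = truth, estimate = estimate)
  structure(matrix(as.integer(cm), nrow = length(classes),
                   dimnames = list(truth = classes, estimate = classes)),
            class = c("plaque_cm", "matrix", "array"))
}

as_plaque_cm <- function(cm) {
  if (inherits(cm, "plaque_cm")) return(cm)
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  if (is.null(dimnames(cm))) {
    cls <- plaque_classes()[seq_len(nrow(cm))]
    dimnames(cm) <- list(truth = cls, estimate = cls)
  }
  structure(cm, class = c("plaque_cm", "matrix", "array"))
}

#' Per-class and macro classification metrics
#'
#' Reduces a square confusion matrix to one-vs-rest tallies per class
#' (TP = diagonal entry, FN = rest of the row, FP = rest of the column,
#' TN = everything else) and computes sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 score
#' (harmonic mean of precision and sensitivity). A ratio with an empty
#' denominator is reported as 0 and flagged in the `undefined` column so
#' that macro means stay defined on degenerate folds. Macro means are
#' unweighted averages over classes; accuracy is the diagonal sum over
#' the total.
#'
#' @param cm A confusion matrix ([confusion_matrix()] or a plain square
#'   matrix, rows = truth).
#' @return Tibble with one row per class (`class`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `precision`, `f1`, `undefined`)
#'   and attributes `macro` (tibble of macro means + accuracy) reachable
#'   via [glance.plaque_cm()].
#' @examples
#' cm <- confusion_matrix(rep(plaque_classes(), each = 10),
#'                        rep(plaque_classes(), each = 10))
#' compute_metrics(cm)
#' @export
compute_metrics <- function(cm) {
  cm <- as_plaque_cm(cm)
  total <- sum(cm)
  if (total <= 0) rlang::abort("confusion matrix is empty")
  classes <- rownames(cm)
  safe_div <- function(num, den) {
    if (den == 0) list(v = 0, undef = TRUE) else list(v = num / den, undef = FALSE)
  }
  rows <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sen <- safe_div(tp, tp + fn)
    spe <- safe_div(tn, tn + fp)
    pre <- safe_div(tp, tp + fp)
    f1s <- safe_div(2 * pre$v * sen$v, pre$v + sen$v)
    undef <- sen$undef || spe$undef || pre$undef || f1s$undef
    tibble::tibble(
      class = classes[i], tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sen$v, specificity = spe$v, precision = pre$v,
      f1 = f1s$v, undefined = undef
    )
  })
  macro <- tibble::tibble(
    sensitivity = mean(rows$sensitivity),
    specificity = mean(rows$specificity),
    precision = mean(rows$precision),
    f1 = mean(rows$f1),
    accuracy = sum(diag(cm)) / total,
    n = total
  )
  attr(rows, "macro") <- macro
  class(rows) <- c("plaque_metrics", class(rows))
  rows
}

#' @export
print.plaque_cm <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Macro summary of a confusion matrix or metrics table
#'
#' @param x A `plaque_cm` or the output of [compute_metrics()].
#' @param ... Unused.
#' @return One-row tibble: macro sensitivity, specificity, precision,
#'   F1, accuracy, and total count.
#' @export
glance.plaque_cm <- function(x, ...) {
  attr(compute_metrics(x), "macro")
}

#' @rdname glance.plaque_cm
#' @export
glance.plaque_metrics <- function(x, ...) attr(x, "macro")

#' @rdname compute_metrics
#' @param x A `plaque_cm` object.
#' @param ... Unused.
#' @export
tidy.plaque_cm <- function(x, ...) compute_metrics(x)
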