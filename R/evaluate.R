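#' Diagnostic class labels
#'
#' The four clinical patterns a color-coded axial topogram is assigned to:
#' spherical cornea, regular symmetric astigmatism, regular asymmetric
#' astigmatism, and irregular astigmatism (keratoconus). `IRREGULAR` is the
#' screening-positive class.
#'
#' @format Character vector of length 4, in canonical order.
#' @export
CLASS_LABELS <- c("SPHERICAL", "SYMMETRIC", "ASYMMETRIC", "IRREGULAR")

as_class_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), CLASS_LABELS)
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = CLASS_LABELS)
}

#' Build a 4x4 confusion matrix from predicted and true labels
#'
#' Rows are the true class, columns the predicted class, both in the
#' canonical order `SPHERICAL, SYMMETRIC, ASYMMETRIC, IRREGULAR`.
#'
#' @param pred,truth Character vectors (or factors) of class labels, equal
#'   length.
#' @return An integer matrix of class `confusion_matrix` with row/column
#'   names set to the class labels.
#' @export
#' @examples
#' confusion_matrix(c("SPHERICAL", "IRREGULAR"), c("SPHERICAL", "SYMMETRIC"))
confusion_matrix <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have the same length")
  }
  cm <- table(truth = as_class_label(truth), pred = as_class_label(pred))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(truth = CLASS_LABELS, pred = CLASS_LABELS))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

new_confusion <- function(rows) {
  m <- matrix(as.integer(rows), 4, 4,
              dimnames = list(truth = CLASS_LABELS, pred = CLASS_LABELS))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Published confusion counts of the original clinician-graded test bank
#'
#' The smartphone screening study this package's pipeline emulates evaluated
#' its network on 212 clinician-labelled topograms: 35 spherical, 62
#' symmetric, 55 asymmetric, and 60 irregular (keratoconus). Its published
#' per-class successes and the stated identities of every error reconstruct
#' the full 4x4 confusion table, which this fixture returns for use as a
#' reference in metric computations and reporting.
#'
#' @return A `confusion_matrix` with row sums (35, 62, 55, 60) and trace 201.
#' @export
#' @examples
#' overall_accuracy(reference_confusion())  # 94.81
reference_confusion <- function() {
  new_confusion(rbind(
    c(34, 0, 0, 1),
    c(0, 58, 3, 1),
    c(0, 3, 52, 0),
    c(0, 1, 2, 57)
  ))
}

#' Overall classification accuracy, percent
#'
#' `100 * trace / total`, rounded half-up to 2 decimals to match the
#' conventional reporting style.
#'
#' @param cm A `confusion_matrix`.
#' @return Percentage (scalar).
#' @export
overall_accuracy <- function(cm) {
  stopifnot(sum(cm) > 0)
  round_half_up(100 * sum(diag(cm)) / sum(cm))
}

#' Per-class correct and error percentages
#'
#' Row-wise diagonal (correct) and off-diagonal (error) rates; each row of a
#' confusion matrix is one true class.
#'
#' @param cm A `confusion_matrix`.
#' @return A tibble with columns `class`, `n`, `correct`, `errors`,
#'   `correct_pct`, `error_pct` (2-decimal half-up percentages).
#' @export
per_class_rates <- function(cm) {
  n <- rowSums(cm)
  stopifnot(all(n > 0))
  correct <- diag(cm)
  tibble(
    class = CLASS_LABELS,
    n = as.integer(n),
    correct = as.integer(correct),
    errors = as.integer(n - correct),
    correct_pct = round_half_up(100 * correct / n),
    error_pct = round_half_up(100 * (n - correct) / n)
  )
}

#' Screening sensitivity and specificity for one positive class
#'
#' Collapses the 4-class confusion matrix into a screening 2x2 with
#' `positive` (by default the irregular/keratoconus class) against the rest:
#' sensitivity is the positive-row diagonal over the positive-row total;
#' specificity is the fraction of non-positive samples not predicted
#' positive.
#'
#' @param cm A `confusion_matrix`.
#' @param positive Positive class label (default `"IRREGULAR"`).
#' @return A tibble with one row: `positive_class`, `sensitivity`,
#'   `specificity`, `false_negative_rate`, `false_positive_rate`, all
#'   2-decimal half-up percentages, plus the supporting counts.
#' @export
#' @examples
#' screening_metrics(reference_confusion())
screening_metrics <- function(cm, positive = "IRREGULAR") {
  positive <- as.character(as_class_label(positive))
  pos <- which(CLASS_LABELS == positive)
  n_pos <- sum(cm[pos, ])
  n_neg <- sum(cm[-pos, ])
  stopifnot(n_pos > 0, n_neg > 0)
  tp <- cm[pos, pos]
  fp <- sum(cm[-pos, pos])
  tn <- n_neg - fp
  tibble(
    positive_class = positive,
    true_positives = as.integer(tp),
    false_negatives = as.integer(n_pos - tp),
    true_negatives = as.integer(tn),
    false_positives = as.integer(fp),
    sensitivity = round_half_up(100 * tp / n_pos),
    specificity = round_half_up(100 * tn / n_neg),
    false_negative_rate = round_half_up(100 * (n_pos - tp) / n_pos),
    false_positive_rate = round_half_up(100 * fp / n_neg)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted), n =", sum(x), "\n")
  print(unclass(x))
  cat(sprintf("Overall accuracy: %.2f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Tidy a confusion matrix into one row per cell
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `truth`, `pred`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(
    truth = rep(CLASS_LABELS, times = 4),
    pred = rep(CLASS_LABELS, each = 4),
    n = as.integer(x[cbind(rep(1:4, times = 4), rep(1:4, each = 4))])
  )
}

#' One-row summary of a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with overall and screening statistics.
#' @export
glance.confusion_matrix <- function(x, ...) {
  sm <- screening_metrics(x)
  tibble(
    n = sum(x),
    n_correct = sum(diag(x)),
    accuracy = overall_accuracy(x),
    error_rate = round_half_up(100 * (sum(x) - sum(diag(x))) / sum(x)),
    sensitivity = sm$sensitivity,
    specificity = sm$specificity
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
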