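#' Confusion matrix of a recognition experiment
#'
#' Tabulates paired true and predicted gesture classes into an H x H
#' count matrix (rows = true class, columns = predicted class), the
#' layout used to report per-gesture recognition performance.
#'
#' @param truth character vector of true classes.
#' @param predicted character vector of predicted classes, same length.
#' @param classes class order of the table; defaults to the sorted
#'   union of observed labels. Labels outside `classes` are an error.
#' @return an object of class `"confusion_matrix"` wrapping the integer
#'   count matrix.
#' @examples
#' cm <- confusion_matrix(c("G1", "G1", "G2"), c("G1", "G2", "G2"))
#' cm
#' accuracy(cm)
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("paired-data mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(c(truth, predicted), classes)
  if (length(bad)) stopf("class-set mismatch: '%s'", bad[1])
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  structure(list(counts = counts, classes = classes),
            class = "confusion_matrix")
}

#' Overall recognition accuracy
#'
#' `100 * trace / total`: the percentage of trials whose predicted class
#' equals the true class.
#'
#' @param conf a `"confusion_matrix"`.
#' @return accuracy in percent.
#' @export
accuracy <- function(conf) {
  stopifnot(inherits(conf, "confusion_matrix"))
  tot <- sum(conf$counts)
  if (tot == 0) stop("no trials")
  100 * sum(diag(conf$counts)) / tot
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$counts)
  if (sum(x$counts) > 0)
    cat(sprintf("Accuracy: %.1f%%\n", accuracy(x)))
  invisible(x)
}
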