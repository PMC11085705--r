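#' Fit a SOM-Hebb gesture classifier
#'
#' The offline training flow: band-power features are extracted from the
#' labeled segments (unless a feature matrix is supplied directly), a
#' self-organizing map is trained on them by competitive learning, and
#' the trained neurons are then labeled by supervised Hebbian win
#' counting; neurons that never win are disabled. The fitted object
#' performs recall with [predict.som_hebb()]: a winner search restricted
#' to enabled neurons, no weight adjustment.
#'
#' @param x a list of labeled [eeg_segment()]s, or a numeric feature
#'   matrix (rows = vectors) with `labels` supplied.
#' @param labels class label per row/segment; taken from the segments
#'   when `NULL`.
#' @param grid_size SOM grid side `M` (default 8, i.e. 64 neurons).
#' @param schedule a [som_schedule()].
#' @param bands band table used for feature extraction from segments.
#' @param classes declared class set; defaults to the unique labels in
#'   order of first appearance. Every declared class must have at least
#'   one training example.
#' @return an object of class `"som_hebb"` with components `map`
#'   (the trained `"som_map"`), `neuron_labels` (a `"som_labels"`),
#'   `classes`, `bands`, `schedule`, `train_qe` (mean quantization error
#'   on the training set) and `call`.
#' @examples
#' segs <- simulate_gesture_dataset(gesture_classes(2), n_per_class = 10, seed = 1)
#' fit <- som_hebb(segs, grid_size = 4, schedule = som_schedule(epochs = 20))
#' fit
#' predict(fit, segs[1:3])
#' @seealso [train_som()], [accumulate_wins()], [assign_labels()],
#'   [run_experiment()]
#' @export
som_hebb <- function(x, labels = NULL, grid_size = 8,
                     schedule = som_schedule(), bands = eeg_bands(),
                     classes = NULL) {
  cl <- match.call()
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    feats <- band_features(x, bands = bands)
    if (is.null(labels)) labels <- attr(feats, "labels")
    x <- feats
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("paired-data mismatch")
  if (anyNA(labels)) stop("unknown class: unlabeled training vector")
  if (is.null(classes)) classes <- unique(labels)
  missing_cl <- setdiff(classes, labels)
  if (length(missing_cl)) stopf("empty class: '%s'", missing_cl[1])
  if (!all(labels %in% classes))
    stopf("unknown class: '%s'", setdiff(labels, classes)[1])

  map <- train_som(x, M = grid_size, schedule = schedule)
  wins <- accumulate_wins(map, x, labels, classes = classes)
  nl <- assign_labels(wins)
  structure(list(map = map,
                 neuron_labels = nl,
                 classes = classes,
                 bands = bands,
                 schedule = schedule,
                 grid_size = as.integer(grid_size),
                 train_qe = quantization_error(map, x),
                 n_train = nrow(x),
                 call = cl),
            class = "som_hebb")
}

#' @export
print.som_hebb <- function(x, ...) {
  cat("SOM-Hebb gesture classifier\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("Map: %d x %d neurons, D = %d; classes: %s\n",
              x$map$M, x$map$M, x$map$D, paste(x$classes, collapse = ", ")))
  cat(sprintf("Enabled neurons: %d of %d; training quantization error: %.4g\n",
              sum(x$neuron_labels$enabled), nrow(x$map$weights), x$train_qe))
  invisible(x)
}

#' Text neuron map
#'
#' The grid of per-neuron class assignments, `"x"` marking disabled
#' neurons — the text analogue of the classifier's map display.
#'
#' @param object a fitted `"som_hebb"`.
#' @return character matrix `M x M` (row-major neuron order).
#' @export
neuron_map <- function(object) {
  stopifnot(inherits(object, "som_hebb"))
  lab <- object$neuron_labels$label
  lab[is.na(lab)] <- "x"
  matrix(lab, object$map$M, object$map$M, byrow = TRUE)
}

#' @export
summary.som_hebb <- function(object, ...) {
  nl <- object$neuron_labels
  per_class <- vapply(object$classes,
                      function(cl) sum(nl$label == cl, na.rm = TRUE),
                      integer(1))
  out <- list(model = object, per_class = per_class,
              n_disabled = sum(!nl$enabled), map = neuron_map(object))
  class(out) <- "summary.som_hebb"
  out
}

#' @export
print.summary.som_hebb <- function(x, ...) {
  print(x$model)
  cat("\nNeurons per class:\n")
  print(x$per_class)
  cat(sprintf("Disabled neurons: %d\n\nNeuron map (x = disabled):\n",
              x$n_disabled))
  m <- x$map
  for (r in seq_len(nrow(m))) cat(sprintf("%-3s", m[r, ]), "\n")
  invisible(x)
}

#' @export
coef.som_hebb <- function(object, ...) object$map$weights

#' Recall: classify segments or feature vectors
#'
#' Runs the recall-phase winner search over the enabled neurons only —
#' weights are frozen, disabled neurons are excluded — and reads the
#' predicted gesture class off the winner's label.
#'
#' @param object a fitted `"som_hebb"`.
#' @param newdata an [eeg_segment()], a list of them, or a feature
#'   matrix/vector matching the training dimension.
#' @param type `"class"` for a character vector of predictions,
#'   `"full"` for a data.frame with the winner's grid coordinates.
#' @param ... unused.
#' @return character vector of gesture classes, or a data.frame with
#'   columns `class`, `row`, `col`, `neuron`.
#' @export
predict.som_hebb <- function(object, newdata, type = c("class", "full"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "eeg_segment")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- band_features(newdata, bands = object$bands)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$map$D) stop("dimension mismatch")
  enabled <- object$neuron_labels$enabled
  if (!any(enabled)) stop("no enabled neurons")
  winners <- vapply(seq_len(nrow(newdata)), function(i)
    find_winner(newdata[i, ], object$map, enabled), integer(1))
  cls <- object$neuron_labels$label[winners]
  if (type == "class") return(cls)
  data.frame(class = cls,
             row = object$map$grid[winners, 1],
             col = object$map$grid[winners, 2],
             neuron = winners)
}

#' Plot the labeled neuron map
#'
#' Draws the `M x M` neuron grid with one circle per neuron, colored by
#' the gesture class assigned during Hebbian labeling; disabled neurons
#' are drawn hollow with a cross. A winner can be highlighted.
#'
#' @param x a fitted `"som_hebb"`.
#' @param winner optional neuron index to highlight.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.som_hebb <- function(x, winner = NULL, ...) {
  M <- x$map$M
  grid <- x$map$grid
  lab <- x$neuron_labels$label
  pal <- grDevices::hcl.colors(max(2L, length(x$classes)), "Dark 3")
  col <- ifelse(is.na(lab), NA, pal[match(lab, x$classes)])
  graphics::plot(grid[, 2], M + 1 - grid[, 1], pch = 21,
                 bg = col, cex = 3, xlim = c(0.5, M + 0.5),
                 ylim = c(0.5, M + 0.5), xlab = "column", ylab = "row",
                 axes = FALSE, asp = 1,
                 main = "SOM-Hebb neuron map", ...)
  graphics::axis(1, at = seq_len(M)); graphics::axis(2, at = seq_len(M),
                                                     labels = rev(seq_len(M)))
  dis <- !x$neuron_labels$enabled
  if (any(dis))
    graphics::points(grid[dis, 2], M + 1 - grid[dis, 1], pch = 4, cex = 1.2)
  if (!is.null(winner))
    graphics::points(grid[winner, 2], M + 1 - grid[winner, 1],
                     pch = 21, bg = "yellow", cex = 3)
  graphics::legend("topright", legend = x$classes, pt.bg = pal, pch = 21,
                   bty = "n", inset = c(-0.12, 0), xpd = TRUE, cex = 0.8)
  invisible(x)
}
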