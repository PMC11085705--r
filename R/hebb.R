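#' Accumulate per-neuron win counts (Hebbian labeling phase)
#'
#' Presents each labeled training vector to the trained map (all neurons
#' enabled), and records, for every neuron, how many times it won and
#' which class caused each win. The result does not depend on the
#' presentation order.
#'
#' @param map a trained `"som_map"`.
#' @param x labeled feature matrix (rows = vectors).
#' @param labels class label per row.
#' @param classes declared class set (column order of the table);
#'   defaults to the unique labels in order of first appearance.
#' @return an object of class `"win_counts"`: list with `counts`
#'   (neurons x classes integer matrix) and `classes`.
#' @export
accumulate_wins <- function(map, x, labels, classes = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("paired-data mismatch")
  if (is.null(classes)) classes <- unique(labels)
  if (length(labels) && !all(labels %in% classes))
    stopf("unknown class: '%s'", setdiff(labels, classes)[1])
  counts <- matrix(0L, nrow(map$weights), length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(nrow(x))) {
    C <- find_winner(x[i, ], map)
    j <- match(labels[i], classes)
    counts[C, j] <- counts[C, j] + 1L
  }
  structure(list(counts = counts, classes = classes), class = "win_counts")
}

#' Assign class labels to neurons from win counts
#'
#' Each neuron that won at least once is associated with the class that
#' made it win most often (ties broken by the lowest class index).
#' Neurons that never won get no label and are disabled: they are
#' excluded from the recall-phase winner search, which prevents false
#' recognition by unrepresentative map regions.
#'
#' @param wins a `"win_counts"` object.
#' @return an object of class `"som_labels"`: list with `label`
#'   (character, `NA` for disabled neurons), `enabled` (logical), and
#'   `counts` (the source table).
#' @export
assign_labels <- function(wins) {
  stopifnot(inherits(wins, "win_counts"))
  tot <- rowSums(wins$counts)
  enabled <- tot > 0
  lab <- rep(NA_character_, nrow(wins$counts))
  if (any(enabled))
    lab[enabled] <- wins$classes[max.col(wins$counts[enabled, , drop = FALSE],
                                         ties.method = "first")]
  structure(list(label = lab, enabled = enabled, counts = wins),
            class = "som_labels")
}
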