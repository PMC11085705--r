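#' Run one synthetic recognition experiment
#'
#' A full replica of one offline-training / recall experiment on
#' synthetic data: simulate a labeled training set (30 segments per
#' gesture by default), fit the SOM-Hebb classifier, simulate an
#' independent test set (30 trials per gesture, or 50 in the two-gesture
#' case), classify it, and tabulate the confusion matrix. All randomness
#' — generator, map initialization, presentation shuffling — derives
#' from the single `seed`, so identical configurations give identical
#' reports.
#'
#' @param n_classes number of gesture classes, a prefix of the ordered
#'   list (2, 4, 5 or 7 in the reference protocol; any 1..7 accepted).
#' @param n_train training segments per class.
#' @param n_test test trials per class; defaults to 50 when
#'   `n_classes == 2`, else 30.
#' @param grid_size SOM grid side.
#' @param schedule a [som_schedule()] (its `seed` is overridden by a
#'   seed derived from `seed`).
#' @param signatures gesture signature model, see [default_signatures()].
#' @param noise_sd background noise standard deviation.
#' @param seed master integer seed.
#' @param ... further generator arguments passed to
#'   [simulate_gesture_dataset()] (`duration`, `sample_rate`).
#' @return an object of class `"gesture_experiment"`: list with `model`,
#'   `confusion`, `accuracy`, `predictions` (per-trial class and winner
#'   coordinates) and `config`.
#' @examples
#' \donttest{
#' rep2 <- run_experiment(n_classes = 2, n_train = 10, n_test = 10,
#'                        schedule = som_schedule(epochs = 20), seed = 1)
#' rep2
#' }
#' @export
run_experiment <- function(n_classes = 7, n_train = 30, n_test = NULL,
                           grid_size = 8, schedule = som_schedule(),
                           signatures = default_signatures(),
                           noise_sd = 2, seed = 1, ...) {
  classes <- gesture_classes(n_classes)
  if (is.null(n_test)) n_test <- if (n_classes == 2) 50 else 30
  seeds <- derive_seeds(seed, 3)
  train <- simulate_gesture_dataset(classes, n_per_class = n_train,
                                    seed = seeds[1], signatures = signatures,
                                    noise_sd = noise_sd, ...)
  test <- simulate_gesture_dataset(classes, n_per_class = n_test,
                                   seed = seeds[2], signatures = signatures,
                                   noise_sd = noise_sd, ...)
  schedule$seed <- seeds[3]
  model <- som_hebb(train, grid_size = grid_size, schedule = schedule,
                    classes = classes)
  pred <- predict(model, test, type = "full")
  cm <- confusion_matrix(segment_labels(test), pred$class, classes = classes)
  structure(list(model = model,
                 confusion = cm,
                 accuracy = accuracy(cm),
                 predictions = cbind(truth = segment_labels(test), pred),
                 config = list(n_classes = n_classes, n_train = n_train,
                               n_test = n_test, grid_size = grid_size,
                               schedule = schedule, noise_sd = noise_sd,
                               seed = seed, derived_seeds = seeds)),
            class = "gesture_experiment")
}

#' @export
print.gesture_experiment <- function(x, ...) {
  cat(sprintf("Synthetic gesture recognition experiment: %d classes, %d train + %d test per class, seed %d\n\n",
              x$config$n_classes, x$config$n_train, x$config$n_test,
              x$config$seed))
  print(x$confusion)
  cat(sprintf("\nEnabled neurons: %d of %d\n",
              sum(x$model$neuron_labels$enabled),
              nrow(x$model$map$weights)))
  invisible(x)
}
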