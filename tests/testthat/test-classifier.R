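test_that("fitting on segments yields the declared map and feature geometry", {
  segs <- simulate_gesture_dataset(gesture_classes(2), n_per_class = 5, seed = 1)
  fit <- som_hebb(segs, grid_size = 8, schedule = quick_schedule(1, 10))
  expect_s3_class(fit, "som_hebb")
  expect_equal(nrow(fit$map$weights), 64)
  expect_equal(fit$map$D, 48)
  expect_identical(fit$classes, c("G1", "G2"))
  expect_gte(sum(fit$neuron_labels$enabled), 1)
  expect_equal(dim(neuron_map(fit)), c(8, 8))
})

test_that("identical inputs and seeds give identical models", {
  segs <- simulate_gesture_dataset(gesture_classes(2), n_per_class = 4, seed = 2)
  f1 <- som_hebb(segs, grid_size = 4, schedule = quick_schedule(3))
  f2 <- som_hebb(segs, grid_size = 4, schedule = quick_schedule(3))
  expect_identical(f1$map$weights, f2$map$weights)
  expect_identical(f1$neuron_labels$label, f2$neuron_labels$label)
})

test_that("on separated constant-feature clusters every enabled neuron takes its nearest centroid's class", {
  d <- two_cluster_data(n_per = 15, sep = 20, sd = 0.2, seed = 5)
  fit <- som_hebb(d$x, labels = d$labels, grid_size = 3,
                  schedule = quick_schedule(5))
  cents <- rbind(G1 = colMeans(d$x[1:15, ]), G2 = colMeans(d$x[16:30, ]))
  for (k in which(fit$neuron_labels$enabled)) {
    near <- rownames(cents)[which.min(apply(cents, 1, oracle_distance,
                                            fit$map$weights[k, ]))]
    expect_identical(fit$neuron_labels$label[k], near)
  }
})

test_that("fit validates class sets", {
  d <- two_cluster_data(n_per = 3, seed = 6)
  expect_error(som_hebb(d$x, d$labels, classes = c("G1", "G2", "G3"),
                        grid_size = 2, schedule = quick_schedule(1)),
               "empty class")
  expect_error(som_hebb(d$x, d$labels, classes = "G1",
                        grid_size = 2, schedule = quick_schedule(1)),
               "unknown class")
  expect_error(som_hebb(d$x, d$labels[-1], grid_size = 2,
                        schedule = quick_schedule(1)),
               "paired-data mismatch")
})

test_that("recall returns the enabled winner's label and grid coordinates", {
  d <- two_cluster_data(n_per = 10, seed = 7)
  fit <- som_hebb(d$x, d$labels, grid_size = 3, schedule = quick_schedule(7))

  # a vector equal to an enabled neuron's weight gets that neuron's label
  k <- which(fit$neuron_labels$enabled)[1]
  p <- predict(fit, fit$map$weights[k, ], type = "full")
  expect_identical(p$class, fit$neuron_labels$label[k])
  expect_equal(c(p$row, p$col), unname(fit$map$grid[k, ]))

  # nearest-overall neuron disabled: prediction follows nearest enabled one
  W <- rbind(c(0, 0), c(10, 10), c(30, 30))
  fake <- fit
  fake$map <- structure(list(weights = W, grid = cbind(1:3, 1L), M = NA,
                             D = 2L), class = "som_map")
  fake$neuron_labels <- structure(
    list(label = c(NA, "G3", "G1"), enabled = c(FALSE, TRUE, TRUE),
         counts = NULL), class = "som_labels")
  expect_identical(predict(fake, c(1, 1)), "G3")

  all_off <- fake
  all_off$neuron_labels$enabled <- rep(FALSE, 3)
  expect_error(predict(all_off, c(1, 1)), "no enabled neurons")
})

test_that("predictions match the brute-force enabled-argmin oracle", {
  segs <- simulate_gesture_dataset(gesture_classes(4), n_per_class = 5, seed = 8)
  fit <- som_hebb(segs, grid_size = 4, schedule = quick_schedule(8, 15))
  test <- simulate_gesture_dataset(gesture_classes(4), n_per_class = 25, seed = 9)
  feats <- band_features(test)
  pred <- predict(fit, test)
  enabled <- fit$neuron_labels$enabled
  for (i in seq_len(nrow(feats))) {   # 100 instances
    k <- oracle_winner(feats[i, ], fit$map$weights, enabled)
    expect_identical(pred[i], fit$neuron_labels$label[k])
  }
})

test_that("confusion matrices count pairs exactly", {
  p <- confusion_matrix(c("G1", "G2"), c("G1", "G2"))
  expect_identical(diag(p$counts), c(G1 = 1L, G2 = 1L))
  expect_true(all(p$counts[upper.tri(p$counts) | lower.tri(p$counts)] == 0))

  z <- confusion_matrix(character(0), character(0), classes = c("G1", "G2"))
  expect_true(all(z$counts == 0))
  expect_error(accuracy(z), "no trials")

  truth <- rep(c("A", "B", "C"), each = 4)
  pred <- c("A", "A", "B", "C", "B", "B", "B", "A", "C", "C", "A", "B")
  sh <- withr::with_seed(1, sample(12))
  cm <- confusion_matrix(truth[sh], pred[sh], classes = c("A", "B", "C"))
  expect_identical(cm$counts,
                   matrix(c(2L, 1L, 1L, 1L, 3L, 0L, 1L, 1L, 2L), 3, 3,
                          byrow = TRUE,
                          dimnames = list(true = c("A", "B", "C"),
                                          predicted = c("A", "B", "C"))))
  expect_equal(accuracy(cm), 100 * 7 / 12)

  expect_error(confusion_matrix("G1", c("G1", "G2")), "paired-data mismatch")
  expect_error(confusion_matrix("G5", "G1", classes = c("G1", "G2")),
               "class-set mismatch")
})

test_that("row sums conserve per-class trial counts and accuracy stays in [0, 100]", {
  segs <- simulate_gesture_dataset(gesture_classes(2), n_per_class = 6, seed = 10)
  fit <- som_hebb(segs, grid_size = 4, schedule = quick_schedule(10))
  test <- simulate_gesture_dataset(gesture_classes(2), n_per_class = 8, seed = 11)
  cm <- confusion_matrix(segment_labels(test), predict(fit, test),
                         classes = fit$classes)
  expect_equal(unname(rowSums(cm$counts)), c(8L, 8L))
  a <- accuracy(cm)
  expect_gte(a, 0); expect_lte(a, 100)
})

test_that("near-noise-free distinct signatures are classified perfectly", {
  # class-recovery in the generator noise -> 0 limit
  sched <- quick_schedule(12, 20)
  train <- simulate_gesture_dataset(gesture_classes(4), n_per_class = 10,
                                    seed = 12, noise_sd = 0.01)
  test <- simulate_gesture_dataset(gesture_classes(4), n_per_class = 10,
                                   seed = 13, noise_sd = 0.01)
  fit <- som_hebb(train, grid_size = 8, schedule = sched)
  cm <- confusion_matrix(segment_labels(test), predict(fit, test),
                         classes = fit$classes)
  expect_equal(accuracy(cm), 100)
})
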