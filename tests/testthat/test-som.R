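test_that("map initialization respects data ranges, seeds, and geometry", {
  x <- matrix(runif(20 * 3), 20, 3)
  x[, 2] <- 7                                   # degenerate dimension
  m <- init_som_map(4, x, seed = 2)
  expect_equal(dim(m$weights), c(16, 3))
  expect_true(all(m$weights[, 2] == 7))
  expect_true(all(m$weights[, 1] >= min(x[, 1]) & m$weights[, 1] <= max(x[, 1])))
  expect_identical(m$weights, init_som_map(4, x, seed = 2)$weights)

  big <- init_som_map(8, matrix(rnorm(10 * 48), 10, 48), seed = 1)
  expect_equal(dim(big$weights), c(64, 48))     # 8 x 8 neurons, D = 48
  # row-major index <-> lattice bijection
  expect_equal(big$grid[1, ], c(row = 1, col = 1))
  expect_equal(big$grid[9, ], c(row = 2, col = 1))
  expect_false(anyDuplicated(big$grid) > 0)

  expect_error(init_som_map(4, matrix(numeric(0), 0, 3)), "cannot initialize")
})

test_that("Euclidean distance matches the elementwise oracle", {
  expect_equal(som_distance(c(3, 4), c(0, 0)), 5)
  expect_equal(som_distance(1:5, 1:5), 0)
  expect_error(som_distance(1:3, 1:4), "dimension mismatch")
  withr::with_seed(42, {
    for (i in 1:100) {
      x <- rnorm(48); m <- rnorm(48)
      expect_equal(som_distance(x, m), oracle_distance(x, m),
                   tolerance = 1e-12)
    }
  })
})

test_that("winner search is an exhaustive enabled argmin with lowest-index ties", {
  W <- matrix(5, 20, 4)
  W[17, ] <- c(1, 2, 3, 4)
  map <- structure(list(weights = W,
                        grid = cbind(rep(1:4, each = 5), rep(1:5, 4)),
                        M = NA, D = 4), class = "som_map")
  expect_equal(find_winner(c(1, 2, 3, 4), map), 17)

  W2 <- matrix(10, 10, 2)
  W2[3, ] <- c(1, 1); W2[9, ] <- c(1, 1)        # equidistant pair
  map2 <- structure(list(weights = W2, grid = cbind(1:10, 1), M = NA, D = 2),
                    class = "som_map")
  expect_equal(find_winner(c(0, 0), map2), 3)

  expect_error(find_winner(c(0, 0), map2, enabled = rep(FALSE, 10)),
               "no enabled neurons")

  withr::with_seed(7, {
    for (i in 1:50) {
      m <- init_som_map(4, matrix(rnorm(30 * 6), 30, 6), seed = i)
      x <- rnorm(6)
      enabled <- runif(16) > 0.3
      if (!any(enabled)) enabled[1] <- TRUE
      expect_identical(find_winner(x, m, enabled),
                       oracle_winner(x, m$weights, enabled))
    }
  })
})

test_that("neighborhood gain is the Gaussian of squared grid distance", {
  grid <- cbind(rep(1:3, each = 3), rep(1:3, 3))
  expect_equal(neighborhood_gain(5, 5, 0.4, 2, grid), 0.4)   # h(C,C) = alpha
  # ||r5 - r6||^2 = 1... pick indices two apart: r5=(2,2), r3=(1,3): d2 = 2
  expect_equal(neighborhood_gain(5, 3, 0.5, 1, grid), 0.5 * exp(-2),
               tolerance = 1e-12)
  h <- neighborhood_gain(1, 1:9, 0.3, 1.5, grid)
  d2 <- rowSums(sweep(grid, 2, grid[1, ])^2)
  expect_true(all(diff(h[order(d2)]) <= 0))                  # monotone decay
  expect_true(all(h > 0 & h <= 0.3))
  expect_error(neighborhood_gain(1, 2, 0.5, 0, grid), "invalid radius")
})

test_that("weight update is the convex move toward the input", {
  m <- init_som_map(3, matrix(rnorm(20 * 5), 20, 5), seed = 3)
  x <- rnorm(5)

  # h = 1 forced at the winner: weight snaps to x exactly
  up <- update_weights(m, x, C = 4, alpha_t = 1, sigma_t = 1)
  expect_equal(up$weights[4, ], x, ignore_attr = TRUE)

  # alpha -> 0: map unchanged
  up0 <- update_weights(m, x, C = 4, alpha_t = 1e-15, sigma_t = 1)
  expect_equal(up0$weights, m$weights, tolerance = 1e-12)

  # convexity: every component lies between old weight and input
  up2 <- update_weights(m, x, C = 2, alpha_t = 0.7, sigma_t = 2)
  xm <- matrix(x, nrow(m$weights), 5, byrow = TRUE)
  expect_true(all(up2$weights >= pmin(m$weights, xm) - 1e-12))
  expect_true(all(up2$weights <= pmax(m$weights, xm) + 1e-12))
  # distance to x never increases
  d_old <- apply(m$weights, 1, oracle_distance, x)
  d_new <- apply(up2$weights, 1, oracle_distance, x)
  expect_true(all(d_new <= d_old + 1e-12))
})

test_that("weight update matches the scalar-loop oracle on random instances", {
  withr::with_seed(11, {
    for (i in 1:100) {
      m <- init_som_map(3, matrix(rnorm(15 * 4), 15, 4), seed = i)
      x <- rnorm(4)
      C <- sample.int(9, 1)
      a <- runif(1, 0.01, 1); s <- runif(1, 0.3, 3)
      expect_equal(update_weights(m, x, C, a, s)$weights,
                   oracle_update(m$weights, x, C, a, s, m$grid),
                   tolerance = 1e-12)
    }
  })
})

test_that("training contracts onto a single training vector", {
  x <- matrix(c(0.3, -1.2, 5, 2), 1, 4)
  map <- train_som(x, M = 3, schedule = som_schedule(epochs = 50, seed = 1))
  C <- find_winner(x[1, ], map)
  expect_lt(som_distance(x[1, ], map$weights[C, ]), 1e-6)
})

test_that("training reduces quantization error on two-cluster data", {
  for (s in 1:10) {
    d <- two_cluster_data(seed = s)
    sched <- som_schedule(epochs = 30, seed = s)
    seeds <- withr::with_seed(s, sample.int(2^31 - 2, 1))  # any init seed
    before <- quantization_error(init_som_map(4, d$x, seed = seeds), d$x)
    after <- quantization_error(train_som(d$x, M = 4, schedule = sched), d$x)
    expect_lt(after, before)
  }
})

test_that("training is deterministic and keeps weights inside the data range", {
  d <- two_cluster_data(seed = 4)
  sched <- som_schedule(epochs = 20, seed = 9)
  m1 <- train_som(d$x, M = 4, schedule = sched)
  m2 <- train_som(d$x, M = 4, schedule = sched)
  expect_identical(m1$weights, m2$weights)

  lo <- apply(d$x, 2, min); hi <- apply(d$x, 2, max)
  expect_true(all(sweep(m1$weights, 2, lo, `-`) >= -1e-9))
  expect_true(all(sweep(m1$weights, 2, hi, `-`) <= 1e-9))
})

test_that("schedule validation enforces the admissible ranges", {
  expect_error(som_schedule(alpha0 = 1.5), "alpha")
  expect_error(som_schedule(alpha_final = 0), "alpha")
  expect_error(som_schedule(epochs = 0), "epochs")
  expect_error(som_schedule(sigma0 = 0.2, sigma_final = 0.5), "sigma")
})
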