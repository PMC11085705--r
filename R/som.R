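#' SOM training schedule
#'
#' Hyperparameters of the competitive-learning phase. The learning rate
#' `alpha` and neighborhood radius `sigma` are interpolated over the
#' total number of vector presentations (epochs x training-set size),
#' i.e. the schedule clock ticks per presentation, not per epoch.
#'
#' Defaults follow conventional Kohonen practice: linear decay of alpha
#' from 0.5 to 0.01 and of sigma from half the grid side to 0.5, over
#' 100 epochs.
#'
#' @param epochs number of passes over the training set.
#' @param alpha0,alpha_final initial and final learning rate,
#'   `0 < alpha_final <= alpha0 <= 1`.
#' @param sigma0,sigma_final initial and final neighborhood radius (grid
#'   units); `sigma0 = NULL` means `M/2`, resolved at training time.
#' @param decay `"linear"` or `"exponential"` interpolation.
#' @param seed integer seed driving weight initialization and the
#'   per-epoch presentation shuffle.
#' @return an object of class `"som_schedule"`.
#' @export
som_schedule <- function(epochs = 100, alpha0 = 0.5, alpha_final = 0.01,
                         sigma0 = NULL, sigma_final = 0.5,
                         decay = c("linear", "exponential"), seed = 1L) {
  decay <- match.arg(decay)
  if (epochs < 1) stop("epochs must be at least 1")
  if (!(alpha_final > 0 && alpha_final <= alpha0 && alpha0 <= 1))
    stop("require 0 < alpha_final <= alpha0 <= 1")
  if (!is.null(sigma0) && !(sigma_final > 0 && sigma_final <= sigma0))
    stop("require 0 < sigma_final <= sigma0")
  structure(list(epochs = as.integer(epochs), alpha0 = alpha0,
                 alpha_final = alpha_final, sigma0 = sigma0,
                 sigma_final = sigma_final, decay = decay,
                 seed = as.integer(seed)),
            class = "som_schedule")
}

# alpha(t) / sigma(t) at presentation t (0-based) of total_t presentations.
schedule_at <- function(v0, v1, t, total_t, decay) {
  frac <- if (total_t <= 1) 1 else t / (total_t - 1)
  switch(decay,
         linear = v0 + (v1 - v0) * frac,
         exponential = v0 * (v1 / v0)^frac)
}

#' Initialize a SOM weight map
#'
#' Creates an `M x M` grid of `D`-dimensional weight vectors, each
#' component drawn uniformly within the per-dimension range of the
#' training data. Neuron `k` (1-based, row-major) sits at grid location
#' `r_k = (row, col)`.
#'
#' @param M grid side.
#' @param x training feature matrix (rows = vectors) supplying the
#'   per-dimension ranges.
#' @param seed integer seed.
#' @return an object of class `"som_map"`: list with `weights`
#'   (`M^2 x D`), `grid` (`M^2 x 2` integer lattice coordinates), `M`,
#'   `D`.
#' @export
init_som_map <- function(M, x, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot initialize: empty training set")
  if (M < 1) stop("M must be at least 1")
  D <- ncol(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  n <- as.integer(M)^2
  W <- withr::with_seed(as.integer(seed), {
    u <- matrix(stats::runif(n * D), n, D)
    sweep(u, 2, hi - lo, "*") + rep(lo, each = n)
  })
  colnames(W) <- colnames(x)
  k <- seq_len(n) - 1L
  grid <- cbind(row = k %/% M + 1L, col = k %% M + 1L)
  structure(list(weights = W, grid = grid, M = as.integer(M), D = D),
            class = "som_map")
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("<som_map> %d x %d neurons, D = %d\n", x$M, x$M, x$D))
  invisible(x)
}

#' Euclidean distance between a feature vector and a weight vector
#'
#' @param x,m numeric vectors of equal length.
#' @return non-negative scalar `sqrt(sum((x - m)^2))`.
#' @export
som_distance <- function(x, m) {
  if (length(x) != length(m)) stop("dimension mismatch")
  sqrt(sum((x - m)^2))
}

#' Winner (best-matching unit) search
#'
#' Returns the index of the enabled neuron whose weight vector is
#' nearest to `x` in Euclidean distance; ties are broken by the lowest
#' neuron index. During recall, disabled neurons (never associated with
#' a class) are excluded via the mask.
#'
#' @param x feature vector.
#' @param map a `"som_map"`.
#' @param enabled logical mask over neurons; `NULL` means all enabled.
#' @return integer neuron index.
#' @export
find_winner <- function(x, map, enabled = NULL) {
  if (length(x) != map$D) stop("dimension mismatch")
  if (is.null(enabled)) enabled <- rep(TRUE, nrow(map$weights))
  if (!any(enabled)) stop("no enabled neurons")
  d2 <- rowSums((map$weights - rep(as.numeric(x), each = nrow(map$weights)))^2)
  d2[!enabled] <- Inf
  which.min(d2)                       # first minimum = lowest index
}

#' Gaussian neighborhood function
#'
#' The per-neuron update gain
#' `h_Ck = alpha_t * exp(-||r_C - r_k||^2 / sigma_t^2)`: maximal (equal
#' to `alpha_t`) at the winner and decaying with squared grid distance.
#' No cutoff radius is applied — every neuron receives a positive gain.
#'
#' @param C winner neuron index.
#' @param k neuron index (may be a vector).
#' @param alpha_t learning rate at the current step.
#' @param sigma_t neighborhood radius at the current step; must be > 0.
#' @param grid integer lattice coordinates as in a `"som_map"`.
#' @return numeric gain(s) in `(0, alpha_t]`.
#' @export
neighborhood_gain <- function(C, k, alpha_t, sigma_t, grid) {
  if (sigma_t <= 0) stop("invalid radius")
  d2 <- (grid[k, 1] - grid[C, 1])^2 + (grid[k, 2] - grid[C, 2])^2
  alpha_t * exp(-d2 / sigma_t^2)
}

#' One SOM weight update
#'
#' Moves every neuron toward the input by its neighborhood gain:
#' `m_k(t+1) = m_k(t) + h_Ck * (x - m_k(t))`. Each updated component is
#' a convex combination of its old value and the input component, so no
#' weight can overshoot the input.
#'
#' @param map a `"som_map"`.
#' @param x input feature vector.
#' @param C winner index.
#' @param alpha_t,sigma_t schedule values at the current step.
#' @return the updated `"som_map"`.
#' @export
update_weights <- function(map, x, C, alpha_t, sigma_t) {
  if (length(x) != map$D) stop("dimension mismatch")
  h <- neighborhood_gain(C, seq_len(nrow(map$weights)), alpha_t, sigma_t,
                         map$grid)
  X <- rep(as.numeric(x), each = nrow(map$weights))
  map$weights <- map$weights + h * (X - map$weights)
  map
}

#' Train a self-organizing map
#'
#' The competitive-learning phase: for each of `schedule$epochs` passes,
#' the training vectors are presented in a freshly shuffled (seeded)
#' order; each presentation runs a winner search over all neurons
#' followed by the neighborhood weight update, with `alpha` and `sigma`
#' interpolated per presentation. Fully deterministic given
#' `(x, M, schedule)`.
#'
#' @param x training feature matrix (rows = vectors).
#' @param M grid side (default 8, i.e. 64 neurons).
#' @param schedule a [som_schedule()].
#' @return the trained `"som_map"`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' map <- train_som(x, M = 3, schedule = som_schedule(epochs = 10))
#' @export
train_som <- function(x, M = 8, schedule = som_schedule()) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot initialize: empty training set")
  sigma0 <- if (is.null(schedule$sigma0)) M / 2 else schedule$sigma0
  if (!(schedule$sigma_final > 0 && schedule$sigma_final <= sigma0))
    stop("require 0 < sigma_final <= sigma0")
  seeds <- derive_seeds(schedule$seed, 2)
  map <- init_som_map(M, x, seed = seeds[1])
  n <- nrow(x)
  total_t <- schedule$epochs * n
  t <- 0L
  withr::with_seed(seeds[2], {
    for (e in seq_len(schedule$epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        a <- schedule_at(schedule$alpha0, schedule$alpha_final, t, total_t,
                         schedule$decay)
        s <- schedule_at(sigma0, schedule$sigma_final, t, total_t,
                         schedule$decay)
        C <- find_winner(x[i, ], map)
        map <- update_weights(map, x[i, ], C, a, s)
        t <- t + 1L
      }
    }
  })
  map
}

#' Mean quantization error
#'
#' Mean Euclidean distance from each vector to its winning neuron; a
#' standard map-quality measure that training should reduce.
#'
#' @param map a `"som_map"`.
#' @param x feature matrix.
#' @param enabled optional logical mask over neurons.
#' @return non-negative scalar.
#' @export
quantization_error <- function(map, x, enabled = NULL) {
  x <- as.matrix(x)
  mean(vapply(seq_len(nrow(x)), function(i) {
    C <- find_winner(x[i, ], map, enabled)
    som_distance(x[i, ], map$weights[C, ])
  }, numeric(1)))
}
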