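#' EEG segment container
#'
#' A fixed-rate multichannel EEG recording, the unit of acquisition and
#' simulation: by default 16 channels sampled at 125 Hz for 2 s
#' (250 samples per channel).
#'
#' @param samples numeric matrix, channels x time.
#' @param sample_rate sampling rate in Hz.
#' @param label optional gesture class the segment belongs to.
#' @return an object of class `"eeg_segment"` with fields `samples`,
#'   `sample_rate`, `channel_ids`, `label`.
#' @export
eeg_segment <- function(samples, sample_rate = 125, label = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("samples must be a finite numeric matrix")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("invalid geometry: sample_rate must be a positive scalar")
  rownames(samples) <- paste0("ch", seq_len(nrow(samples)))
  structure(list(samples = samples,
                 sample_rate = as.numeric(sample_rate),
                 channel_ids = seq_len(nrow(samples)),
                 label = label),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz (%.3g s)%s\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

# Band-pass white noise by zeroing FFT bins outside [lo, hi] Hz.
bandpass_noise <- function(n, sd, lo, hi, sample_rate) {
  z <- stats::rnorm(n, sd = sd)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)               # fold to physical frequency
  keep <- f >= lo & f <= hi
  zf <- stats::fft(z)
  zf[!keep] <- 0
  Re(stats::fft(zf, inverse = TRUE)) / n
}

#' Simulate one gesture EEG segment
#'
#' Generates a labeled multichannel segment whose band-power structure
#' follows the gesture's signature. Each channel is a sum of three
#' band-limited oscillations — one random-phase sinusoid per band, with
#' frequency drawn uniformly within the band (alpha 8-13, beta 14-30,
#' theta 4-7 Hz) — scaled by the signature's amplitude multipliers, plus
#' band-passed (14-30 Hz) white EMG-like noise on the signature's EMG
#' channels, plus white Gaussian background noise. A unit multiplier
#' yields an expected band power of 1/2 (sinusoid power A^2/2), which
#' gives closed-form expectations for every feature.
#'
#' Output is fully determined by `(gesture, parameters, seed)`.
#'
#' @param gesture gesture id, one of `names(signatures)`.
#' @param signatures named list of [gesture_signature()] objects.
#' @param duration segment length in seconds.
#' @param sample_rate sampling rate in Hz; must exceed twice the highest
#'   synthesized frequency (30 Hz).
#' @param noise_sd standard deviation of the white background noise.
#' @param seed integer seed.
#' @return an [eeg_segment()] with `label = gesture`.
#' @examples
#' seg <- simulate_gesture("G2", seed = 1)
#' seg
#' @export
simulate_gesture <- function(gesture, signatures = default_signatures(),
                             duration = 2, sample_rate = 125,
                             noise_sd = 2, seed = 1) {
  if (!is.character(gesture) || length(gesture) != 1 ||
      !gesture %in% names(signatures))
    stopf("unknown class: '%s'", as.character(gesture)[1])
  if (!is.numeric(duration) || duration <= 0 ||
      !is.numeric(sample_rate) || sample_rate <= 0)
    stop("invalid geometry: duration and sample_rate must be positive")
  bands <- eeg_bands()
  if (sample_rate <= 2 * max(bands$hi))
    stop("invalid geometry: sample_rate below twice the highest band edge")
  if (noise_sd < 0) stop("noise_sd must be non-negative")

  sig <- signatures[[gesture]]
  mult <- sig$multipliers
  n_ch <- nrow(mult)
  n_t <- round(duration * sample_rate)
  tt <- (seq_len(n_t) - 1) / sample_rate

  withr::with_seed(as.integer(seed), {
    freqs <- matrix(stats::runif(n_ch * 3, rep(bands$lo, each = n_ch),
                                 rep(bands$hi, each = n_ch)), n_ch, 3)
    phases <- matrix(stats::runif(n_ch * 3, 0, 2 * pi), n_ch, 3)
    x <- matrix(0, n_ch, n_t)
    for (b in 1:3) {
      # one sinusoid per band per channel; amplitude = signature multiplier
      arg <- outer(2 * pi * freqs[, b], tt) + phases[, b]
      x <- x + mult[, b] * sin(arg)
    }
    if (length(sig$emg_channels) && sig$emg_gain > 0) {
      for (ch in sig$emg_channels)
        x[ch, ] <- x[ch, ] + bandpass_noise(n_t, sig$emg_gain, 14, 30,
                                            sample_rate)
    }
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(n_ch * n_t, sd = noise_sd), n_ch, n_t)
    eeg_segment(x, sample_rate = sample_rate, label = gesture)
  })
}

#' Simulate a labeled gesture dataset
#'
#' Generates `n_per_class` segments for each requested class, emulating
#' the offline acquisition protocol (30 two-second recordings per gesture;
#' 7 classes x 30 gives the 210-vector training set). Per-segment seeds
#' are derived deterministically from the master seed, so the whole
#' dataset is reproducible from `(classes, n_per_class, seed)`.
#'
#' @param classes character vector of gesture ids (no duplicates).
#' @param n_per_class segments per class, at least 1.
#' @param seed master integer seed.
#' @param ... further arguments passed to [simulate_gesture()]
#'   (`signatures`, `duration`, `sample_rate`, `noise_sd`).
#' @return list of labeled [eeg_segment()] objects, grouped by class in
#'   the order of `classes`.
#' @examples
#' segs <- simulate_gesture_dataset(gesture_classes(2), n_per_class = 3, seed = 7)
#' sapply(segs, function(s) s$label)
#' @export
simulate_gesture_dataset <- function(classes = gesture_classes(),
                                     n_per_class = 30, seed = 1, ...) {
  if (length(classes) == 0) stop("classes must be non-empty")
  if (anyDuplicated(classes)) stop("duplicate class")
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("n_per_class must be at least 1")
  n_per_class <- as.integer(n_per_class)
  seeds <- derive_seeds(seed, length(classes) * n_per_class)
  out <- vector("list", length(classes) * n_per_class)
  i <- 0L
  for (cl in classes) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      out[[i]] <- simulate_gesture(cl, seed = seeds[i], ...)
    }
  }
  out
}

#' Labels of a segment list
#'
#' @param segments list of [eeg_segment()] objects.
#' @return character vector of labels (`NA` where unlabeled).
#' @export
segment_labels <- function(segments) {
  vapply(segments, function(s) {
    if (is.null(s$label)) NA_character_ else as.character(s$label)
  }, character(1))
}
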