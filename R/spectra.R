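#' Canonical EEG frequency bands
#'
#' The three bands whose per-channel powers form the feature vector:
#' alpha 8-13 Hz, beta 14-30 Hz, theta 4-7 Hz. The row order (alpha,
#' beta, theta) is the block order of the feature vector layout. The
#' delta band is deliberately absent: its cycles are too slow to measure
#' reliably in a 2 s window.
#'
#' @return data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(band = c("alpha", "beta", "theta"),
             lo = c(8, 14, 4),
             hi = c(13, 30, 7))
}

#' Welch power spectral density of an EEG segment
#'
#' Averaged Hann-windowed periodograms (Welch's method): the segment is
#' split into overlapping windows, each window is Hann-tapered and its
#' one-sided periodogram computed, and the periodograms are averaged per
#' channel. The density is scaled so that its integral over the full
#' frequency grid approximates the channel's mean squared amplitude
#' (Parseval). With the defaults (1 s window, 50% overlap) a 2 s segment
#' at 125 Hz yields three averaged windows on a 1 Hz grid.
#'
#' @param segment an [eeg_segment()].
#' @param window_length window length in seconds; must not exceed the
#'   segment duration.
#' @param overlap_fraction fractional overlap between consecutive
#'   windows, in `[0, 1)`.
#' @return an object of class `"eeg_psd"`: list with `freq` (Hz grid
#'   from 0 to Nyquist) and `power` (channels x frequencies density
#'   matrix, units amplitude^2/Hz).
#' @examples
#' seg <- simulate_gesture("G1", noise_sd = 0, seed = 1)
#' psd <- power_spectrum(seg)
#' dim(psd$power)
#' @export
power_spectrum <- function(segment, window_length = 1, overlap_fraction = 0.5) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  fs <- segment$sample_rate
  x <- segment$samples
  n_t <- ncol(x)
  n_win <- round(window_length * fs)
  if (n_win < 2 || n_win > n_t)
    stop("segment too short for the requested window length")

  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n_win) - 1) / (n_win - 1)))  # Hann
  step <- max(1L, floor(n_win * (1 - overlap_fraction)))
  starts <- seq(1L, n_t - n_win + 1L, by = step)

  n_f <- floor(n_win / 2) + 1L
  acc <- matrix(0, nrow(x), n_f)
  for (s in starts) {
    seg <- x[, s:(s + n_win - 1L), drop = FALSE] * rep(w, each = nrow(x))
    X <- stats::mvfft(t(seg))                 # columns = channels
    p <- (Mod(X[seq_len(n_f), , drop = FALSE])^2) / (fs * sum(w^2))
    # one-sided: double everything except DC (and Nyquist when n even)
    dbl <- rep(2, n_f); dbl[1] <- 1
    if (n_win %% 2 == 0) dbl[n_f] <- 1
    acc <- acc + t(p) * rep(dbl, each = nrow(x))
  }
  power <- acc / length(starts)
  rownames(power) <- rownames(x)
  structure(list(freq = (seq_len(n_f) - 1) * fs / n_win,
                 power = power,
                 sample_rate = fs,
                 window_length = window_length,
                 overlap_fraction = overlap_fraction),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d channels, %d frequency bins (0-%g Hz, df = %g Hz)\n",
              nrow(x$power), length(x$freq), max(x$freq),
              x$freq[2] - x$freq[1]))
  invisible(x)
}

#' Band power from a spectral density
#'
#' Integrates the density over a frequency band: trapezoidal rule over
#' the bins whose centers fall in the closed interval `[lo, hi]`. At the
#' default 1 Hz resolution the alpha/beta (13 vs 14 Hz) and theta/alpha
#' (7 vs 8 Hz) boundaries put no bin in two bands.
#'
#' @param psd an `"eeg_psd"` from [power_spectrum()].
#' @param band either a length-2 numeric `c(lo, hi)` in Hz or a one-row
#'   slice of [eeg_bands()].
#' @return named numeric vector of per-channel band power
#'   (amplitude^2 units).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (is.data.frame(band)) band <- c(band$lo[1], band$hi[1])
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be c(lo, hi) with lo < hi")
  if (band[2] > psd$sample_rate / 2)
    stop("band exceeds the Nyquist frequency")
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(sel) < 2)
    stop("band unresolved at this resolution")
  apply(psd$power[, sel, drop = FALSE], 1,
        function(p) pracma::trapz(psd$freq[sel], p))
}

#' Band-power feature vector
#'
#' Converts segments into the feature representation the classifier
#' consumes: for each band (alpha, beta, theta) and each channel, the
#' integrated band power. The layout is band-major, channel-ascending —
#' alpha ch1..chN, beta ch1..chN, theta ch1..chN — giving D = 3 x 16 = 48
#' for the default headset.
#'
#' @param x an [eeg_segment()] or a list of them.
#' @param bands band table as from [eeg_bands()].
#' @param window_length,overlap_fraction passed to [power_spectrum()].
#' @param normalize if `TRUE`, z-score each feature across segments
#'   (list input only; off by default — raw absolute powers are the
#'   canonical features).
#' @return for a single segment, a named numeric vector of length
#'   `3 * channels` with attribute `"label"`; for a list, a matrix with
#'   one row per segment and attribute `"labels"`.
#' @examples
#' seg <- simulate_gesture("G2", seed = 1)
#' length(band_features(seg))   # 48
#' @export
band_features <- function(x, bands = eeg_bands(), window_length = 1,
                          overlap_fraction = 0.5, normalize = FALSE) {
  if (inherits(x, "eeg_segment")) {
    psd <- power_spectrum(x, window_length, overlap_fraction)
    feats <- unlist(lapply(seq_len(nrow(bands)), function(b) {
      p <- band_power(psd, bands[b, ])
      names(p) <- paste0(bands$band[b], ".", names(p))
      p
    }))
    attr(feats, "label") <- if (is.null(x$label)) NA_character_ else
      as.character(x$label)
    return(feats)
  }
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "eeg_segment")))
    stop("x must be an eeg_segment or a list of eeg_segments")
  rows <- lapply(x, band_features, bands = bands,
                 window_length = window_length,
                 overlap_fraction = overlap_fraction)
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- names(rows[[1]])[seq_len(ncol(m))]
  if (normalize) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    sd[sd == 0] <- 1
    m <- sweep(sweep(m, 2, mu), 2, sd, "/")
  }
  attr(m, "labels") <- segment_labels(x)
  m
}
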