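#' Facial gesture classes
#'
#' The seven facial gestures the classifier distinguishes. Gestures are
#' combinations of facial movements chosen because each leaves a strong,
#' spatially distinct artifact in the EEG: eye closure raises posterior
#' alpha power, eye widening raises frontal power, and clenching the left
#' or right teeth injects broadband EMG into the temporal electrode on
#' that side.
#'
#' Experiments use prefix subsets of the ordered list: the two-gesture
#' task is (G1, G2), the four-gesture task (G1..G4), and so on.
#'
#' @param n number of classes, between 1 and 7; the first `n` gestures of
#'   the ordered list are returned.
#' @return character vector of gesture ids (`"G1"` ... ).
#' @seealso [gesture_descriptions()], [default_signatures()]
#' @examples
#' gesture_classes()
#' gesture_classes(4)
#' @export
gesture_classes <- function(n = 7) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n > 7 || n != round(n))
    stop("unknown class: 'n' must be an integer in 1..7")
  paste0("G", seq_len(n))
}

#' @rdname gesture_classes
#' @return for `gesture_descriptions()`, a named character vector mapping
#'   gesture id to a human-readable description.
#' @export
gesture_descriptions <- function() {
  c(G1 = "open eyes",
    G2 = "close eyes",
    G3 = "open eyes and clench right teeth",
    G4 = "open eyes and clench left teeth",
    G5 = "open eyes wide",
    G6 = "close eyes and clench right teeth",
    G7 = "close eyes and clench left teeth")
}

#' Electrode role map
#'
#' Which channels of the 16-electrode montage play which role in the
#' gesture signatures. Only the relative roles matter to the method, so
#' the map is configuration rather than hard-coded: the temporal
#' electrodes 13 (left) and 14 (right) pick up teeth-clench EMG, the
#' posterior pair carries the closed-eye alpha rise, and the frontal pair
#' responds to eye widening.
#'
#' @return named list of integer channel indices with elements `frontal`,
#'   `posterior`, `left_temporal`, `right_temporal`.
#' @export
channel_roles <- function() {
  list(frontal = 1:2,
       posterior = 7:8,
       left_temporal = 13L,
       right_temporal = 14L)
}

#' Construct a gesture signature
#'
#' A signature describes how one gesture modulates the background EEG: a
#' per-channel, per-band amplitude multiplier matrix for the oscillatory
#' part, plus an optional set of channels receiving broadband EMG-like
#' noise with a given gain. The all-ones signature with zero EMG gain is
#' the unmodulated background.
#'
#' @param multipliers non-negative numeric matrix, channels x 3 bands
#'   (columns alpha, beta, theta).
#' @param emg_channels integer channel indices receiving band-passed
#'   EMG-like noise.
#' @param emg_gain non-negative standard deviation of the EMG noise before
#'   band-passing.
#' @param channels number of channels when `multipliers` is omitted.
#' @return an object of class `"gesture_signature"`.
#' @export
gesture_signature <- function(multipliers = NULL, emg_channels = integer(),
                              emg_gain = 0, channels = 16) {
  if (is.null(multipliers))
    multipliers <- matrix(1, channels, 3)
  multipliers <- as.matrix(multipliers)
  if (ncol(multipliers) != 3)
    stop("signature multipliers must have 3 band columns (alpha, beta, theta)")
  if (any(!is.finite(multipliers)) || any(multipliers < 0))
    stop("signature multipliers must be finite and non-negative")
  colnames(multipliers) <- c("alpha", "beta", "theta")
  rownames(multipliers) <- paste0("ch", seq_len(nrow(multipliers)))
  emg_channels <- as.integer(emg_channels)
  if (length(emg_channels) &&
      (any(emg_channels < 1) || any(emg_channels > nrow(multipliers))))
    stop("emg_channels out of range")
  if (!is.numeric(emg_gain) || length(emg_gain) != 1 || emg_gain < 0 ||
      !is.finite(emg_gain))
    stop("emg_gain must be a non-negative finite scalar")
  structure(list(multipliers = multipliers,
                 emg_channels = emg_channels,
                 emg_gain = emg_gain),
            class = "gesture_signature")
}

#' Default gesture signature model
#'
#' The built-in signature set encodes the qualitative artifact structure
#' the gestures produce: closed-eye gestures (G2, G6, G7) multiply alpha
#' amplitude on the posterior channels, eye widening (G5) multiplies all
#' bands on the frontal channels, and teeth clenching (G3/G6 right,
#' G4/G7 left) adds band-passed broadband EMG noise on the corresponding
#' temporal electrode. G1 (open eyes, relaxed) is the unmodulated
#' background.
#'
#' G5 additionally elevates the temporal electrodes: the region affected
#' by eye widening lies near electrodes 13 and 14, which is why that
#' gesture tends to be misrecognised as a clench gesture.
#'
#' Effect sizes are free parameters of the simulation (only orderings are
#' dictated by the physiology); the defaults give artifact effects that
#' dominate the background, which is what makes these particular gestures
#' detectable in the first place.
#'
#' @param alpha_gain amplitude multiplier for posterior alpha with closed
#'   eyes (power scales with its square).
#' @param frontal_gain amplitude multiplier for all bands on frontal
#'   channels with eyes wide open.
#' @param spread_gain amplitude multiplier on the temporal electrodes for
#'   eye widening: the frontal muscle activity spills over to the region
#'   near electrodes 13/14, which is what makes this gesture confusable
#'   with the clench gestures.
#' @param emg_gain standard deviation of the EMG-like noise injected on
#'   the clench-side temporal electrode.
#' @param roles electrode role map, see [channel_roles()].
#' @param channels number of channels.
#' @return named list of [gesture_signature()] objects, one per gesture
#'   `G1`..`G7`.
#' @examples
#' sig <- default_signatures()
#' sig$G2$multipliers[7:8, "alpha"]   # posterior alpha raised when eyes close
#' @export
default_signatures <- function(alpha_gain = 3, frontal_gain = 2.5,
                               spread_gain = 1.6, emg_gain = 3,
                               roles = channel_roles(), channels = 16) {
  base <- function() matrix(1, channels, 3,
                            dimnames = list(NULL, c("alpha", "beta", "theta")))
  closed <- function() {
    m <- base()
    m[roles$posterior, "alpha"] <- alpha_gain
    m
  }
  wide <- function() {
    m <- base()
    m[roles$frontal, ] <- frontal_gain
    m[c(roles$left_temporal, roles$right_temporal), ] <- spread_gain
    m
  }
  list(
    G1 = gesture_signature(base()),
    G2 = gesture_signature(closed()),
    G3 = gesture_signature(base(), emg_channels = roles$right_temporal,
                           emg_gain = emg_gain),
    G4 = gesture_signature(base(), emg_channels = roles$left_temporal,
                           emg_gain = emg_gain),
    G5 = gesture_signature(wide()),
    G6 = gesture_signature(closed(), emg_channels = roles$right_temporal,
                           emg_gain = emg_gain),
    G7 = gesture_signature(closed(), emg_channels = roles$left_temporal,
                           emg_gain = emg_gain)
  )
}
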