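# Preprocessing: band-pass filtering, windowed RMS envelopes, MVC
# estimation, contraction onset detection and segmentation.

#' Band-pass filter an EMG signal
#'
#' Applies a 2nd-order Butterworth band-pass (default 10-500 Hz). Offline
#' analysis uses zero-phase forward-backward filtering so that group delay
#' does not distort contraction onsets; `zero_phase = FALSE` gives the causal
#' single-pass variant used on streaming data.
#'
#' @param x numeric vector, channels-by-samples matrix, or `emg_recording`.
#' @param fs sampling rate (Hz); taken from the recording when `x` is one.
#'   Must exceed twice the upper band edge.
#' @param low,high band edges in Hz.
#' @param order filter order.
#' @param zero_phase forward-backward filtering (offline) if `TRUE`.
#' @return object of the same shape/class as `x`.
#' @export
bandpass <- function(x, fs = NULL, low = 10, high = 500, order = 2,
                     zero_phase = TRUE) {
  if (inherits(x, "emg_recording")) {
    x$signal <- bandpass(x$signal, x$fs, low, high, order, zero_phase)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for plain signals")
  if (fs <= 2 * high)
    stop("sampling rate (", fs, " Hz) must exceed twice the upper band edge (",
         high, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  run <- function(v) {
    if (zero_phase) signal::filtfilt(bf, v) else signal::filter(bf, v)
  }
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) x[i, ] <- run(x[i, ])
    x
  } else {
    run(as.numeric(x))
  }
}

#' Windowed RMS envelope
#'
#' Per-channel RMS over sliding windows (default 250 ms) plus the
#' channel-averaged envelope used as the muscle activation estimate.
#'
#' @param x channels-by-samples matrix (a vector is treated as one channel),
#'   or an `emg_recording`.
#' @param fs sampling rate (Hz), taken from the recording when applicable.
#' @param window_s window length in seconds.
#' @param hop_s hop between window starts in seconds (default half-window).
#' @return an object of class `emg_envelope`: list with `values`
#'   (channels x windows RMS), `mean` (channel-averaged), `time_s` (window
#'   start times), `window_s`, `hop_s`, `fs`.
#' @export
rms_envelope <- function(x, fs = NULL, window_s = 0.25, hop_s = window_s / 2) {
  if (inherits(x, "emg_recording")) {
    fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) stop("fs is required for plain signals")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  W <- round(window_s * fs)
  H <- max(1L, round(hop_s * fs))
  if (ncol(x) < W)
    stop("signal (", ncol(x), " samples) is shorter than one window (", W, ")")
  starts <- seq.int(1L, ncol(x) - W + 1L, by = H)
  vals <- vapply(starts, function(s) sqrt(rowMeans(x[, s:(s + W - 1L), drop = FALSE]^2)),
                 numeric(nrow(x)))
  vals <- matrix(vals, nrow = nrow(x))
  structure(list(values = vals, mean = colMeans(vals),
                 time_s = (starts - 1L) / fs, window_s = window_s,
                 hop_s = H / fs, fs = fs),
            class = "emg_envelope")
}

#' Estimate the maximum voluntary contraction (MVC) amplitude
#'
#' The MVC value of a 3-s sustained maximal contraction: RMS over 250-ms
#' windows, averaged across all channels and over the contraction period.
#'
#' @param rec an `emg_recording` (or channels-by-samples matrix with `fs`).
#' @param fs sampling rate, required for plain matrices.
#' @param window_s RMS window length (s).
#' @param contraction_s duration of the contraction period analysed (s); the
#'   recording must be at least this long.
#' @return scalar MVC amplitude (microvolt RMS).
#' @export
compute_mvc <- function(rec, fs = NULL, window_s = 0.25, contraction_s = 3) {
  if (inherits(rec, "emg_recording")) {
    fs <- rec$fs
    sig <- rec$signal
  } else {
    sig <- if (is.matrix(rec)) rec else matrix(rec, nrow = 1)
    if (is.null(fs)) stop("fs is required for plain signals")
  }
  n_need <- round(contraction_s * fs)
  if (ncol(sig) < n_need)
    stop("MVC recording must cover at least ", contraction_s, " s (got ",
         ncol(sig) / fs, " s)")
  env <- rms_envelope(sig[, seq_len(n_need), drop = FALSE], fs,
                      window_s = window_s, hop_s = window_s)
  mean(env$mean)
}

#' Detect the contraction onset in an activation envelope
#'
#' First window whose channel-averaged RMS reaches 10% of the MVC.
#'
#' @param envelope an `emg_envelope`, or a numeric vector taken as the
#'   channel-averaged envelope.
#' @param mvc MVC amplitude (same units as the envelope), must be positive.
#' @param threshold fraction of MVC defining the onset.
#' @return 1-based index of the first crossing window, or `NA_integer_` if
#'   the envelope never crosses the threshold.
#' @export
detect_onset <- function(envelope, mvc, threshold = 0.10) {
  stopifnot(mvc > 0)
  m <- if (inherits(envelope, "emg_envelope")) envelope$mean else as.numeric(envelope)
  i <- which(m >= threshold * mvc)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Segment a task recording into its contractions
#'
#' Non-rest task recordings follow the two-trapezoid profile and yield the
#' two supra-threshold contraction segments, delimited by the 10%-MVC onset
#' rule; the offset is the first window after which the envelope stays below
#' threshold for two consecutive windows (hysteresis against chatter). The
#' contraction levels of the two segments are assigned by order (first low,
#' second moderate), matching the profile design. Rest recordings yield one
#' 4-s segment.
#'
#' @param rec an `emg_recording`.
#' @param mvc MVC amplitude for the recording's gesture (microvolt RMS).
#' @param threshold onset threshold as a fraction of MVC.
#' @param window_s envelope window (s).
#' @param hop_s envelope hop (s); half-window by default.
#' @param rest_s duration of the rest segment (s).
#' @param rest_start_s start of the rest segment within the recording (s).
#' @return list of `emg_segment` objects: `signal` (channels x samples),
#'   `fs`, `label` (with `level` filled in: `"low"`, `"moderate"` or
#'   `"rest"`), `contraction`, and the parent `range` in samples.
#' @export
segment_contractions <- function(rec, mvc, threshold = 0.10,
                                 window_s = 0.25, hop_s = 0.125,
                                 rest_s = 4, rest_start_s = 1) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$fs
  if (rec$label$gesture == "RE") {
    from <- round(rest_start_s * fs) + 1L
    to <- from + round(rest_s * fs) - 1L
    if (to > ncol(rec$signal))
      stop("rest recording too short for a ", rest_s, "-s rest segment")
    lab <- rec$label
    lab$level <- "rest"
    return(list(structure(list(signal = rec$signal[, from:to, drop = FALSE],
                               fs = fs, label = lab, contraction = "rest",
                               range = c(from, to)),
                          class = "emg_segment")))
  }
  stopifnot(is.finite(mvc), mvc > 0)
  env <- rms_envelope(rec$signal, fs, window_s = window_s, hop_s = hop_s)
  supra <- env$mean >= threshold * mvc
  W <- round(window_s * fs)
  H <- round(hop_s * fs)
  nwin <- length(supra)
  segs <- list()
  i <- 1L
  while (i <= nwin && length(segs) < 2L) {
    if (!supra[i]) { i <- i + 1L; next }
    onset <- i
    j <- i
    # offset: first window after onset below threshold for 2 consecutive windows
    while (j < nwin && !(!supra[j] && j < nwin && !supra[j + 1L])) j <- j + 1L
    last_supra <- if (supra[j]) j else j - 1L
    while (last_supra > onset && !supra[last_supra]) last_supra <- last_supra - 1L
    from <- (onset - 1L) * H + 1L
    to <- min((last_supra - 1L) * H + W, ncol(rec$signal))
    lab <- rec$label
    lab$level <- if (length(segs) == 0L) "low" else "moderate"
    segs[[length(segs) + 1L]] <- structure(
      list(signal = rec$signal[, from:to, drop = FALSE], fs = fs, label = lab,
           contraction = length(segs) + 1L, range = c(from, to)),
      class = "emg_segment")
    i <- j + 2L
  }
  if (length(segs) < 2L)
    stop("expected two contractions in task '", rec$label$gesture, "/",
         rec$label$wrist, "' but found ", length(segs),
         " supra-threshold segment(s)")
  segs
}
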