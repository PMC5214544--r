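## Butterworth filtering and EMG envelope processing.

#' Low-pass Butterworth filter
#'
#' Zero-phase (bidirectional) low-pass filtering with unit DC gain; the
#' default settings (3rd order, 12 Hz) match the preprocessing applied to
#' force and kinematic data before inverse simulations.
#'
#' @param series numeric vector or matrix (filtered column-wise).
#' @param rate sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz), must be below the Nyquist rate.
#' @param order filter order (default 3).
#' @param bidirectional forward-backward filtering for zero phase lag
#'   (default TRUE).
#' @return filtered series, same shape as the input.
#' @export
lowpass_filter <- function(series, rate, cutoff = 12, order = 3L,
                           bidirectional = TRUE) {
  if (cutoff >= rate / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  apply_filter <- function(x) {
    if (bidirectional) {
      reflect_filtfilt(bf, x, npad = ceiling(8 * rate / cutoff))
    } else {
      as.numeric(signal::filter(bf, x))
    }
  }
  if (is.matrix(series)) apply(series, 2L, apply_filter)
  else apply_filter(as.numeric(series))
}

## zero-phase filtering with reflected-end padding long enough for the
## filter transient to die out (signal::filtfilt starts from zero state)
reflect_filtfilt <- function(bf, x, npad) {
  n <- length(x)
  npad <- min(n - 1L, as.integer(npad))
  if (npad < 1L) return(signal::filtfilt(bf, x))
  xp <- c(2 * x[1L] - rev(x[2:(npad + 1L)]), x,
          2 * x[n] - rev(x[(n - npad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1L):(npad + n)]
}

#' Band-pass Butterworth filter
#'
#' @inheritParams lowpass_filter
#' @param band length-2 vector of corner frequencies (Hz).
#' @return filtered series.
#' @export
bandpass_filter <- function(series, rate, band = c(10, 500), order = 2L,
                            bidirectional = TRUE) {
  if (band[2L] >= rate / 2) {
    stop("upper band edge (", band[2L],
         " Hz) must be below the Nyquist frequency (", rate / 2, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  run1 <- function(x) {
    if (bidirectional) reflect_filtfilt(bf, x,
                                        npad = ceiling(8 * rate / band[1L]))
    else as.numeric(signal::filter(bf, x))
  }
  if (is.matrix(series)) apply(series, 2L, run1) else run1(as.numeric(series))
}

## moving rectangular window mean with shrinking windows at the edges
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  cs <- cumsum(c(0, x))
  half <- n %/% 2L
  N <- length(x)
  i0 <- pmax(seq_len(N) - half, 1L)
  i1 <- pmin(seq_len(N) + (n - half - 1L), N)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

#' EMG envelope with MVC normalization
#'
#' Processing chain: band-pass 10-500 Hz (Butterworth order 2, zero phase),
#' full-wave rectification, 50-ms moving rectangular window, division by the
#' maximum-voluntary-contraction reference. Band-pass precedes rectification
#' so the rectified signal's low-frequency envelope content is preserved
#' (rectifying first and then band-passing above 10 Hz would remove the
#' envelope itself); the set of operations matches the published chain.
#' Envelope values above 1 are reported (not clipped) with a warning.
#'
#' @param raw raw EMG vector.
#' @param rate sampling rate (Hz); 2000 Hz or more recommended. Rates at or
#'   below 1000 Hz are rejected (500 Hz band edge at/above Nyquist).
#' @param mvc_reference positive normalization value (same units as `raw`
#'   after enveloping).
#' @param band band-pass corners (Hz).
#' @param window envelope window (s).
#' @return normalized envelope (same length as `raw`).
#' @export
emg_envelope <- function(raw, rate, mvc_reference, band = c(10, 500),
                         window = 0.050) {
  if (rate <= 2 * band[2L]) {
    stop("sampling rate ", rate, " Hz too low for a ", band[2L],
         " Hz band edge (Nyquist)", call. = FALSE)
  }
  if (mvc_reference <= 0) {
    stop("mvc_reference must be positive", call. = FALSE)
  }
  bp <- bandpass_filter(as.numeric(raw), rate, band = band, order = 2L,
                        bidirectional = TRUE)
  env <- moving_average(abs(bp), round(window * rate))
  out <- env / mvc_reference
  if (any(out > 1)) {
    warning(sum(out > 1), " envelope sample(s) exceed the MVC reference",
            call. = FALSE)
  }
  out
}

#' MVC reference from a maximal-contraction segment
#'
#' Convenience: the mean un-normalized envelope over a maximal-effort
#' recording, for use as `mvc_reference` in [emg_envelope()].
#'
#' @inheritParams emg_envelope
#' @return scalar reference value.
#' @export
mvc_reference <- function(raw, rate, band = c(10, 500), window = 0.050) {
  bp <- bandpass_filter(as.numeric(raw), rate, band = band, order = 2L,
                        bidirectional = TRUE)
  mean(moving_average(abs(bp), round(window * rate)))
}
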