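#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass (default 0.4–8 Hz, the
#' physiological PPG band: heart rate and its useful harmonics) forward and
#' backward (`signal::filtfilt`), so the filter is zero-phase and does not
#' distort the timing of the systolic/tidal/dicrotic landmarks that the
#' derivative channels depend on.
#'
#' @param wave A [waveform()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return A filtered [waveform()] of the same length.
#' @export
bandpass <- function(wave, low_hz = 0.4, high_hz = 8, order = 4) {
  stopifnot(inherits(wave, "waveform"))
  nyq <- fs_hz(wave) / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  bt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  rewave(signal::filtfilt(bt, as.numeric(wave)), wave)
}

#' Min–max normalisation to [0, 1]
#'
#' @param wave A non-constant [waveform()].
#' @return A [waveform()] with minimum 0 and maximum 1.
#' @export
normalize <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  r <- range(wave)
  if (diff(r) < .Machine$double.eps * max(1, abs(r[2]))) {
    stop("cannot normalize a constant signal", call. = FALSE)
  }
  rewave((as.numeric(wave) - r[1]) / diff(r), wave, units = "normalized")
}

#' Split a record into consecutive fixed-length segments
#'
#' Non-overlapping consecutive segments of `seg_s` seconds; a trailing
#' partial segment is discarded.
#'
#' @param wave A [waveform()] at least one segment long.
#' @param seg_s Segment duration in seconds (default 5).
#' @return A tibble with columns `segment` (index), `start_index` (1-based
#'   offset in the parent record) and list-column `wave`.
#' @examples
#' w <- waveform(sin(seq(0, 20 * pi, length.out = 1250)), fs_hz = 125)
#' segment_record(w) # two 625-sample segments
#' @export
segment_record <- function(wave, seg_s = 5) {
  stopifnot(inherits(wave, "waveform"))
  n_seg <- round(seg_s * fs_hz(wave))
  k <- length(wave) %/% n_seg
  if (k < 1) {
    stop(sprintf("record (%d samples) shorter than one %g-s segment (%d samples)",
                 length(wave), seg_s, n_seg), call. = FALSE)
  }
  starts <- (seq_len(k) - 1) * n_seg + 1
  tibble::tibble(
    segment = seq_len(k),
    start_index = starts,
    wave = purrr::map(starts, function(s) {
      rewave(as.numeric(wave)[s:(s + n_seg - 1)], wave)
    })
  )
}

#' First and second derivatives of a waveform
#'
#' Central finite differences scaled by the sampling rate, with one-sided
#' differences at the boundaries; the second derivative is the derivative of
#' the first. PPG' tracks aortic flow velocity and PPG'' (the acceleration
#' plethysmogram, SDPTG) its change, which is why both are carried as extra
#' image channels downstream.
#'
#' @param wave A [waveform()] with at least 5 samples.
#' @return A `derivative_set`: list with [waveform()] fields `ppg`, `d1`, `d2`.
#' @export
derivatives <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  if (length(wave) < 5) stop("need at least 5 samples", call. = FALSE)
  d1 <- finite_diff(as.numeric(wave), fs_hz(wave))
  d2 <- finite_diff(d1, fs_hz(wave))
  structure(list(ppg = wave,
                 d1 = rewave(d1, wave, units = paste0(wave_units(wave), "/s")),
                 d2 = rewave(d2, wave, units = paste0(wave_units(wave), "/s^2"))),
            class = "derivative_set")
}

finite_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d * fs
}
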